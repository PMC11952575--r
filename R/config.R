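#' Default pipeline configuration
#'
#' Returns the nested list of tunable parameters used across the pipeline.
#' Any subset can be overridden by passing a nested list; unspecified values
#' keep their defaults.
#'
#' Sections:
#' \describe{
#'   \item{io}{`min_quality` (phred-like transcript quality cutoff, default
#'     20), `min_counts` (cells with fewer total transcripts are dropped from
#'     count matrices and summaries, default 5), `aliases` (column alias map
#'     accepting both generic and Xenium column names).}
#'   \item{reference}{`fold_change` (a gene is a marker of a cell type when
#'     its mean expression there exceeds `fold_change` times its mean in every
#'     other type, default 2), `min_expr` (minimum-expression floor for marker
#'     calls).}
#'   \item{embedding}{`mode` (`"reference"` or `"learned"`), `d` (embedding
#'     dimension, default 16).}
#'   \item{graph}{`k_tt` / `tt_max_dist` (transcript-transcript kNN, default
#'     5 neighbours within 5 um), `k_cells` / `tc_max_dist` (candidate
#'     transcript-cell edges to nearest nucleus centroids, default 4 within
#'     15 um), `z_scale` (weight of the z axis in distances), `tile_target`
#'     (max core transcripts per tile), `margin` (`NULL` = computed from the
#'     model receptive field so tiling never changes results).}
#'   \item{model}{architecture and training hyperparameters; see
#'     [train_model()].}
#'   \item{policy}{assignment and fragment-grouping thresholds; see
#'     [assign_transcripts()] and [group_fragments()].}
#' }
#'
#' @param overrides nested list of values to override.
#' @return Nested configuration list.
#' @export
linkseg_config <- function(overrides = list()) {
  cfg <- list(
    io = list(
      min_quality = 20,
      min_counts = 5,
      aliases = default_aliases()
    ),
    reference = list(fold_change = 2, min_expr = 1e-6),
    embedding = list(mode = "reference", d = 16),
    graph = list(
      k_tt = 5, tt_max_dist = 5,
      k_cells = 4, tc_max_dist = 15,
      z_scale = 1,
      tile_target = 50000, margin = NULL,
      missing_gene = "error"
    ),
    model = list(
      d_latent = 64, n_layers = 2, n_heads = 4, dropout = 0.1,
      lr = 3e-3, epochs = 50, batch_tiles = 1, neg_per_pos = 4,
      val_fraction = 0.1, seed = 1
    ),
    policy = list(
      score_threshold = 0.5,
      fragment_min_size = 5,
      fragment_link_dist = 5,
      fragment_sim_threshold = 0.5
    )
  )
  modifyList(cfg, overrides)
}

#' Receptive-field radius of the model, in micrometres
#'
#' Message passing widens the neighbourhood a node's latent state depends
#' on: per layer, transcripts gather over transcript-transcript edges (up to
#' `tt_max_dist`) and then over candidate cell edges (up to `tc_max_dist`);
#' cells gather from the updated transcripts. The returned radius bounds how
#' far away an input can influence a transcript-cell score, and is used as
#' the default tile margin so that per-tile inference is exact: a core
#' transcript's score never depends on data outside its padded tile.
#'
#' @param cfg configuration list from [linkseg_config()].
#' @return Radius in micrometres.
#' @export
receptive_field <- function(cfg) {
  tt <- cfg$graph$tt_max_dist
  tc <- cfg$graph$tc_max_dist
  r_t <- 0; r_c <- 0
  for (l in seq_len(cfg$model$n_layers)) {
    r_t <- max(r_t + tt, r_c + tc)
    r_c <- max(r_c, r_t + tc)
  }
  max(r_t, r_c) + tc  # + tc: the scored edge itself spans up to tc_max_dist
}
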