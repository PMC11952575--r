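# Turning edge scores into per-transcript assignments, grouping leftover
# transcripts into fragments, and stitching tiles into one slide-level
# result.

#' Assignment policy
#'
#' @param score_threshold minimum link score to accept an assignment.
#' @param fragment_min_size minimum transcripts per fragment.
#' @param fragment_link_dist spatial gate for fragment edges, um.
#' @param fragment_sim_threshold cosine-similarity gate on transcript latents.
#' @return An `assignment_policy` list.
#' @export
assignment_policy <- function(score_threshold = 0.5, fragment_min_size = 5,
                              fragment_link_dist = 5,
                              fragment_sim_threshold = 0.5) {
  stopifnot(score_threshold >= 0, score_threshold <= 1,
            fragment_min_size >= 1,
            fragment_sim_threshold >= -1, fragment_sim_threshold <= 1)
  structure(list(score_threshold = score_threshold,
                 fragment_min_size = fragment_min_size,
                 fragment_link_dist = fragment_link_dist,
                 fragment_sim_threshold = fragment_sim_threshold),
            class = "assignment_policy")
}

#' Assign each transcript to its best-scoring candidate cell
#'
#' A transcript takes the argmax-scoring candidate cell when that score
#' reaches `score_threshold`, else it is `UNASSIGNED`. Exact score ties
#' break toward the smaller `cell_id`.
#'
#' @param scores data.frame `transcript_id, cell_id, score` from
#'   [predict_scores()].
#' @param policy an [assignment_policy()].
#' @return data.frame `transcript_id, assignment, score` (one row per
#'   transcript appearing in `scores`).
#' @export
assign_transcripts <- function(scores, policy = assignment_policy()) {
  if (nrow(scores) == 0) {
    return(data.frame(transcript_id = character(0), assignment = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  o <- order(scores$transcript_id, -scores$score, scores$cell_id)
  best <- scores[o, , drop = FALSE]
  best <- best[!duplicated(best$transcript_id), , drop = FALSE]
  out <- data.frame(transcript_id = best$transcript_id,
                    assignment = ifelse(best$score >= policy$score_threshold,
                                        best$cell_id, UNASSIGNED),
                    score = best$score, stringsAsFactors = FALSE)
  out[order(out$transcript_id), , drop = FALSE]
}

#' Group unassigned transcripts into fragments
#'
#' Builds a graph on unassigned transcripts with an edge when the spatial
#' distance is at most `fragment_link_dist` and the cosine similarity of
#' model latents is at least `fragment_sim_threshold`; fragments are the
#' connected components of size at least `fragment_min_size`. Smaller
#' components stay unassigned. Fragment ids are deterministic, ordered by
#' the smallest member `transcript_id`.
#'
#' @param unassigned `transcript_table` subset of unassigned transcripts.
#' @param latents matrix of final transcript latents, rows named by
#'   transcript id (attribute `"z_t"` of [predict_scores()]).
#' @param policy an [assignment_policy()].
#' @return Named character vector transcript_id -> fragment_id for all
#'   transcripts placed in a fragment.
#' @export
group_fragments <- function(unassigned, latents, policy = assignment_policy()) {
  n <- nrow(unassigned)
  if (n == 0) return(setNames(character(0), character(0)))
  pr <- cpp_radius_pairs(unassigned$x, unassigned$y, policy$fragment_link_dist)
  keep <- logical(length(pr$i))
  if (length(pr$i)) {
    z <- latents[unassigned$transcript_id, , drop = FALSE]
    nz <- sqrt(rowSums(z^2)); nz[nz == 0] <- 1
    zn <- z / nz
    cs <- rowSums(zn[pr$i, , drop = FALSE] * zn[pr$j, , drop = FALSE])
    keep <- cs >= policy$fragment_sim_threshold
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(rbind(pr$i[keep], pr$j[keep])))
  comp <- igraph::components(g)$membership
  ids <- unassigned$transcript_id
  frag_members <- split(ids, comp)
  frag_members <- frag_members[lengths(frag_members) >= policy$fragment_min_size]
  if (length(frag_members) == 0) return(setNames(character(0), character(0)))
  ord <- order(vapply(frag_members, min, ""))
  frag_members <- frag_members[ord]
  fids <- sprintf("frag_%06d", seq_along(frag_members))
  out <- setNames(rep(fids, lengths(frag_members)),
                  unlist(frag_members, use.names = FALSE))
  out
}

#' Stitch per-tile assignments into one result
#'
#' Each transcript's record is taken only from the tile where it is core;
#' margin duplicates are discarded. Errors if any transcript is core in
#' zero or several tiles.
#'
#' @param tile_assignments list of per-tile data.frames
#'   (`transcript_id, assignment, score, core`).
#' @param plan the `tile_plan` used.
#' @return data.frame `transcript_id, assignment, score` covering every
#'   transcript exactly once.
#' @export
stitch_tiles <- function(tile_assignments, plan) {
  core_rows <- lapply(tile_assignments, function(df) {
    df[df$core, c("transcript_id", "assignment", "score"), drop = FALSE]
  })
  out <- do.call(rbind, core_rows)
  if (anyDuplicated(out$transcript_id)) {
    stop("internal consistency error: transcript core in multiple tiles")
  }
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end segmentation of a dataset
#'
#' Composes tiling, graph construction, model scoring, thresholded
#' assignment, tile stitching and slide-wide fragment grouping, and attaches
#' a run report (counts per category, median transcripts per cell and per
#' fragment).
#'
#' @param transcripts a `transcript_table`.
#' @param nuclei a `boundary_set` of initial (nucleus) boundaries.
#' @param model a `trained_model`.
#' @param cfg configuration; defaults to the model's.
#' @param policy an [assignment_policy()]; defaults from `cfg$policy`.
#' @return A `segmentation_result` with a `report` attribute.
#' @export
segment_dataset <- function(transcripts, nuclei, model, cfg = model$config,
                            policy = NULL) {
  if (is.null(policy)) policy <- do.call(assignment_policy, cfg$policy)
  if (nrow(transcripts) == 0) {
    res <- segmentation_result(character(0), character(0), numeric(0),
                               character(0))
    attr(res, "report") <- list(n_transcripts = 0L, n_assigned = 0L,
                                n_fragment = 0L, n_unassigned = 0L,
                                n_cells = 0L, n_fragments = 0L,
                                median_per_cell = NA_real_,
                                median_per_fragment = NA_real_)
    return(res)
  }
  margin <- cfg$graph$margin
  if (is.null(margin)) margin <- receptive_field(cfg)
  plan <- plan_tiles(transcripts, tile_target = cfg$graph$tile_target,
                     margin = margin)
  overlap <- label_by_overlap(transcripts, nuclei)
  tile_out <- vector("list", length(plan$tiles))
  latents <- vector("list", length(plan$tiles))
  for (k in seq_along(plan$tiles)) {
    g <- build_tile_graph(plan$tiles[[k]], transcripts, nuclei,
                          model$embedding, cfg, overlap = overlap,
                          feat_stats = model$feat_stats)
    sc <- predict_scores(model, g)
    asg <- assign_transcripts(sc, policy)
    # transcripts with no candidate edge at all stay unassigned
    missing <- setdiff(g$t_ids, asg$transcript_id)
    if (length(missing)) {
      asg <- rbind(asg, data.frame(transcript_id = missing,
                                   assignment = UNASSIGNED, score = NA_real_,
                                   stringsAsFactors = FALSE))
    }
    asg$core <- g$core[match(asg$transcript_id, g$t_ids)]
    tile_out[[k]] <- asg
    zt <- attr(sc, "z_t")
    latents[[k]] <- zt[g$core[match(rownames(zt), g$t_ids)], , drop = FALSE]
  }
  stitched <- stitch_tiles(tile_out, plan)
  if (!setequal(stitched$transcript_id, transcripts$transcript_id)) {
    stop("internal consistency error: stitched result does not cover inputs")
  }
  z_all <- do.call(rbind, latents)
  un_ids <- stitched$transcript_id[stitched$assignment == UNASSIGNED]
  un_tab <- transcripts[match(un_ids, transcripts$transcript_id), , drop = FALSE]
  frags <- group_fragments(un_tab, z_all, policy)
  assignment <- stitched$assignment
  source <- ifelse(assignment == UNASSIGNED, "none", "model")
  score <- ifelse(source == "model", stitched$score, NA_real_)
  fi <- match(stitched$transcript_id, names(frags))
  hit <- !is.na(fi)
  assignment[hit] <- frags[fi[hit]]
  source[hit] <- "fragment"
  score[hit] <- NA_real_
  res <- segmentation_result(
    stitched$transcript_id, assignment, score, source,
    provenance = list(config_hash = rlang::hash(cfg),
                      seed = cfg$model$seed, model_id = model$model_id))
  cell_sizes <- table(res$assignment[res$source == "model"])
  frag_sizes <- table(res$assignment[res$source == "fragment"])
  attr(res, "report") <- list(
    n_transcripts = nrow(res),
    n_assigned = sum(res$source == "model"),
    n_fragment = sum(res$source == "fragment"),
    n_unassigned = sum(res$source == "none"),
    n_cells = length(cell_sizes),
    n_fragments = length(frag_sizes),
    median_per_cell = if (length(cell_sizes)) median(as.numeric(cell_sizes)) else NA_real_,
    median_per_fragment = if (length(frag_sizes)) median(as.numeric(frag_sizes)) else NA_real_)
  res
}
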