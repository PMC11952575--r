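# Ground-truthed synthetic tissue: convex cell territories from a bounded
# Voronoi tessellation, interior nuclei, cell-type-specific gene programs
# with designated markers, mostly-cytoplasmic transcript placement, a
# diffusion (mis-localisation) noise fraction, and nucleus-free cells. All
# randomness flows through one seeded generator, so outputs are fully
# deterministic under `seed`.

#' Parameters of the synthetic tissue generator
#'
#' Defaults describe a desk-scale tissue patch: 100 cells in a
#' 150 x 150 um window (~225 um^2 per cell, typical of packed epithelium),
#' a 60-gene panel over 4 cell types with 5 designated markers each, a mean
#' of 50 transcripts per cell, nuclei at half the linear size of their cell,
#' 30% of a cell's transcripts nuclear (cytoplasmic transcripts dominate),
#' 5% of transcripts displaced by 2 um isotropic Gaussian diffusion, and 10%
#' of cells lacking a detectable nucleus.
#'
#' @param extent width/height of the tissue rectangle, um.
#' @param n_cells number of cells.
#' @param n_genes panel size.
#' @param n_types number of cell types.
#' @param markers_per_type designated marker genes per type.
#' @param transcripts_per_cell_mean Poisson mean of per-cell transcript count.
#' @param nuclear_fraction share of a cell's transcripts placed inside its
#'   nucleus (inside the whole cell when it has no nucleus).
#' @param diffusion_fraction share of transcripts displaced by Gaussian noise.
#' @param diffusion_sigma displacement scale per axis, um.
#' @param nucleus_free_fraction share of cells with no nucleus.
#' @param nucleus_scale linear scale of nucleus relative to its cell.
#' @param marker_boost expression multiplier of a marker in its own type.
#' @param min_spacing minimum distance between cell seed points, um.
#' @param z_thickness slab thickness for 3D mode; 0 keeps all z at 0.
#' @param seed RNG seed.
#' @return A `tissue_params` list.
#' @export
tissue_params <- function(extent = c(150, 150), n_cells = 100, n_genes = 60,
                          n_types = 4, markers_per_type = 5,
                          transcripts_per_cell_mean = 50,
                          nuclear_fraction = 0.3, diffusion_fraction = 0.05,
                          diffusion_sigma = 2, nucleus_free_fraction = 0.1,
                          nucleus_scale = 0.5, marker_boost = 10,
                          min_spacing = 2, z_thickness = 0, seed = 1) {
  p <- list(extent = extent, n_cells = n_cells, n_genes = n_genes,
            n_types = n_types, markers_per_type = markers_per_type,
            transcripts_per_cell_mean = transcripts_per_cell_mean,
            nuclear_fraction = nuclear_fraction,
            diffusion_fraction = diffusion_fraction,
            diffusion_sigma = diffusion_sigma,
            nucleus_free_fraction = nucleus_free_fraction,
            nucleus_scale = nucleus_scale, marker_boost = marker_boost,
            min_spacing = min_spacing, z_thickness = z_thickness, seed = seed)
  fr <- c(p$nuclear_fraction, p$diffusion_fraction, p$nucleus_free_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (p$n_types > p$n_cells) stop("n_types must not exceed n_cells")
  if (p$markers_per_type * p$n_types > p$n_genes) {
    stop("markers_per_type * n_types must not exceed n_genes")
  }
  class(p) <- "tissue_params"
  p
}

#' Simulate the cell map: territories, nuclei, types
#'
#' Places `n_cells` seed points uniformly (with a minimum spacing), takes
#' their bounded Voronoi territories as cell polygons (tiling the extent
#' exactly), shrinks each toward its centroid by `nucleus_scale` to form the
#' nucleus, removes the nucleus from `floor(nucleus_free_fraction * n_cells)`
#' cells, and assigns cell types uniformly at random.
#'
#' @param params a [tissue_params()] list.
#' @return List with `cells` and `nuclei` (`boundary_set`s; nucleus-free
#'   cells are absent from `nuclei`) and `truth` (partial ground truth:
#'   `type`, `cell_polygons`, `nucleus_polygons`, `seeds`).
#' @export
simulate_cell_map <- function(params) {
  p <- params
  area_per_cell <- prod(p$extent) / p$n_cells
  if (area_per_cell < 2 * p$min_spacing^2) {
    stop("generation error: extent too small to host n_cells at minimum spacing")
  }
  with_seed(p$seed, {
    # dart throwing for seed points with minimum spacing
    sx <- numeric(0); sy <- numeric(0)
    tries <- 0
    while (length(sx) < p$n_cells) {
      cx <- runif(1, 0, p$extent[1]); cy <- runif(1, 0, p$extent[2])
      if (length(sx) == 0 ||
          min((sx - cx)^2 + (sy - cy)^2) >= p$min_spacing^2) {
        sx <- c(sx, cx); sy <- c(sy, cy)
      }
      tries <- tries + 1
      if (tries > 200 * p$n_cells) {
        stop("generation error: extent too small to host n_cells at minimum spacing")
      }
    }
    ids <- sprintf("cell_%04d", seq_len(p$n_cells))
    polys <- bounded_voronoi(sx, sy, p$extent[1], p$extent[2])
    names(polys) <- ids
    n_free <- floor(p$nucleus_free_fraction * p$n_cells)
    free_ids <- if (n_free > 0) sample(ids, n_free) else character(0)
    nuc <- lapply(polys, function(pp) scale_polygon(pp, p$nucleus_scale))
    nuc <- nuc[setdiff(ids, free_ids)]
    types <- sample(sprintf("type_%02d", seq_len(p$n_types)),
                    p$n_cells, replace = TRUE)
    names(types) <- ids
    truth <- list(type = types, cell_polygons = polys, nucleus_polygons = nuc,
                  seeds = cbind(x = sx, y = sy), nucleus_free = free_ids)
    list(cells = boundary_set(polys, "cell"),
         nuclei = boundary_set(nuc, "nucleus"),
         truth = truth)
  })
}

#' Synthetic scRNA-seq-style reference matrix
#'
#' Non-marker genes get a uniform positive baseline expression in every cell
#' type. Designated markers are strictly type-exclusive: a marker's baseline
#' is multiplied by `marker_boost` in its own type and zeroed in all other
#' types, so markers of different types are never co-expressed — the property
#' the exclusive-pair / MECR evaluation relies on. Columns are normalized to
#' sum to 1. Markers are recorded exactly as designated (even when
#' `marker_boost = 1` leaves the own-type level at baseline).
#'
#' @param n_genes,n_types,markers_per_type panel layout.
#' @param marker_boost expression multiplier (default 10).
#' @param seed RNG seed.
#' @return A `reference_matrix` with columns summing to 1.
#' @export
derive_reference <- function(n_genes, n_types, markers_per_type,
                             marker_boost = 10, seed = 1) {
  if (markers_per_type * n_types > n_genes) {
    stop("markers_per_type * n_types must not exceed n_genes")
  }
  with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    types <- sprintf("type_%02d", seq_len(n_types))
    m <- matrix(runif(n_genes * n_types, 0.5, 1.5), n_genes, n_types,
                dimnames = list(genes, types))
    markers <- list()
    for (t in seq_len(n_types)) {
      sel <- ((t - 1) * markers_per_type + 1):(t * markers_per_type)
      m[sel, ] <- 0                          # markers are type-exclusive
      m[sel, t] <- runif(length(sel), 0.5, 1.5) * marker_boost
      markers[[types[t]]] <- genes[sel]
    }
    m <- sweep(m, 2, colSums(m), "/")
    reference_matrix(m, markers = markers)
  })
}

#' Sample transcripts from the cell map
#'
#' Per cell, the transcript count is Poisson(`transcripts_per_cell_mean`);
#' each transcript's gene is drawn from the cell type's normalized reference
#' profile. Placement is uniform in the nucleus with probability
#' `nuclear_fraction` (uniform in the whole cell for nucleus-free cells),
#' otherwise uniform in the cytoplasm (cell minus nucleus). A
#' `diffusion_fraction` of transcripts is then displaced by Gaussian noise
#' of scale `diffusion_sigma` per axis. `true_assignment` records the source
#' cell regardless of where the transcript lands.
#'
#' @param params a [tissue_params()] list.
#' @param truth partial ground truth from [simulate_cell_map()].
#' @param ref a `reference_matrix` with `n_types` columns.
#' @return List with `transcripts` (a `transcript_table`) and `truth`
#'   (augmented with `assignment`: transcript_id -> source cell_id).
#' @export
sample_transcripts <- function(params, truth, ref) {
  p <- params
  if (length(ref$cell_types) != p$n_types) {
    stop("reference must have n_types columns")
  }
  with_seed(p$seed + 1L, {
    ids <- names(truth$cell_polygons)
    counts <- rpois(length(ids), p$transcripts_per_cell_mean)
    total <- sum(counts)
    src <- rep(ids, counts)
    gene <- character(total); xs <- numeric(total); ys <- numeric(total)
    pos <- 1
    for (ci in seq_along(ids)) {
      n <- counts[ci]
      if (n == 0) next
      id <- ids[ci]
      cellp <- truth$cell_polygons[[id]]
      nucp <- truth$nucleus_polygons[[id]]
      profile <- ref$mean_expr[, truth$type[[id]]]
      g <- sample(ref$genes, n, replace = TRUE, prob = profile)
      nuclear <- runif(n) < p$nuclear_fraction
      pts <- matrix(0, n, 2)
      if (is.null(nucp)) {
        pts <- sample_in_polygon(n, cellp)
      } else {
        if (any(nuclear)) pts[nuclear, ] <- sample_in_polygon(sum(nuclear), nucp)
        if (any(!nuclear)) {
          # cytoplasm = cell minus nucleus, by rejection against the nucleus
          need <- sum(!nuclear)
          acc <- matrix(0, 0, 2)
          while (nrow(acc) < need) {
            cand <- sample_in_polygon(2 * (need - nrow(acc)) + 8, cellp)
            inside_nuc <- point_in_polygon(cand[, 1], cand[, 2], nucp)
            acc <- rbind(acc, cand[!inside_nuc, , drop = FALSE])
          }
          pts[!nuclear, ] <- acc[seq_len(need), ]
        }
      }
      seg <- pos:(pos + n - 1)
      gene[seg] <- g; xs[seg] <- pts[, 1]; ys[seg] <- pts[, 2]
      pos <- pos + n
    }
    diffused <- runif(total) < p$diffusion_fraction
    nd <- sum(diffused)
    if (nd > 0 && p$diffusion_sigma > 0) {
      xs[diffused] <- xs[diffused] + rnorm(nd, 0, p$diffusion_sigma)
      ys[diffused] <- ys[diffused] + rnorm(nd, 0, p$diffusion_sigma)
    }
    z <- if (p$z_thickness > 0) runif(total, 0, p$z_thickness) else rep(0, total)
    tid <- sprintf("t%07d", seq_len(total))
    tt <- transcript_table(tid, gene, xs, ys, z = z,
                           quality = round(runif(total, 25, 45), 1))
    truth$assignment <- setNames(src, tid)[tt$transcript_id]
    list(transcripts = tt, truth = truth)
  })
}

#' One-call synthetic tissue
#'
#' Composes [simulate_cell_map()], [derive_reference()] and
#' [sample_transcripts()].
#'
#' @param params a [tissue_params()] list.
#' @return List with `transcripts`, `cells`, `nuclei`, `reference`, `truth`.
#' @export
simulate_tissue <- function(params = tissue_params()) {
  cm <- simulate_cell_map(params)
  ref <- derive_reference(params$n_genes, params$n_types,
                          params$markers_per_type,
                          marker_boost = params$marker_boost,
                          seed = params$seed)
  st <- sample_transcripts(params, cm$truth, ref)
  list(transcripts = st$transcripts, cells = cm$cells, nuclei = cm$nuclei,
       reference = ref, truth = st$truth)
}
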