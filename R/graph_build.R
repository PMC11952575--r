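# Conversion of transcripts + boundaries into labeled heterogeneous graphs:
# nucleus-overlap labeling, spatial kNN transcript-transcript edges,
# candidate transcript-cell edges, cell geometry features, adaptive tiling.

#' Label transcripts by nucleus overlap
#'
#' Maps each transcript to the unique nucleus containing its (x, y) under
#' the even-odd rule with boundary points counting as inside. Transcripts
#' inside several (overlapping) nuclei are ambiguous and map to none; the
#' ambiguous count is reported via `message()`.
#'
#' @param transcripts a `transcript_table`.
#' @param nuclei a `boundary_set`.
#' @return Named character vector transcript_id -> cell_id (`NA` = none).
#' @export
label_by_overlap <- function(transcripts, nuclei) {
  n <- nrow(transcripts)
  hits <- integer(n)           # how many nuclei contain each transcript
  lab <- rep(NA_character_, n)
  px <- transcripts$x; py <- transcripts$y
  for (id in names(nuclei$polygons)) {
    p <- nuclei$polygons[[id]]
    bx <- range(p[, 1]); by <- range(p[, 2])
    cand <- which(px >= bx[1] & px <= bx[2] & py >= by[1] & py <= by[2])
    if (length(cand) == 0) next
    inside <- point_in_polygon(px[cand], py[cand], p)
    sel <- cand[inside]
    lab[sel] <- ifelse(hits[sel] == 0, id, lab[sel])
    hits[sel] <- hits[sel] + 1
  }
  amb <- hits > 1
  if (any(amb)) {
    message(sprintf("label_by_overlap: %d transcript(s) inside multiple nuclei; left unlabeled", sum(amb)))
    lab[amb] <- NA_character_
  }
  setNames(lab, transcripts$transcript_id)
}

#' Spatial k-nearest-neighbour transcript-transcript edges
#'
#' For each transcript, edges to its `k` nearest neighbours under the metric
#' `sqrt(dx^2 + dy^2 + (z_scale*dz)^2)`, dropping pairs beyond `max_dist`,
#' then symmetrized (both directions present). No self edges; exact distance
#' ties break toward the smaller `transcript_id`.
#'
#' @param transcripts a `transcript_table` (rows id-sorted).
#' @param k neighbours per transcript.
#' @param max_dist distance cutoff, um (`Inf` allowed).
#' @param z_scale weight of the z axis.
#' @return data.frame `i, j, dist` of directed edges (row indices into
#'   `transcripts`), containing each undirected edge in both directions.
#' @export
knn_tt_edges <- function(transcripts, k = 5, max_dist = 5, z_scale = 1) {
  stopifnot(k >= 1)
  n <- nrow(transcripts)
  if (n < 2 || max_dist <= 0) {
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  e <- cpp_grid_knn(transcripts$x, transcripts$y, transcripts$z,
                    z_scale, as.integer(min(k, n - 1)), max_dist)
  if (length(e$i) == 0) {
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  # symmetrize: keep the union of (i,j) and (j,i)
  a <- pmin(e$i, e$j); b <- pmax(e$i, e$j)
  key <- paste(a, b)
  keep <- !duplicated(key)
  ua <- a[keep]; ub <- b[keep]; ud <- e$dist[keep]
  out <- data.frame(i = c(ua, ub), j = c(ub, ua), dist = c(ud, ud))
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate transcript-cell edges with training labels
#'
#' Per transcript, edges to its `k_cells` nearest nuclei by centroid
#' distance within `max_dist`. The edge to the transcript's containing
#' nucleus (from `overlap`) is labeled `positive` (and added even if the
#' centroid ranks beyond `k_cells`); edges to other nuclei are `negative`
#' for transcripts that have a containing nucleus, and `unlabeled` for
#' transcripts that do not (excluded from any training loss). The `dist`
#' attribute carried by each edge is the distance to the nucleus polygon
#' itself (0 for transcripts inside it), which is far more informative to
#' the model's distance-aware attention than the centroid distance used for
#' candidate selection.
#'
#' @param transcripts a `transcript_table`.
#' @param nuclei a `boundary_set`.
#' @param overlap mapping from [label_by_overlap()].
#' @param k_cells candidate nuclei per transcript.
#' @param max_dist centroid distance cutoff, um.
#' @return data.frame `t, c, dist, label` (`t` row index into `transcripts`,
#'   `c` index into `names(nuclei$polygons)`).
#' @export
candidate_tc_edges <- function(transcripts, nuclei, overlap, k_cells = 4,
                               max_dist = 15) {
  ids <- names(nuclei$polygons)
  n <- nrow(transcripts)
  if (n == 0 || length(ids) == 0) {
    return(data.frame(t = integer(0), c = integer(0), dist = numeric(0),
                      label = character(0)))
  }
  cen <- t(vapply(nuclei$polygons, polygon_centroid, numeric(2)))
  e <- cpp_knn_query(transcripts$x, transcripts$y, cen[, 1], cen[, 2],
                     as.integer(min(k_cells, length(ids))), max_dist)
  t_idx <- e$i; c_idx <- e$j; dist <- e$dist
  own <- match(overlap[transcripts$transcript_id], ids)  # containing nucleus
  # ensure the positive edge exists even when its centroid is not in range
  has_pos <- rep(FALSE, n)
  if (length(t_idx)) {
    pos_edge <- own[t_idx] == c_idx & !is.na(own[t_idx])
    has_pos[unique(t_idx[which(pos_edge)])] <- TRUE
  }
  add <- which(!is.na(own) & !has_pos)
  if (length(add)) {
    dd <- sqrt((transcripts$x[add] - cen[own[add], 1])^2 +
               (transcripts$y[add] - cen[own[add], 2])^2)
    t_idx <- c(t_idx, add); c_idx <- c(c_idx, own[add]); dist <- c(dist, dd)
  }
  lab <- rep("unlabeled", length(t_idx))
  labeled <- !is.na(own[t_idx])
  lab[labeled] <- ifelse(own[t_idx[labeled]] == c_idx[labeled],
                         "positive", "negative")
  # replace centroid distance (selection metric) by polygon distance
  for (ci in unique(c_idx)) {
    sel <- c_idx == ci
    dist[sel] <- points_polygon_distance(transcripts$x[t_idx[sel]],
                                         transcripts$y[t_idx[sel]],
                                         nuclei$polygons[[ci]])
  }
  out <- data.frame(t = t_idx, c = c_idx, dist = dist, label = lab)
  out <- out[order(out$t, out$c), , drop = FALSE]
  rownames(out) <- NULL
  isolated <- n - length(unique(out$t))
  if (isolated > 0) {
    warning(sprintf("%d transcript(s) have no nucleus within %g um", isolated,
                    max_dist))
  }
  out
}

#' Geometric features of a boundary polygon
#'
#' Area (shoelace), perimeter, circularity `4*pi*A/P^2`, elongation
#' (minor/major axis ratio of the second-moment ellipse), convexity
#' `A / A_hull`, and `log1p` of the transcript count inside.
#'
#' @param poly vertex matrix (x, y).
#' @param n_inside transcripts inside the polygon (for the count feature).
#' @return Named numeric vector of the 6 features.
#' @export
cell_geom_features <- function(poly, n_inside = 0) {
  a <- polygon_area(poly)
  if (nrow(poly) < 3 || a <= 0) stop("degenerate polygon")
  per <- polygon_perimeter(poly)
  mom <- polygon_second_moments(poly)
  co <- matrix(c(mom$iyy, mom$ixy, mom$ixy, mom$ixx), 2) / mom$area
  ev <- eigen(co, symmetric = TRUE, only.values = TRUE)$values
  elong <- sqrt(max(ev[2], 0) / max(ev[1], 1e-12))
  hull <- poly[rev(grDevices::chull(poly[, 1], poly[, 2])), , drop = FALSE]
  conv <- min(a / polygon_area(hull), 1)
  c(area = a, perimeter = per, circularity = min(4 * pi * a / per^2, 1),
    elongation = elong, convexity = conv, log_count = log1p(n_inside))
}

#' Adaptive tile plan
#'
#' Splits the data extent by recursive bisection at the median coordinate
#' along the longer axis until each core tile holds at most `tile_target`
#' transcripts. Core rectangles are half-open (a transcript on a shared core
#' edge belongs to the lower-coordinate tile) and partition the extent;
#' padded rectangles expand cores by `margin`, clipped to the extent.
#'
#' @param transcripts a `transcript_table`.
#' @param tile_target max core transcripts per tile.
#' @param margin padding width, um.
#' @return A `tile_plan`: list with `tiles` (each `list(core, padded)` as
#'   `c(x0, y0, x1, y1)`), `margin`, `extent`.
#' @export
plan_tiles <- function(transcripts, tile_target = 50000, margin = 30) {
  stopifnot(tile_target >= 1)
  ext <- c(min(transcripts$x), min(transcripts$y),
           max(transcripts$x), max(transcripts$y))
  if (nrow(transcripts) == 0) ext <- c(0, 0, 0, 0)
  split_rect <- function(rect, xs, ys) {
    if (length(xs) <= tile_target) return(list(rect))
    w <- rect[3] - rect[1]; h <- rect[4] - rect[2]
    if (w >= h) {
      s <- median(xs)
      if (s <= rect[1] || s >= rect[3]) return(list(rect))  # no progress
      left <- xs < s
      c(split_rect(c(rect[1], rect[2], s, rect[4]), xs[left], ys[left]),
        split_rect(c(s, rect[2], rect[3], rect[4]), xs[!left], ys[!left]))
    } else {
      s <- median(ys)
      if (s <= rect[2] || s >= rect[4]) return(list(rect))
      low <- ys < s
      c(split_rect(c(rect[1], rect[2], rect[3], s), xs[low], ys[low]),
        split_rect(c(rect[1], s, rect[3], rect[4]), xs[!low], ys[!low]))
    }
  }
  cores <- split_rect(ext, transcripts$x, transcripts$y)
  tiles <- lapply(cores, function(core) {
    padded <- c(max(core[1] - margin, ext[1]), max(core[2] - margin, ext[2]),
                min(core[3] + margin, ext[3]), min(core[4] + margin, ext[4]))
    list(core = core, padded = padded, extent = ext)
  })
  structure(list(tiles = tiles, margin = margin, extent = ext),
            class = "tile_plan")
}

# Half-open core membership: lower edges inclusive, upper edges exclusive
# except where they coincide with the data extent (closed there), so every
# point in the extent belongs to exactly one core.
in_core_halfopen <- function(x, y, core, ext) {
  inx <- x >= core[1] & (x < core[3] | (core[3] == ext[3] & x <= core[3]))
  iny <- y >= core[2] & (y < core[4] | (core[4] == ext[4] & y <= core[4]))
  inx & iny
}

# Which tile's core contains each point.
tile_core_index <- function(plan, x, y) {
  out <- integer(length(x))
  for (k in seq_along(plan$tiles)) {
    sel <- in_core_halfopen(x, y, plan$tiles[[k]]$core, plan$extent)
    out[sel & out != 0L] <- -1L   # overlap: internal error flagged by caller
    out[sel & out == 0L] <- k
  }
  out
}

in_rect_closed <- function(x, y, r) {
  x >= r[1] & x <= r[3] & y >= r[2] & y <= r[4]
}

#' Build the heterogeneous graph of one tile
#'
#' Restricts transcripts to the padded tile, computes nucleus-overlap labels
#' (or reuses a precomputed global mapping), kNN transcript-transcript edges
#' and labeled candidate transcript-cell edges, and attaches node features:
#' gene-embedding rows for transcripts, standardized geometry for cells.
#' Nuclei overlapping the padded tile are included with features computed
#' from the full polygon and global transcript counts, so a cell's features
#' do not depend on the tiling.
#'
#' @param tile `list(core, padded)` from a [plan_tiles()] plan (or `NULL`
#'   for the whole extent).
#' @param transcripts full `transcript_table`.
#' @param nuclei full `boundary_set`.
#' @param embedding a `gene_embedding` covering the panel.
#' @param cfg configuration list ([linkseg_config()]).
#' @param overlap optional precomputed [label_by_overlap()] mapping.
#' @param feat_stats optional `list(mean, sd)` standardization statistics
#'   for cell features (stored in a trained model); computed from this
#'   tile's cells when absent.
#' @return A `hetero_graph` list: `t_ids`, `x_t`, `coords`, `core`,
#'   `c_ids`, `x_c`, `centroids`, `tt`, `tc`, `feat_stats`.
#' @export
build_tile_graph <- function(tile, transcripts, nuclei, embedding, cfg,
                             overlap = NULL, feat_stats = NULL) {
  g <- cfg$graph
  if (is.null(tile)) {
    ext <- c(-Inf, -Inf, Inf, Inf)
    tile <- list(core = ext, padded = ext)
  }
  sel <- in_rect_closed(transcripts$x, transcripts$y, tile$padded)
  tt_tab <- transcripts[sel, , drop = FALSE]
  class(tt_tab) <- c("transcript_table", "data.frame")
  core <- if (!is.null(tile$extent)) {
    in_core_halfopen(tt_tab$x, tt_tab$y, tile$core, tile$extent)
  } else {
    in_rect_closed(tt_tab$x, tt_tab$y, tile$core)
  }
  # nuclei relevant to the padded tile (bbox test, generous)
  keep_nuc <- vapply(nuclei$polygons, function(p) {
    bx <- range(p[, 1]); by <- range(p[, 2])
    reach <- g$tc_max_dist
    bx[2] >= tile$padded[1] - reach && bx[1] <= tile$padded[3] + reach &&
      by[2] >= tile$padded[2] - reach && by[1] <= tile$padded[4] + reach
  }, logical(1))
  nuc <- nuclei
  nuc$polygons <- nuclei$polygons[keep_nuc]
  if (is.null(overlap)) overlap <- label_by_overlap(transcripts, nuclei)
  ov_counts <- table(overlap)  # global per-nucleus transcript counts
  # transcript features
  gi <- match(tt_tab$gene, embedding$genes)
  if (anyNA(gi)) {
    if (identical(g$missing_gene, "error")) {
      stop("gene(s) absent from embedding: ",
           paste(unique(tt_tab$gene[is.na(gi)]), collapse = ", "))
    }
  }
  x_t <- matrix(0, nrow(tt_tab), embedding$d)
  ok <- !is.na(gi)
  x_t[ok, ] <- embedding$vectors[gi[ok], , drop = FALSE]
  # cell features, standardized with training-set statistics
  c_ids <- names(nuc$polygons)
  feats <- if (length(c_ids)) {
    t(vapply(c_ids, function(id) {
      cnt <- if (id %in% names(ov_counts)) as.integer(ov_counts[[id]]) else 0L
      cell_geom_features(nuc$polygons[[id]], cnt)
    }, numeric(6)))
  } else matrix(0, 0, 6)
  if (is.null(feat_stats)) {
    mu <- colMeans(feats)
    sd <- apply(feats, 2, stats::sd)
    sd[!is.finite(sd) | sd < 1e-8] <- 1
    feat_stats <- list(mean = mu, sd = sd)
  }
  x_c <- if (nrow(feats)) {
    sweep(sweep(feats, 2, feat_stats$mean), 2, feat_stats$sd, "/")
  } else feats
  cen <- if (length(c_ids)) {
    t(vapply(nuc$polygons, polygon_centroid, numeric(2)))
  } else matrix(0, 0, 2)
  tt_e <- knn_tt_edges(tt_tab, k = g$k_tt, max_dist = g$tt_max_dist,
                       z_scale = g$z_scale)
  tc_e <- suppressWarnings(
    candidate_tc_edges(tt_tab, nuc, overlap, k_cells = g$k_cells,
                       max_dist = g$tc_max_dist))
  structure(list(t_ids = tt_tab$transcript_id, x_t = x_t,
                 coords = cbind(x = tt_tab$x, y = tt_tab$y, z = tt_tab$z),
                 gene_index = gi, core = core,
                 c_ids = c_ids, x_c = x_c, centroids = cen,
                 tt = tt_e, tc = tc_e, feat_stats = feat_stats),
            class = "hetero_graph")
}
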