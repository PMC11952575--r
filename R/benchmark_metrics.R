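# Evaluation statistics: positive marker purity (PMP), mutually exclusive
# co-expression rate (MECR) with exclusive-pair selection, segmentation
# summary statistics, and precision/recall against synthetic ground truth.

#' Positive cell-type marker purity (PMP)
#'
#' For each cell, the fraction of its cell-type-marker transcripts that are
#' markers of the cell's own annotated type:
#' `PMP(cell) = counts(own-type markers) / counts(markers of any type)`.
#' A true-positive-rate proxy: contamination from neighbouring cells of
#' other types pulls PMP below 1. Cells with zero marker counts are excluded
#' and reported via the `"excluded"` attribute.
#'
#' @param cell_counts cells x genes count matrix (dimnames required).
#' @param cell_type named vector cell -> type (every cell annotated).
#' @param markers named list type -> marker gene set (disjoint across types).
#' @return Named numeric vector of per-cell PMP in `[0, 1]`.
#' @export
positive_marker_purity <- function(cell_counts, cell_type, markers) {
  cells <- rownames(cell_counts)
  missing <- cells[!cells %in% names(cell_type)]
  if (length(missing)) {
    stop("cell type missing for: ", paste(head(missing, 10), collapse = ", "))
  }
  if (anyDuplicated(unlist(markers))) stop("marker sets must be disjoint")
  all_markers <- intersect(unlist(markers), colnames(cell_counts))
  tot <- Matrix::rowSums(cell_counts[, all_markers, drop = FALSE])
  own <- vapply(cells, function(cl) {
    mk <- intersect(markers[[cell_type[[cl]]]], colnames(cell_counts))
    if (length(mk) == 0) return(0)
    sum(cell_counts[cl, mk])
  }, numeric(1))
  ok <- tot > 0
  out <- setNames(as.numeric(own[ok] / tot[ok]), cells[ok])
  attr(out, "excluded") <- cells[!ok]
  out
}

#' Select mutually exclusive gene pairs from a reference
#'
#' Unordered gene pairs whose codetection rate in the reference count matrix
#' — cells detecting both genes divided by cells detecting at least one — is
#' below `codetect_max`. "Detected" means count > 0.
#'
#' @param ref_counts cells x genes reference count matrix.
#' @param codetect_max maximum codetection rate (default 0.01, i.e. <1%).
#' @return data.frame `gene1, gene2, codetection` in lexicographic order.
#' @export
select_exclusive_pairs <- function(ref_counts, codetect_max = 0.01) {
  b <- (as.matrix(ref_counts) > 0) * 1
  genes <- colnames(b)
  both <- crossprod(b)                      # cells detecting both
  npos <- diag(both)
  either <- outer(npos, npos, "+") - both   # cells detecting at least one
  rate <- ifelse(either > 0, both / either, NA)
  sel <- which(upper.tri(rate) & !is.na(rate) & rate < codetect_max,
               arr.ind = TRUE)
  out <- data.frame(gene1 = genes[sel[, 1]], gene2 = genes[sel[, 2]],
                    codetection = rate[sel], stringsAsFactors = FALSE)
  swap <- out$gene1 > out$gene2
  tmp <- out$gene1[swap]; out$gene1[swap] <- out$gene2[swap]; out$gene2[swap] <- tmp
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutually exclusive co-expression rate (MECR)
#'
#' For each selected exclusive pair, the fraction of segmented cells
#' detecting both genes among cells detecting either:
#' `MECR(g1, g2) = #cells(both > 0) / #cells(g1 > 0 or g2 > 0)`.
#' A false-positive (contamination) proxy. Pairs detected in no cell are
#' undefined (`NA`) and excluded from summaries.
#'
#' @param cell_counts cells x genes count matrix from a segmentation.
#' @param pairs data.frame `gene1, gene2` (subset of measured genes).
#' @return Numeric vector of per-pair rates (`NA` = undefined), named
#'   `gene1|gene2`.
#' @export
mecr <- function(cell_counts, pairs) {
  stopifnot(all(c(pairs$gene1, pairs$gene2) %in% colnames(cell_counts)))
  out <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- cell_counts[, pairs$gene1[i]] > 0
    b <- cell_counts[, pairs$gene2[i]] > 0
    denom <- sum(a | b)
    out[i] <- if (denom == 0) NA_real_ else sum(a & b) / denom
  }
  names(out) <- paste(pairs$gene1, pairs$gene2, sep = "|")
  out
}

#' Summary statistics of a segmentation
#'
#' Counts and medians over cells passing the minimum-counts filter
#' (default 5 transcripts); fragments are summarized separately. Median
#' areas are reported only when boundary polygons are supplied.
#'
#' @param result a `segmentation_result`.
#' @param transcripts the matching `transcript_table`.
#' @param boundaries optional `boundary_set` for cell areas.
#' @param min_counts minimum transcripts per cell (default 5).
#' @return List: `n_cells`, `n_fragments`, `median_counts_per_cell`,
#'   `median_counts_per_fragment`, and `median_area` when polygons given.
#' @export
summary_stats <- function(result, transcripts, boundaries = NULL,
                          min_counts = 5) {
  cell_rows <- result[result$source == "model", , drop = FALSE]
  frag_rows <- result[result$source == "fragment", , drop = FALSE]
  cs <- table(cell_rows$assignment)
  fs <- table(frag_rows$assignment)
  cs <- cs[cs >= min_counts]
  fs <- fs[fs >= min_counts]
  out <- list(
    n_cells = length(cs),
    n_fragments = length(fs),
    median_counts_per_cell = if (length(cs)) median(as.numeric(cs)) else NA_real_,
    median_counts_per_fragment = if (length(fs)) median(as.numeric(fs)) else NA_real_
  )
  if (!is.null(boundaries)) {
    ids <- intersect(names(cs), names(boundaries$polygons))
    if (length(ids)) {
      out$median_area <- median(vapply(boundaries$polygons[ids],
                                       polygon_area, numeric(1)))
    }
  }
  out
}

# Greedy largest-overlap matching between predicted and true cells: repeat
# taking the largest remaining overlap entry whose row and column are both
# unmatched; deterministic tie-break by (predicted id, true id).
greedy_match <- function(tab) {
  if (length(tab) == 0 || sum(tab) == 0) return(character(0))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("pred", "true", "n")
  df <- df[df$n > 0, , drop = FALSE]
  df <- df[order(-df$n, df$pred, df$true), , drop = FALSE]
  match_out <- character(0)
  used_pred <- character(0); used_true <- character(0)
  for (i in seq_len(nrow(df))) {
    if (df$pred[i] %in% used_pred || df$true[i] %in% used_true) next
    match_out[df$pred[i]] <- df$true[i]
    used_pred <- c(used_pred, df$pred[i])
    used_true <- c(used_true, df$true[i])
  }
  match_out
}

#' Precision / recall / F1 of transcript assignment vs ground truth
#'
#' Predicted cells are matched to true cells by greedy largest-overlap
#' matching; a cell-assigned transcript is a true positive iff its predicted
#' cell is matched to its true source cell. Precision = TP / cell-assigned
#' transcripts; recall = TP / all transcripts; F1 is their harmonic mean.
#' With no assigned transcripts, precision is undefined and reported as 0
#' with attribute `"precision_undefined"`.
#'
#' @param result a `segmentation_result` (fragment members count as not
#'   cell-assigned).
#' @param truth ground truth with `assignment` (transcript -> source cell).
#' @return List `precision`, `recall`, `f1`, `matching` (pred -> true).
#' @export
assignment_prf <- function(result, truth) {
  true_cell <- truth$assignment[result$transcript_id]
  assigned <- result$source == "model"
  if (!any(assigned)) {
    out <- list(precision = 0, recall = 0, f1 = 0, matching = character(0))
    attr(out, "precision_undefined") <- TRUE
    return(out)
  }
  tab <- table(result$assignment[assigned], true_cell[assigned])
  matching <- greedy_match(tab)
  tp <- sum(matching[result$assignment[assigned]] == true_cell[assigned],
            na.rm = TRUE)
  precision <- tp / sum(assigned)
  recall <- tp / nrow(result)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, matching = matching)
}

#' Nearest-nucleus baseline segmentation
#'
#' Assigns each transcript inside a nucleus to that nucleus, and each other
#' transcript to the nearest nucleus centroid within `max_dist` (else
#' unassigned). The distance-only baseline the model comparison uses.
#'
#' @param transcripts a `transcript_table`.
#' @param nuclei a `boundary_set`.
#' @param max_dist assignment radius, um.
#' @return A `segmentation_result` (source `"model"` with score 1 for
#'   assigned transcripts, to keep the container contract).
#' @export
baseline_nearest_nucleus <- function(transcripts, nuclei, max_dist = 15) {
  overlap <- label_by_overlap(transcripts, nuclei)
  cen <- t(vapply(nuclei$polygons, polygon_centroid, numeric(2)))
  ids <- names(nuclei$polygons)
  e <- cpp_knn_query(transcripts$x, transcripts$y, cen[, 1], cen[, 2],
                     1L, max_dist)
  nearest <- rep(NA_character_, nrow(transcripts))
  nearest[e$i] <- ids[e$j]
  asg <- overlap[transcripts$transcript_id]
  asg[is.na(asg)] <- nearest[is.na(asg)]
  asg[is.na(asg)] <- UNASSIGNED
  src <- ifelse(asg == UNASSIGNED, "none", "model")
  segmentation_result(transcripts$transcript_id, asg,
                      ifelse(src == "model", 1, NA_real_), src)
}

#' Full metrics report for a segmentation
#'
#' @param result a `segmentation_result`.
#' @param transcripts the matching `transcript_table`.
#' @param ref a `reference_matrix` (markers + expression) or `NULL`.
#' @param cell_type named vector cell -> type (required for PMP).
#' @param truth optional ground truth for precision/recall.
#' @param boundaries optional polygons for areas.
#' @param min_counts minimum transcripts per cell.
#' @param codetect_max exclusive-pair codetection cutoff.
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(result, transcripts, ref = NULL, cell_type = NULL,
                           truth = NULL, boundaries = NULL, min_counts = 5,
                           codetect_max = 0.01) {
  out <- summary_stats(result, transcripts, boundaries, min_counts)
  counts <- count_matrix(result, transcripts, min_counts = min_counts)
  cells <- rownames(counts)[!grepl("^frag_", rownames(counts))]
  ccounts <- counts[cells, , drop = FALSE]
  if (!is.null(ref) && !is.null(cell_type)) {
    ct <- cell_type[intersect(names(cell_type), rownames(ccounts))]
    pm <- positive_marker_purity(ccounts[names(ct), , drop = FALSE], ct,
                                 ref$markers)
    out$pmp_per_cell <- pm
    out$mean_pmp <- mean(pm)
    # exclusive pairs from reference profiles: types as pseudo-cells
    pairs <- select_exclusive_pairs(t(ref$mean_expr), codetect_max)
    pairs <- pairs[pairs$gene1 %in% colnames(ccounts) &
                   pairs$gene2 %in% colnames(ccounts), , drop = FALSE]
    if (nrow(pairs)) {
      me <- mecr(ccounts, pairs)
      out$mecr_per_pair <- me
      out$mean_mecr <- mean(me, na.rm = TRUE)
    }
  }
  if (!is.null(truth)) {
    out <- c(out, assignment_prf(result, truth)[c("precision", "recall", "f1")])
  }
  class(out) <- "metrics_report"
  out
}
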