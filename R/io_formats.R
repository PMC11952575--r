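# Readers and writers for on-disk artifacts: transcript tables, boundary
# polygons, reference expression matrices, segmentation results, and
# cell x gene count matrices. CSV is read with data.table::fread; parquet
# via the arrow package when available.

#' Column alias map for transcript tables
#'
#' Accepts both generic column names and the Xenium transcript-table dialect
#' (`x_location`, `feature_name`, `qv`, ...), so public datasets load without
#' renaming. First match wins, in the order listed.
#'
#' @return Named list mapping canonical field -> accepted column names.
#' @export
default_aliases <- function() {
  list(
    transcript_id = c("transcript_id", "id"),
    gene = c("gene", "feature_name"),
    x = c("x", "x_location"),
    y = c("y", "y_location"),
    z = c("z", "z_location"),
    quality = c("quality", "qv"),
    prior_cell_id = c("prior_cell_id", "cell_id")
  )
}

read_table_any <- function(path) {
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading parquet requires the 'arrow' package")
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    as.data.frame(data.table::fread(path))
  }
}

resolve_alias <- function(cols, aliases, field) {
  hit <- intersect(aliases[[field]], cols)
  if (length(hit) == 0) return(NA_character_)
  hit[1]
}

#' Read a transcript table
#'
#' Loads detected molecules (one row per transcript) from CSV or parquet,
#' mapping columns through a configurable alias table, and drops rows below
#' a phred-like quality cutoff.
#'
#' @param path CSV or parquet file.
#' @param min_quality drop transcripts with quality below this (default 20).
#' @param aliases column alias map, see [default_aliases()].
#' @return A `transcript_table`: data.frame with columns `transcript_id`,
#'   `gene`, `x`, `y`, `z`, `quality`, `prior_cell_id`, sorted by
#'   `transcript_id`.
#' @export
read_transcripts <- function(path, min_quality = 20, aliases = default_aliases()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_table_any(path)
  cols <- names(df)
  need <- c("transcript_id", "gene", "x", "y", "quality")
  found <- vapply(need, function(f) resolve_alias(cols, aliases, f), "")
  if (anyNA(found)) {
    stop("format error: missing mandatory column(s): ",
         paste(need[is.na(found)], collapse = ", "))
  }
  zcol <- resolve_alias(cols, aliases, "z")
  pcol <- resolve_alias(cols, aliases, "prior_cell_id")
  out <- data.frame(
    transcript_id = as.character(df[[found["transcript_id"]]]),
    gene = as.character(df[[found["gene"]]]),
    x = as.numeric(df[[found["x"]]]),
    y = as.numeric(df[[found["y"]]]),
    z = if (!is.na(zcol)) as.numeric(df[[zcol]]) else 0,
    quality = as.numeric(df[[found["quality"]]]),
    prior_cell_id = if (!is.na(pcol)) as.character(df[[pcol]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  validate_transcripts(out)
  n0 <- nrow(out)
  out <- out[out$quality >= min_quality, , drop = FALSE]
  if (n0 - nrow(out) > 0) {
    message(sprintf("read_transcripts: dropped %d of %d rows below quality %g",
                    n0 - nrow(out), n0, min_quality))
  }
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transcript_table", "data.frame")
  out
}

validate_transcripts <- function(df) {
  if (anyDuplicated(df$transcript_id)) {
    stop("validation error: duplicate transcript_id values")
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(!is.finite(df$z))) {
    stop("validation error: non-finite coordinates")
  }
  if (any(is.na(df$gene) | df$gene == "")) {
    stop("validation error: empty gene names")
  }
  if (any(df$quality < 0, na.rm = TRUE)) {
    stop("validation error: negative quality values")
  }
  invisible(df)
}

#' Construct a transcript table from vectors
#'
#' @param transcript_id,gene,x,y character / numeric vectors of equal length.
#' @param z,quality,prior_cell_id optional; defaults 0, 40, NA.
#' @return A `transcript_table` sorted by `transcript_id`.
#' @export
transcript_table <- function(transcript_id, gene, x, y, z = 0, quality = 40,
                             prior_cell_id = NA_character_) {
  out <- data.frame(
    transcript_id = as.character(transcript_id), gene = as.character(gene),
    x = as.numeric(x), y = as.numeric(y),
    z = rep_len(as.numeric(z), length(x)),
    quality = rep_len(as.numeric(quality), length(x)),
    prior_cell_id = rep_len(as.character(prior_cell_id), length(x)),
    stringsAsFactors = FALSE
  )
  validate_transcripts(out)
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transcript_table", "data.frame")
  out
}

#' Construct a boundary set from a named list of polygons
#'
#' @param polygons named list of vertex matrices (columns x, y).
#' @param kind `"nucleus"` or `"cell"`.
#' @return A `boundary_set` (list with `polygons`, `kind`).
#' @export
boundary_set <- function(polygons, kind = c("nucleus", "cell")) {
  kind <- match.arg(kind)
  if (is.null(names(polygons)) || anyDuplicated(names(polygons))) {
    stop("validation error: polygons must have unique cell_id names")
  }
  bad <- character(0); selfx <- character(0)
  for (id in names(polygons)) {
    p <- polygons[[id]]
    pu <- unique(round(p, 9))
    if (nrow(pu) < 3 || polygon_area(p) <= 0) {
      bad <- c(bad, id)
    } else if (!polygon_is_simple(p)) {
      selfx <- c(selfx, id)
    }
  }
  if (length(bad)) {
    stop("validation error: degenerate polygon(s): ", paste(bad, collapse = ", "))
  }
  if (length(selfx)) {
    stop("validation error: self-intersecting polygon(s): ",
         paste(selfx, collapse = ", "))
  }
  structure(list(polygons = polygons, kind = kind), class = "boundary_set")
}

#' Read nucleus or cell boundaries
#'
#' Accepts a vertex-list table (columns `cell_id`, `vertex_x`, `vertex_y`,
#' vertices in file order) in CSV/parquet, or a GeoJSON FeatureCollection of
#' Polygon features keyed by a `cell_id` (or `id`) property.
#'
#' @param path input file.
#' @param kind `"nucleus"` or `"cell"`.
#' @return A `boundary_set`.
#' @export
read_boundaries <- function(path, kind = c("nucleus", "cell")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    polys <- list()
    for (i in seq_along(feats)) {
      f <- feats[[i]]
      if (!identical(f$geometry$type, "Polygon")) {
        stop("format error: only Polygon geometries are supported")
      }
      id <- f$properties$cell_id
      if (is.null(id)) id <- f$properties$id
      if (is.null(id)) id <- as.character(i)
      ring <- f$geometry$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
      # GeoJSON rings repeat the first vertex; store the open ring
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      colnames(m) <- c("x", "y")
      polys[[as.character(id)]] <- m
    }
    return(boundary_set(polys, kind))
  }
  df <- read_table_any(path)
  need <- c("cell_id", "vertex_x", "vertex_y")
  if (!all(need %in% names(df))) {
    stop("format error: boundary table needs columns ",
         paste(need, collapse = ", "))
  }
  ids <- unique(as.character(df$cell_id))  # file order
  polys <- lapply(ids, function(id) {
    sel <- df$cell_id == id
    m <- cbind(x = as.numeric(df$vertex_x[sel]), y = as.numeric(df$vertex_y[sel]))
    m
  })
  names(polys) <- ids
  boundary_set(polys, kind)
}

#' Write boundaries as a vertex-list CSV
#' @param b a `boundary_set`.
#' @param path output CSV path.
#' @export
write_boundaries <- function(b, path) {
  rows <- lapply(names(b$polygons), function(id) {
    p <- b$polygons[[id]]
    data.frame(cell_id = id, vertex_x = p[, 1], vertex_y = p[, 2])
  })
  df <- do.call(rbind, rows)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Construct a reference expression matrix
#'
#' Markers per cell type are derived as the genes whose mean expression in
#' that type strictly exceeds `fold_change` times their mean in every other
#' type (so marker sets are disjoint by construction) and exceeds a
#' minimum-expression floor.
#'
#' @param mean_expr genes x cell-types nonnegative matrix with dimnames.
#' @param fold_change marker fold-change rule (default 2).
#' @param min_expr minimum expression for a marker call.
#' @param markers optional pre-designated marker list (named by cell type);
#'   when supplied, derivation is skipped.
#' @return A `reference_matrix` (list with `genes`, `cell_types`,
#'   `mean_expr`, `markers`).
#' @export
reference_matrix <- function(mean_expr, fold_change = 2, min_expr = 1e-6,
                             markers = NULL) {
  if (any(mean_expr < 0)) stop("validation error: negative mean expression")
  genes <- rownames(mean_expr); types <- colnames(mean_expr)
  if (is.null(genes) || is.null(types)) stop("mean_expr needs dimnames")
  if (is.null(markers)) {
    markers <- lapply(types, function(t) {
      own <- mean_expr[, t]
      others <- mean_expr[, setdiff(types, t), drop = FALSE]
      maxo <- apply(others, 1, max)
      genes[own > fold_change * maxo & own >= min_expr]
    })
    names(markers) <- types
  } else {
    markers <- markers[types]
    bad <- setdiff(unlist(markers), genes)
    if (length(bad)) stop("validation error: markers not in genes: ",
                          paste(bad, collapse = ", "))
    if (anyDuplicated(unlist(markers))) {
      stop("validation error: marker sets must be disjoint across cell types")
    }
  }
  structure(list(genes = genes, cell_types = types, mean_expr = mean_expr,
                 markers = markers),
            class = "reference_matrix")
}

#' Read a reference expression matrix
#'
#' @param path_matrix CSV (genes x types, numeric body) or MatrixMarket .mtx.
#' @param path_genes text file of gene names (one per line).
#' @param path_types text file of cell-type names (one per line).
#' @param fold_change,min_expr marker derivation rule, see
#'   [reference_matrix()].
#' @return A `reference_matrix`.
#' @export
read_reference <- function(path_matrix, path_genes, path_types,
                           fold_change = 2, min_expr = 1e-6) {
  genes <- readLines(path_genes)
  types <- readLines(path_types)
  if (grepl("\\.mtx$", path_matrix, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path_matrix))
  } else {
    m <- as.matrix(read_table_any(path_matrix))
  }
  if (nrow(m) != length(genes) || ncol(m) != length(types)) {
    stop("format error: matrix is ", nrow(m), "x", ncol(m),
         " but name files give ", length(genes), " genes and ",
         length(types), " types")
  }
  dimnames(m) <- list(genes, types)
  reference_matrix(m, fold_change = fold_change, min_expr = min_expr)
}

#' Assemble a segmentation result
#'
#' @param transcript_id character vector (all input transcripts, each once).
#' @param assignment cell id, fragment id, or `"UNASSIGNED"` per transcript.
#' @param score model link score in `[0,1]`; `NA` unless `source == "model"`.
#' @param source one of `"model"`, `"fragment"`, `"none"` per transcript.
#' @param provenance list carrying `config_hash`, `seed`, `model_id`.
#' @return A `segmentation_result` data.frame sorted by `transcript_id`.
#' @export
segmentation_result <- function(transcript_id, assignment, score, source,
                                provenance = list()) {
  stopifnot(length(assignment) == length(transcript_id),
            length(score) == length(transcript_id),
            length(source) == length(transcript_id))
  if (anyDuplicated(transcript_id)) {
    stop("validation error: duplicated transcript_id in result")
  }
  if (!all(source %in% c("model", "fragment", "none"))) {
    stop("validation error: bad source values")
  }
  if (any((source == "model") != !is.na(score))) {
    stop("validation error: score must be present iff source == 'model'")
  }
  out <- data.frame(transcript_id = as.character(transcript_id),
                    assignment = as.character(assignment),
                    score = as.numeric(score),
                    source = as.character(source),
                    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  class(out) <- c("segmentation_result", "data.frame")
  out
}

#' Write a segmentation result to CSV
#'
#' Columns `transcript_id, assignment, score, source`, sorted by
#' `transcript_id`; round-trips losslessly through [read_segmentation()].
#'
#' @param result a `segmentation_result`.
#' @param path output CSV.
#' @export
write_segmentation <- function(result, path) {
  df <- as.data.frame(result)[, c("transcript_id", "assignment", "score", "source")]
  df <- df[order(df$transcript_id), , drop = FALSE]
  data.table::fwrite(df, path, na = "")
  invisible(path)
}

#' Read a segmentation result written by [write_segmentation()]
#' @param path CSV path.
#' @return A `segmentation_result`.
#' @export
read_segmentation <- function(path) {
  df <- as.data.frame(data.table::fread(path, na.strings = ""))
  if (nrow(df) == 0) {
    return(segmentation_result(character(0), character(0), numeric(0), character(0)))
  }
  segmentation_result(df$transcript_id, df$assignment, as.numeric(df$score),
                      df$source)
}

#' Cell x gene count matrix from a segmentation
#'
#' @param result a `segmentation_result`.
#' @param transcripts the `transcript_table` the result refers to.
#' @param min_counts cells/fragments with fewer total transcripts are
#'   dropped (default 5).
#' @return Sparse `dgCMatrix`, rows = cells/fragments, cols = genes.
#' @export
count_matrix <- function(result, transcripts, min_counts = 5) {
  idx <- match(result$transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) stop("result references transcripts absent from the table")
  keep <- result$assignment != UNASSIGNED
  cells <- sort(unique(result$assignment[keep]))
  genes <- sort(unique(transcripts$gene))
  if (!any(keep)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0, length(genes)),
                                dimnames = list(character(0), genes)))
  }
  i <- match(result$assignment[keep], cells)
  j <- match(transcripts$gene[idx[keep]], genes)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(cells), length(genes)),
                            dimnames = list(cells, genes))
  m <- methods::as(m, "CsparseMatrix")
  tot <- Matrix::rowSums(m)
  m[tot >= min_counts, , drop = FALSE]
}

#' Write the cell x gene matrix in MatrixMarket form
#'
#' Writes `<path>` (.mtx), plus `<stem>_cells.txt` and `<stem>_genes.txt`
#' name files. Cells and fragments with total counts below `min_counts` are
#' omitted; unassigned transcripts are excluded.
#'
#' @inheritParams count_matrix
#' @param path output `.mtx` path.
#' @return Invisibly, the paths written.
#' @export
write_cell_matrix <- function(result, transcripts, path, min_counts = 5) {
  m <- count_matrix(result, transcripts, min_counts = min_counts)
  Matrix::writeMM(m, path)
  stem <- sub("\\.mtx$", "", path)
  cells_path <- paste0(stem, "_cells.txt")
  genes_path <- paste0(stem, "_genes.txt")
  writeLines(rownames(m), cells_path)
  writeLines(colnames(m), genes_path)
  invisible(c(path, cells_path, genes_path))
}
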