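# Gene feature vectors for transcript nodes: either computed from an
# scRNA-seq-style reference (log1p + row L2 + PCA) or a learnable Gaussian
# table trained together with the model.

new_gene_embedding <- function(genes, vectors, mode) {
  stopifnot(nrow(vectors) == length(genes))
  rownames(vectors) <- genes
  structure(list(genes = genes, vectors = vectors, mode = mode,
                 d = ncol(vectors)),
            class = "gene_embedding")
}

#' Reference-informed gene embedding
#'
#' Rows of `log1p(mean_expr)` are unit-L2-normalized and projected onto the
#' top-`d` principal directions of the resulting gene x type matrix.
#' Deterministic up to sign; signs are fixed by making each component's
#' largest-magnitude loading positive. All-zero gene rows map to the zero
#' vector (with a warning).
#'
#' @param ref a `reference_matrix`.
#' @param d embedding dimension; at most the number of cell types.
#' @return A `gene_embedding` with `mode = "reference"`.
#' @export
reference_embedding <- function(ref, d = 16) {
  m <- log1p(ref$mean_expr)
  norms <- sqrt(rowSums(m^2))
  zero <- norms == 0
  if (any(zero)) {
    warning("all-zero gene row(s): ", paste(ref$genes[zero], collapse = ", "),
            "; assigned the zero vector")
    norms[zero] <- 1
  }
  mn <- m / norms
  ncomp <- min(dim(mn))
  if (d > ncomp) stop("d must not exceed min(n_genes, n_types) = ", ncomp)
  pc <- prcomp(mn, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  scores <- pc$x[, seq_len(d), drop = FALSE]
  # fix signs: largest-|loading| per component positive
  for (k in seq_len(d)) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  v <- scores
  v[zero, ] <- 0
  emb <- new_gene_embedding(ref$genes, v, "reference")
  attr(emb, "rotation") <- rot
  attr(emb, "center") <- pc$center
  emb
}

#' Trainable gene embedding initialization
#'
#' Entries drawn i.i.d. from Gaussian(0, 1/d); marked trainable so the
#' training loop updates rows by gradient descent.
#'
#' @param genes character vector of gene names.
#' @param d embedding dimension.
#' @param seed RNG seed.
#' @return A `gene_embedding` with `mode = "learned"`.
#' @export
learned_embedding_init <- function(genes, d = 16, seed = 1) {
  stopifnot(d >= 1)
  v <- with_seed(seed, {
    matrix(rnorm(length(genes) * d, sd = sqrt(1 / d)), length(genes), d)
  })
  new_gene_embedding(genes, v, "learned")
}

#' Write an embedding as CSV (gene, v1..vd)
#' @param emb a `gene_embedding`.
#' @param path output CSV.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(gene = emb$genes, emb$vectors, check.names = FALSE)
  names(df)[-1] <- paste0("v", seq_len(emb$d))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#' @param path CSV path.
#' @param mode stored mode label.
#' @return A `gene_embedding`.
#' @export
read_embedding <- function(path, mode = "reference") {
  df <- as.data.frame(data.table::fread(path))
  v <- as.matrix(df[, -1, drop = FALSE])
  colnames(v) <- NULL
  new_gene_embedding(df$gene, v, mode)
}
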