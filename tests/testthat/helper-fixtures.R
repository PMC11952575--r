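# Shared fixtures, all built in code at test time.

# small tissue for fast unit tests
small_params <- function(...) {
  tissue_params(n_cells = 20, extent = c(70, 70), n_genes = 20, n_types = 2,
                markers_per_type = 3, transcripts_per_cell_mean = 25,
                seed = 11, ...)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_tissue(small_params())
    cache
  }
})

# tiny config matched to small sims (reference embedding rank <= n_types)
small_cfg <- function(...) {
  linkseg_config(modifyList(
    list(embedding = list(d = 2),
         model = list(d_latent = 16, n_heads = 2, epochs = 8, lr = 3e-3,
                      dropout = 0.1, seed = 3)),
    list(...)))
}

# unit square polygon
unit_square <- function() cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))

# write a minimal transcripts CSV; returns path
write_transcripts_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# brute-force kNN oracle under the anisotropic metric
brute_knn <- function(x, y, z, zscale, k, max_dist) {
  n <- length(x)
  out <- list()
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2 + (zscale * (z - z[i]))^2)
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    sel <- ord[seq_len(min(k, n - 1))]
    sel <- sel[d[sel] <= max_dist]
    if (length(sel)) out[[i]] <- data.frame(i = i, j = sel, dist = d[sel])
  }
  do.call(rbind, out)
}
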