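test_that("attention weights are a proper softmax per node and head", {
  set.seed(1)
  d <- 8; heads <- 2
  par <- linkseg:::init_relation_par(d, heads)
  # random 20-node graph
  n <- 20
  Hd <- matrix(rnorm(n * d), n, d)
  Hs <- matrix(rnorm(n * d), n, d)
  src <- sample(n, 60, replace = TRUE)
  dst <- sample(n, 60, replace = TRUE)
  dist <- runif(60, 0, 5)
  out <- attention_message_pass(Hd, Hs, src, dst, dist, par, heads)
  A <- attr(out, "weights")
  expect_true(all(A >= 0))
  sums <- rowsum(A, dst)
  expect_equal(as.numeric(sums), rep(1, length(unique(dst)) * heads),
               tolerance = 1e-6)
  # dense softmax oracle, head 1
  dh <- d / heads
  Q <- Hd %*% par$Wq; K <- Hs %*% par$Wk
  for (nd in unique(dst)) {
    es <- which(dst == nd)
    logit <- sapply(es, function(e) {
      sum(Q[nd, 1:dh] * K[src[e], 1:dh]) / sqrt(dh) + par$bdist[1] * dist[e]
    })
    expect_equal(unname(A[es, 1]), exp(logit) / sum(exp(logit)),
                 tolerance = 1e-8)
  }
  # nodes with no incoming edges keep their state
  lonely <- setdiff(seq_len(n), dst)
  if (length(lonely)) {
    expect_equal(out[lonely, , drop = FALSE], Hd[lonely, , drop = FALSE])
  }
})

test_that("singleton and tied attention weights are exact", {
  d <- 4
  par <- linkseg:::init_relation_par(d, 1)
  Hd <- matrix(rnorm(2 * d), 2, d)
  Hs <- matrix(rnorm(2 * d), 2, d)
  out1 <- attention_message_pass(Hd, Hs, src = 1L, dst = 1L, dist = 0,
                                 par, 1)
  expect_equal(as.numeric(attr(out1, "weights")), 1)
  # two incoming edges from the same source (identical keys): 0.5 each
  out2 <- attention_message_pass(Hd, Hs, src = c(2L, 2L), dst = c(1L, 1L),
                                 dist = c(1, 1), par, 1)
  expect_equal(as.numeric(attr(out2, "weights")), c(0.5, 0.5))
})

test_that("link score is a symmetric sigmoid of the dot product", {
  expect_equal(score_link(rep(0, 4), rep(0, 4)), 0.5)
  e1 <- c(10, 0, 0, 0)
  expect_gt(score_link(e1, e1), 0.999)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(score_link(a, b), score_link(b, a))
  # monotone in the dot product
  zs <- seq(-3, 3, by = 0.5)
  s <- vapply(zs, function(t) score_link(c(t, 0), c(1, 0)), 1)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
})

test_that("analytic gradients match central finite differences", {
  sim <- simulate_tissue(tissue_params(n_cells = 6, extent = c(40, 40),
                                       n_genes = 10, n_types = 2,
                                       markers_per_type = 2,
                                       transcripts_per_cell_mean = 10,
                                       seed = 3))
  emb <- learned_embedding_init(sim$reference$genes, d = 4, seed = 5)
  cfg <- linkseg_config(list(model = list(d_latent = 8, n_heads = 2,
                                          n_layers = 2, dropout = 0)))
  g <- build_tile_graph(NULL, sim$transcripts, sim$nuclei, emb, cfg)
  cm <- cfg$model
  par <- linkseg:::with_seed(1, linkseg:::init_params(emb$d, ncol(g$x_c), cm,
                                                      emb$vectors))
  lab <- which(g$tc$label != "unlabeled")
  y <- as.numeric(g$tc$label[lab] == "positive")
  loss_fn <- function(pp) {
    fwd <- linkseg:::forward_graph(pp, g, cm, training = FALSE)
    linkseg:::bce_and_grads(fwd, g, lab, y)$loss
  }
  fwd <- linkseg:::forward_graph(par, g, cm, training = FALSE)
  bl <- linkseg:::bce_and_grads(fwd, g, lab, y)
  grads <- linkseg:::backward_graph(par, g, cm, fwd, bl$dz_t, bl$dz_c)
  eps <- 1e-5
  set.seed(99)
  for (nm in names(grads)) {
    idx <- sample(length(grads[[nm]]), min(3, length(grads[[nm]])))
    for (ii in idx) {
      p2 <- par; p2[[nm]][ii] <- p2[[nm]][ii] + eps
      p3 <- par; p3[[nm]][ii] <- p3[[nm]][ii] - eps
      num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})

test_that("forward pass is permutation-equivariant", {
  sim <- small_sim()
  emb <- reference_embedding(sim$reference, d = 2)
  cfg <- small_cfg()
  g <- build_tile_graph(NULL, sim$transcripts, sim$nuclei, emb, cfg)
  cm <- cfg$model
  par <- linkseg:::with_seed(2, linkseg:::init_params(emb$d, ncol(g$x_c), cm))
  fwd <- linkseg:::forward_graph(par, g, cm)
  # permute transcript node order
  n <- length(g$t_ids)
  perm <- linkseg:::with_seed(4, sample(n))
  g2 <- g
  g2$t_ids <- g$t_ids[perm]; g2$x_t <- g$x_t[perm, , drop = FALSE]
  g2$gene_index <- g$gene_index[perm]
  inv <- order(perm)
  g2$tt$i <- inv[g$tt$i]; g2$tt$j <- inv[g$tt$j]
  g2$tc$t <- inv[g$tc$t]
  fwd2 <- linkseg:::forward_graph(par, g2, cm)
  expect_equal(fwd2$z_t[inv, ], fwd$z_t, tolerance = 1e-10)
  expect_equal(fwd2$z_c, fwd$z_c, tolerance = 1e-10)
})

test_that("training descends, is seeded, and recovers noise-free labels", {
  p <- small_params(diffusion_fraction = 0, nucleus_free_fraction = 0)
  sim <- simulate_tissue(p)
  emb <- reference_embedding(sim$reference, d = 2)
  cfg <- small_cfg(model = list(epochs = 10))
  g <- build_tile_graph(NULL, sim$transcripts, sim$nuclei, emb, cfg)
  m1 <- train_model(list(g), cfg, emb)
  expect_lt(tail(m1$history$loss, 1), m1$history$loss[1])
  m2 <- train_model(list(g), cfg, emb)
  expect_identical(m1$history, m2$history)  # bitwise-identical loss curve
  expect_identical(m1$par, m2$par)
  # scores: every edge in (0,1); positives rank above negatives per transcript
  sc <- predict_scores(m1, g)
  expect_true(all(sc$score > 0 & sc$score < 1))
})

test_that("training errors without positive edges", {
  tt <- transcript_table(c("a", "b"), c("g1", "g1"), x = c(30, 31), y = c(30, 31))
  nuc <- boundary_set(list(N = unit_square()), "nucleus")
  emb <- learned_embedding_init("g1", d = 2, seed = 1)
  cfg <- small_cfg()
  g <- suppressWarnings(build_tile_graph(NULL, tt, nuc, emb, cfg))
  expect_error(train_model(list(g), cfg, emb), "no positive")
})

test_that("predict_scores is deterministic and complete", {
  sim <- small_sim()
  emb <- reference_embedding(sim$reference, d = 2)
  cfg <- small_cfg(model = list(epochs = 2))
  g <- build_tile_graph(NULL, sim$transcripts, sim$nuclei, emb, cfg)
  m <- train_model(list(g), cfg, emb)
  s1 <- predict_scores(m, g)
  s2 <- predict_scores(m, g)
  expect_identical(s1$score, s2$score)
  expect_equal(nrow(s1), nrow(g$tc))   # labeled and unlabeled all scored
  # empty graph -> empty mapping
  ge <- build_tile_graph(list(core = c(500, 500, 510, 510),
                              padded = c(500, 500, 510, 510)),
                         sim$transcripts, sim$nuclei, emb, cfg)
  expect_equal(nrow(predict_scores(m, ge)), 0)
})

test_that("model archives round-trip through JSON", {
  sim <- small_sim()
  emb <- reference_embedding(sim$reference, d = 2)
  cfg <- small_cfg(model = list(epochs = 2))
  g <- build_tile_graph(NULL, sim$transcripts, sim$nuclei, emb, cfg)
  m <- train_model(list(g), cfg, emb)
  p <- tempfile(fileext = ".json")
  write_model(m, p)
  m2 <- read_model(p)
  s1 <- predict_scores(m, g)
  s2 <- predict_scores(m2, g)
  expect_equal(s2$score, s1$score, tolerance = 1e-12)
})
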