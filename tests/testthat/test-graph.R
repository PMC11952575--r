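test_that("point-in-polygon follows the even-odd rule with inclusive boundary", {
  sq <- unit_square()
  expect_true(point_in_polygon(0.5, 0.5, sq))
  expect_false(point_in_polygon(2, 2, sq))
  # boundary and vertex count as inside
  expect_true(point_in_polygon(1, 0.5, sq))
  expect_true(point_in_polygon(0, 0, sq))
  # a concave polygon's notch is outside
  lshape <- cbind(x = c(0, 2, 2, 1, 1, 0), y = c(0, 0, 1, 1, 2, 2))
  expect_true(point_in_polygon(0.5, 1.5, lshape))
  expect_false(point_in_polygon(1.5, 1.5, lshape))
})

test_that("label_by_overlap maps interior points, leaves ambiguity unlabeled", {
  nuc <- boundary_set(list(
    A = unit_square(),
    B = cbind(x = c(0.5, 1.5, 1.5, 0.5), y = c(0.5, 0.5, 1.5, 1.5)),
    C = cbind(x = c(3, 4, 4, 3), y = c(3, 3, 4, 4))), "nucleus")
  tt <- transcript_table(c("p1", "p2", "p3", "p4"), rep("g", 4),
                         x = c(0.25, 0.75, 3.5, 9), y = c(0.25, 0.75, 3.5, 9))
  expect_message(ov <- label_by_overlap(tt, nuc), "multiple nuclei")
  expect_equal(unname(ov[c("p1", "p2", "p3", "p4")]),
               c("A", NA, "C", NA))
})

test_that("knn_tt_edges matches the brute-force oracle and is symmetric", {
  set.seed(7)
  n <- 400
  tt <- transcript_table(sprintf("t%04d", 1:n), rep("g", n),
                         x = runif(n, 0, 60), y = runif(n, 0, 60),
                         z = runif(n, 0, 4))
  for (prm in list(list(k = 5, md = 5, zs = 1), list(k = 3, md = 2, zs = 0.5))) {
    e <- knn_tt_edges(tt, k = prm$k, max_dist = prm$md, z_scale = prm$zs)
    # symmetric and no self edges
    expect_true(all(e$i != e$j))
    key <- paste(e$i, e$j); rkey <- paste(e$j, e$i)
    expect_setequal(key, rkey)
    # every oracle edge present (kNN union is symmetrized, so oracle ⊆ edges)
    o <- brute_knn(tt$x, tt$y, tt$z, prm$zs, prm$k, prm$md)
    expect_true(all(paste(o$i, o$j) %in% key))
    # and every edge is an oracle edge in at least one direction
    okey <- paste(o$i, o$j)
    expect_true(all(key %in% okey | rkey %in% okey))
  }
})

test_that("knn edge cases: complete graph, zero radius, collinear ties", {
  tt <- transcript_table(c("a", "b", "c", "d"), rep("g", 4),
                         x = c(0, 1, 3, 7), y = rep(0, 4))
  e <- knn_tt_edges(tt, k = 10, max_dist = Inf)
  expect_equal(nrow(e), 4 * 3)  # complete graph, both directions
  expect_equal(nrow(knn_tt_edges(tt, k = 2, max_dist = 0)), 0)
  # equidistant tie breaks toward the smaller transcript_id: the middle point
  # of three collinear equally spaced points must pick the earlier neighbour
  # (checked on the directed selection, before symmetrization)
  e2 <- linkseg:::cpp_grid_knn(c(-1, 0, 1), c(0, 0, 0), numeric(3),
                               1, 1L, Inf)
  expect_equal(e2$j[e2$i == 2], 1)
})

test_that("candidate edges label containment and nearby nuclei", {
  nuc <- boundary_set(list(
    A = unit_square(),
    B = cbind(x = c(3, 4, 4, 3), y = c(0, 0, 1, 1))), "nucleus")
  tt <- transcript_table(c("in_a", "stray"), c("g", "g"),
                         x = c(0.5, 0.6), y = c(0.5, 1.8))
  ov <- label_by_overlap(tt, nuc)
  e <- candidate_tc_edges(tt, nuc, ov, k_cells = 4, max_dist = 15)
  ea <- e[e$t == 1, ]
  expect_equal(ea$label[ea$c == 1], "positive")
  expect_equal(ea$label[ea$c == 2], "negative")
  es <- e[e$t == 2, ]
  expect_true(all(es$label == "unlabeled"))
  # k_cells = 1: single positive edge for the contained transcript
  e1 <- candidate_tc_edges(tt[1, ], nuc, ov, k_cells = 1, max_dist = 15)
  expect_equal(nrow(e1), 1)
  expect_equal(e1$label, "positive")
})

test_that("every positive edge's transcript verifies inside its polygon", {
  sim <- small_sim()
  ov <- label_by_overlap(sim$transcripts, sim$nuclei)
  e <- suppressWarnings(candidate_tc_edges(sim$transcripts, sim$nuclei, ov))
  pos <- e[e$label == "positive", ]
  ids <- names(sim$nuclei$polygons)
  ok <- vapply(seq_len(nrow(pos)), function(r) {
    point_in_polygon(sim$transcripts$x[pos$t[r]], sim$transcripts$y[pos$t[r]],
                     sim$nuclei$polygons[[ids[pos$c[r]]]])
  }, logical(1))
  expect_true(all(ok))
  # at most one positive edge per transcript
  expect_false(anyDuplicated(pos$t) > 0)
})

test_that("cell geometry features match closed forms", {
  f <- cell_geom_features(unit_square(), n_inside = 0)
  expect_equal(unname(f["area"]), 1)
  expect_equal(unname(f["perimeter"]), 4)
  expect_equal(unname(f["circularity"]), pi / 4, tolerance = 1e-12)
  expect_equal(unname(f["convexity"]), 1)
  expect_equal(unname(f["elongation"]), 1, tolerance = 1e-9)

  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circle <- cbind(x = cos(th), y = sin(th))
  expect_equal(unname(cell_geom_features(circle)["circularity"]), 1,
               tolerance = 1e-3)

  lshape <- cbind(x = c(0, 2, 2, 1, 1, 0), y = c(0, 0, 1, 1, 2, 2))
  expect_lt(cell_geom_features(lshape)["convexity"], 1)

  stretched <- cbind(x = c(0, 4, 4, 0), y = c(0, 0, 1, 1))
  expect_lt(cell_geom_features(stretched)["elongation"], 0.5)

  expect_error(cell_geom_features(cbind(x = c(0, 1), y = c(0, 1))), "degenerate")
})

test_that("tile plan partitions transcripts; margins pad cores", {
  sim <- small_sim()
  tt <- sim$transcripts
  # single tile when target >= n
  p1 <- plan_tiles(tt, tile_target = nrow(tt) + 1, margin = 5)
  expect_length(p1$tiles, 1)
  # margin 0: padded equals core
  p0 <- plan_tiles(tt, tile_target = nrow(tt), margin = 0)
  expect_equal(p0$tiles[[1]]$core, p0$tiles[[1]]$padded)
  # 4 tiles partition the transcripts exactly
  p4 <- plan_tiles(tt, tile_target = ceiling(nrow(tt) / 4), margin = 10)
  expect_length(p4$tiles, 4)
  idx <- linkseg:::tile_core_index(p4, tt$x, tt$y)
  expect_true(all(idx >= 1))
  sizes <- table(idx)
  expect_equal(sum(sizes), nrow(tt))
  expect_true(all(sizes <= ceiling(nrow(tt) / 4)))
})

test_that("four separated clusters yield one core tile each", {
  xs <- c(runif(25, 0, 10), runif(25, 90, 100), runif(25, 0, 10), runif(25, 90, 100))
  ys <- c(runif(50, 0, 10), runif(50, 90, 100))
  tt <- transcript_table(sprintf("t%03d", 1:100), rep("g", 100), xs, ys)
  pl <- plan_tiles(tt, tile_target = 25, margin = 2)
  expect_length(pl$tiles, 4)
  idx <- linkseg:::tile_core_index(pl, tt$x, tt$y)
  expect_equal(unname(as.numeric(table(idx))), rep(25, 4))
})

test_that("tile graph is canonical under input permutation", {
  sim <- small_sim()
  emb <- reference_embedding(sim$reference, d = 2)
  cfg <- small_cfg()
  g1 <- build_tile_graph(NULL, sim$transcripts, sim$nuclei, emb, cfg)
  perm <- sim$transcripts[sample(nrow(sim$transcripts)), ]
  perm <- perm[order(perm$transcript_id), ]  # constructor contract: id-sorted
  class(perm) <- class(sim$transcripts)
  g2 <- build_tile_graph(NULL, perm, sim$nuclei, emb, cfg)
  expect_identical(g1$t_ids, g2$t_ids)
  expect_equal(g1$tt, g2$tt)
  expect_equal(g1$tc, g2$tc)
  expect_equal(g1$x_t, g2$x_t)
})

test_that("tile graph composes labels, features and flags", {
  nuc <- boundary_set(list(N = 10 * unit_square()), "nucleus")
  tt <- transcript_table(c("a", "b", "c"), c("g1", "g2", "g1"),
                         x = c(2, 5, 8), y = c(2, 5, 8))
  emb <- learned_embedding_init(c("g1", "g2"), d = 4, seed = 1)
  cfg <- small_cfg()
  g <- build_tile_graph(NULL, tt, nuc, emb, cfg)
  expect_equal(sum(g$tc$label == "positive"), 3)
  expect_true(all(g$core))
  expect_equal(g$x_t, unname(emb$vectors[c("g1", "g2", "g1"), ]),
               ignore_attr = TRUE)
  # unknown gene errors by default, zero vector when configured
  tt2 <- transcript_table("q", "gX", 1, 1)
  expect_error(build_tile_graph(NULL, tt2, nuc, emb, cfg), "gX")
  cfg2 <- small_cfg(graph = list(missing_gene = "zero"))
  g2 <- build_tile_graph(NULL, tt2, nuc, emb, cfg2)
  expect_equal(unname(g2$x_t[1, ]), rep(0, 4))
  # empty tile is valid
  g3 <- build_tile_graph(list(core = c(100, 100, 110, 110),
                              padded = c(100, 100, 110, 110)),
                         tt, nuc, emb, cfg)
  expect_length(g3$t_ids, 0)
  expect_equal(nrow(g3$tt), 0)
})
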