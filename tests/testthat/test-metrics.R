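test_that("PMP counts own-type marker share, excluding markerless cells", {
  counts <- matrix(c(3, 1, 0,
                     4, 0, 0,
                     0, 0, 5), 3, 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2", "c3"), c("mA", "mB", "other")))
  markers <- list(TA = "mA", TB = "mB")
  types <- c(c1 = "TA", c2 = "TA", c3 = "TB")
  pm <- positive_marker_purity(counts, types, markers)
  expect_equal(unname(pm["c1"]), 0.75)  # 3 own / (3 + 1) marker counts
  expect_equal(unname(pm["c2"]), 1)
  expect_false("c3" %in% names(pm))     # no marker transcripts at all
  expect_equal(attr(pm, "excluded"), "c3")
  expect_error(positive_marker_purity(counts, types[-1], markers), "missing")
})

test_that("exclusive pair selection uses the codetection rate", {
  counts <- rbind(c(1, 0, 1, 0),
                  c(0, 1, 1, 0),
                  c(1, 0, 0, 1),
                  c(0, 1, 0, 1))
  colnames(counts) <- c("g1", "g2", "g3", "g4")
  rownames(counts) <- paste0("c", 1:4)
  pr <- select_exclusive_pairs(counts, codetect_max = 0.01)
  expect_true(all(c("g1|g2") %in% paste(pr$gene1, pr$gene2, sep = "|")))
  # g1,g3 codetected in c1: rate = 1 / #union(c1,c2,c3) = 1/3 >= 0.01 -> excluded
  expect_false("g1|g3" %in% paste(pr$gene1, pr$gene2, sep = "|"))
  pr2 <- select_exclusive_pairs(counts, codetect_max = 0.5)
  expect_true("g1|g3" %in% paste(pr2$gene1, pr2$gene2, sep = "|"))
  # always co-expressed genes are never selected
  cc <- cbind(g5 = c(1, 1), g6 = c(2, 3))
  rownames(cc) <- c("x", "y")
  expect_equal(nrow(select_exclusive_pairs(cc, 0.5)), 0)
})

test_that("MECR enumerates codetection among expressing cells", {
  counts <- rbind(A = c(2, 0), B = c(0, 1), C = c(1, 3))
  colnames(counts) <- c("g1", "g2")
  pairs <- data.frame(gene1 = "g1", gene2 = "g2")
  expect_equal(unname(mecr(counts, pairs)), 1 / 3)
  # no expressing cell -> undefined
  z <- counts * 0
  expect_true(is.na(mecr(z, pairs)))
  # all expressing cells co-express -> 1
  co <- rbind(A = c(1, 2), B = c(3, 1))
  colnames(co) <- c("g1", "g2")
  expect_equal(unname(mecr(co, pairs)), 1)
  # invariance to adding cells expressing neither gene
  bigger <- rbind(counts, D = c(0, 0), E = c(0, 0))
  expect_equal(mecr(bigger, pairs), mecr(counts, pairs))
})

test_that("summary stats respect the min-counts filter", {
  tt <- transcript_table(sprintf("t%02d", 1:63), rep("g", 63),
                         x = 1:63, y = 1:63)
  asg <- c(rep("c1", 10), rep("c2", 20), rep("c3", 30), rep("c4", 3))
  res <- segmentation_result(tt$transcript_id, asg, rep(0.9, 63),
                             rep("model", 63))
  st <- summary_stats(res, tt, min_counts = 5)
  expect_equal(st$n_cells, 3)                 # c4 below the filter
  expect_equal(st$median_counts_per_cell, 20)
  expect_equal(st$n_fragments, 0)
  # areas only when polygons provided
  expect_null(st$median_area)
  b <- boundary_set(list(c1 = unit_square(), c2 = 2 * unit_square(),
                         c3 = 3 * unit_square()), "cell")
  st2 <- summary_stats(res, tt, boundaries = b, min_counts = 5)
  expect_equal(st2$median_area, 4)
})

test_that("assignment PRF matches a hand-built confusion table", {
  # 2 true cells of 10 transcripts each; predictions swap half of cell B
  tid <- sprintf("t%02d", 1:20)
  truth <- list(assignment = setNames(c(rep("A", 10), rep("B", 10)), tid))
  pred <- c(rep("A", 10), rep("A", 5), rep("B", 5))
  res <- segmentation_result(tid, pred, rep(0.9, 20), rep("model", 20))
  prf <- assignment_prf(res, truth)
  # matching: A->A (15 overlap? A gets 15 preds, 10 from true A) ; B->B
  # TP = 10 (true A in pred A) + 5 (true B in pred B) = 15
  expect_equal(prf$precision, 15 / 20)
  expect_equal(prf$recall, 15 / 20)
  expect_equal(prf$f1, 0.75)

  perfect <- segmentation_result(tid, truth$assignment[tid], rep(1, 20),
                                 rep("model", 20))
  p2 <- assignment_prf(perfect, truth)
  expect_equal(c(p2$precision, p2$recall, p2$f1), c(1, 1, 1))

  none <- segmentation_result(tid, rep("UNASSIGNED", 20), rep(NA_real_, 20),
                              rep("none", 20))
  p3 <- assignment_prf(none, truth)
  expect_equal(p3$recall, 0)
  expect_equal(p3$precision, 0)
  expect_true(isTRUE(attr(p3, "precision_undefined")))
})

test_that("greedy matching equals exhaustive optimal matching on small instances", {
  # brute-force oracle: maximize total overlap over all injections pred->true
  optimal_tp <- function(tab) {
    preds <- rownames(tab); trues <- colnames(tab)
    k <- min(length(preds), length(trues))
    best <- 0
    perm_all <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perm_all(v[-i]), function(p) c(v[i], p))))
    for (sub in utils::combn(length(preds), k, simplify = FALSE)) {
      for (pt in perm_all(seq_along(trues))) {
        sel <- pt[seq_len(k)]
        tp <- sum(tab[cbind(sub, sel)])
        if (tp > best) best <- tp
      }
    }
    best
  }
  set.seed(21)
  for (rep_i in 1:5) {
    n_true <- sample(2:4, 1); n_pred <- sample(2:4, 1)
    # diagonally dominant tables, as segmentation overlaps are in practice
    tab <- matrix(rpois(n_pred * n_true, 1), n_pred, n_true)
    for (i in seq_len(min(n_pred, n_true))) tab[i, i] <- tab[i, i] + 10
    dimnames(tab) <- list(paste0("p", seq_len(n_pred)),
                          paste0("t", seq_len(n_true)))
    m <- linkseg:::greedy_match(as.table(tab))
    tp_greedy <- sum(tab[cbind(match(names(m), rownames(tab)),
                               match(m, colnames(tab)))])
    expect_equal(tp_greedy, optimal_tp(tab))
  }
})

test_that("ground-truth segmentation yields PMP 1 and MECR 0 on exclusive pairs", {
  sim <- small_sim()
  truth_res <- segmentation_result(
    sim$transcripts$transcript_id,
    sim$truth$assignment[sim$transcripts$transcript_id],
    rep(1, nrow(sim$transcripts)), rep("model", nrow(sim$transcripts)))
  counts <- count_matrix(truth_res, sim$transcripts, min_counts = 5)
  pm <- positive_marker_purity(counts, sim$truth$type, sim$reference$markers)
  expect_true(all(pm == 1))
  pairs <- select_exclusive_pairs(t(sim$reference$mean_expr), 0.01)
  expect_gt(nrow(pairs), 0)
  me <- mecr(counts, pairs)
  expect_true(all(me[!is.na(me)] == 0))
})

test_that("baseline nearest-nucleus recovers noise-free nuclear truth", {
  p <- small_params(diffusion_fraction = 0, nucleus_free_fraction = 0)
  sim <- simulate_tissue(p)
  res <- baseline_nearest_nucleus(sim$transcripts, sim$nuclei)
  ov <- label_by_overlap(sim$transcripts, sim$nuclei)
  nuc <- names(ov)[!is.na(ov)]
  asg <- setNames(res$assignment, res$transcript_id)
  expect_true(all(asg[nuc] == sim$truth$assignment[nuc]))
})
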