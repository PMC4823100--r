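test_that("z-scoring uses the sample SD and zeroes constant genes", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(m) <- c("s1", "s2", "s3")
  expect_warning(z <- zscore_panel(m), "constant")
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))

  set.seed(1)
  big <- matrix(rnorm(200), 10, 20,
                dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:20)))
  zb <- zscore_panel(big)
  expect_equal(unname(rowMeans(zb)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(zb, 1, sd)), rep(1, 10), tolerance = 1e-12)
})

test_that("equal-frequency discretization handles ties and boundaries", {
  x <- c(10, 20, 30, 40, 50, 60, 70, 80)
  cuts <- equal_freq_cuts(x, 4)
  b <- apply_bins(x, cuts)
  expect_equal(as.integer(table(b)), rep(2L, 4))

  ties <- rep(7, 10)
  expect_equal(unique(apply_bins(ties, equal_freq_cuts(ties, 4))), 1L)

  expect_equal(apply_bins(-100, cuts), 1L)   # below all cut-points
  expect_equal(apply_bins(1e6, cuts), 4L)
})

test_that("chi-squared merit matches contingency-table arithmetic", {
  # constant gene: one bin, chi-squared 0 in every fold
  m <- rbind(flat = rep(1, 20),
             perfect = rep(c(0, 10), each = 10))
  colnames(m) <- sprintf("s%02d", 1:20)
  pan <- mk_panel(m, rep(c("A", "B"), each = 10))
  mt <- chi2_merit(pan, folds = 10, seed = 1)
  expect_equal(mt$merit[mt$gene_id == "flat"], 0)
  # perfectly separating binary feature: per-fold chi-squared = N_train
  expect_equal(mt$merit[mt$gene_id == "perfect"], 18)
  expect_setequal(mt$rank, 1:2)

  # 3-class fixture: per-fold statistic equals a hand computation
  set.seed(4)
  m3 <- matrix(rnorm(3 * 18), 3, 18,
               dimnames = list(c("x", "y", "z"), sprintf("s%02d", 1:18)))
  lab <- rep(c("A", "B", "C"), each = 6)
  pan3 <- mk_panel(m3, lab)
  folds <- 3
  mt3 <- chi2_merit(pan3, folds = folds, seed = 2)
  fold <- aerlnc:::stratified_folds(factor(stats::setNames(lab, colnames(m3))),
                                    folds, 2)
  hand <- sapply(rownames(m3), function(g) {
    mean(sapply(seq_len(folds), function(f) {
      tr <- fold != f
      x <- m3[g, tr]
      b <- apply_bins(x, equal_freq_cuts(x, 4))
      O <- table(b, lab[tr])
      E <- outer(rowSums(O), colSums(O)) / sum(O)
      sum(((O - E)^2 / E)[E > 0])
    }))
  })
  expect_equal(stats::setNames(mt3$merit, mt3$gene_id), hand)
})

test_that("merit is invariant to gene order", {
  set.seed(9)
  m <- matrix(10^rnorm(8 * 20), 8, 20,
              dimnames = list(sprintf("g%d", 1:8), sprintf("s%02d", 1:20)))
  lab <- rep(c("A", "B"), each = 10)
  a <- chi2_merit(mk_panel(m, lab), folds = 5, seed = 3)
  b <- chi2_merit(mk_panel(m[sample(8), ], lab), folds = 5, seed = 3)
  expect_equal(stats::setNames(a$merit, a$gene_id)[sort(a$gene_id)],
               stats::setNames(b$merit, b$gene_id)[sort(b$gene_id)])
})

test_that("signature selection uses a strict threshold and merit order", {
  mt <- data.frame(gene_id = c("a", "b", "c"), merit = c(20, 15, 15.01),
                   rank = c(1L, 3L, 2L))
  class(mt) <- c("merit_table", "data.frame")
  sig <- select_signature(mt, 15)
  expect_equal(as.character(sig), c("a", "c"))
  expect_equal(attr(sig, "merit"), c(20, 15.01))
  none <- select_signature(mt, 25)
  expect_length(none, 0)
})

test_that("label noise caps cross-validated accuracy below 100%", {
  set.seed(6)
  m <- matrix(10^rnorm(5 * 12), 5, 12,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:12)))
  m[, 2] <- m[, 1]  # identical samples ...
  lab <- rep(c("A", "B"), 6)  # ... with different labels
  res <- crossval_classify(mk_panel(m, lab), folds = 2, seed = 1)
  expect_lt(res$accuracy, 1)
  bad <- mk_panel(m, lab)
  bad$values[1, 1] <- NA
  expect_error(crossval_classify(bad, folds = 2, seed = 1), "non-finite")
})

test_that("Ward clustering separates distant clouds and merges duplicates first", {
  set.seed(7)
  a <- matrix(rnorm(2 * 8, 0, 0.1), 2)
  b <- matrix(rnorm(2 * 8, 50, 0.1), 2)
  m <- cbind(a, b)
  dimnames(m) <- list(c("g1", "g2"), sprintf("s%02d", 1:16))
  pan <- mk_panel(abs(m) + 1, rep(c("low", "high"), each = 8))
  cl <- hierarchical_cluster(pan, k = 2, log_transform = FALSE)
  expect_equal(cl$purity, 1)

  dup <- m; dup[, 2] <- dup[, 1]
  pd <- mk_panel(abs(dup) + 1, rep(c("low", "high"), each = 8))
  tr <- hierarchical_cluster(pd, k = 2, log_transform = FALSE)$tree
  expect_equal(tr$height[1], 0)
  expect_setequal(abs(tr$merge[1, ]), c(1, 2))
})

test_that("a 6-point Ward dendrogram matches manual Lance-Williams merges", {
  set.seed(3)
  P <- matrix(rnorm(12), 6, 2)
  pan <- mk_panel(t(P), rep(c("u", "v"), 3))
  hc <- hierarchical_cluster(pan, k = 2, log_transform = FALSE)$tree
  oracle <- ward_lw_heights(P)
  expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
  merged_sets <- lapply(seq_len(5), function(s) {
    collect <- function(node)
      if (node < 0) -node else unlist(lapply(hc$merge[node, ], collect))
    sort(collect(s))
  })
  expect_identical(merged_sets, oracle$merges)
})

test_that("PCA explained variance and scores match eigendecomposition", {
  # collinear two-gene panel: PC1 carries all variance
  x <- c(1, 3, 7, 2, 9, 4)
  m <- rbind(g1 = x, g2 = 2 * x)
  colnames(m) <- sprintf("s%d", 1:6)
  pc <- pca_panel(mk_panel(m, rep(c("A", "B"), 3)))
  expect_equal(pc$explained_variance[1], 1)
  expect_equal(sum(pc$explained_variance), 1)

  M <- matrix(c(2, 4, 1, 7, 5, 3, 8, 2, 6, 1, 9, 4), nrow = 4)
  rownames(M) <- sprintf("s%d", 1:4)
  pan <- mk_panel(t(M), rep("A", 4))
  pc2 <- pca_panel(pan, log_transform = FALSE)
  eg <- eigen(stats::cov(M))
  V <- eg$vectors
  for (j in 1:ncol(V)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  S <- sweep(M, 2, colMeans(M)) %*% V
  expect_equal(unname(pc2$scores[, 1:3]), unname(S[, 1:3]), tolerance = 1e-9)
  expect_equal(pc2$explained_variance[1:3],
               (eg$values / sum(eg$values))[1:3], tolerance = 1e-9)
})

test_that("planted signature genes dominate merit stochastically", {
  cfg <- panel_cfg(12, effect = 3)
  gp <- gen_panel(gen_annotation(cfg), cfg)
  mt <- chi2_merit(gp$panel, seed = 12)
  planted <- mt$merit[mt$gene_id %in% gp$truth$gene_id]
  rest <- mt$merit[!mt$gene_id %in% gp$truth$gene_id]
  expect_lt(stats::wilcox.test(planted, rest,
                               alternative = "greater")$p.value, 1e-6)
})

test_that("the signature clusters better than random gene sets", {
  wins <- 0L
  for (s in 1:20) {
    cfg <- panel_cfg(s + 40, effect = 3)
    gp <- gen_panel(gen_annotation(cfg), cfg)
    p_sig <- hierarchical_cluster(gp$panel, genes = gp$truth$gene_id,
                                  k = 4)$purity
    set.seed(s)
    rnd <- sample(rownames(gp$panel$values), nrow(gp$truth))
    p_rnd <- hierarchical_cluster(gp$panel, genes = rnd, k = 4)$purity
    wins <- wins + (p_sig >= p_rnd)
  }
  expect_gte(wins, 17)
})
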