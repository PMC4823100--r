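test_that("size factors recover the proportional-column closed form", {
  set.seed(1)
  c1 <- rpois(50, 200) + 1L
  m <- cbind(s1 = c1, s2 = 2L * c1)
  rownames(m) <- sprintf("g%02d", 1:50)
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
})

test_that("identical condition columns give a flat null", {
  set.seed(2)
  X <- matrix(rnbinom(300 * 3, mu = 100, size = 10), 300)
  m <- cbind(X, X)
  rownames(m) <- sprintf("g%03d", 1:300)
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  cm <- count_matrix(m, stats::setNames(rep(c("A", "B"), each = 3),
                                        colnames(m)))
  res <- de_test(cm)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$log2_fc == 0))
  expect_true(all(res$adj_p >= res$p_value))
})

test_that("a strongly planted gene is detected almost surely", {
  hits <- sapply(1:100, function(s) {
    set.seed(s)
    mu <- exp(rnorm(500, log(100), 1))
    cnt <- matrix(rnbinom(500 * 6, mu = mu, size = 20), 500)
    cnt[1, 4:6] <- rnbinom(3, mu = 500 * 2^4, size = 20)
    cnt[1, 1:3] <- rnbinom(3, mu = 500, size = 20)
    rownames(cnt) <- sprintf("g%03d", 1:500)
    colnames(cnt) <- c(paste0("a", 1:3), paste0("b", 1:3))
    cm <- count_matrix(cnt, stats::setNames(rep(c("A", "B"), each = 3),
                                            colnames(cnt)))
    de_test(cm)$adj_p[1] < 0.05
  })
  expect_gte(sum(hits), 95)
})

test_that("consensus requires support and sign concordance", {
  mk <- function(ids, p, lfc) data.frame(
    gene_id = ids, base_mean_A = 1, base_mean_B = 1, log2_fc = lfc,
    p_value = p, adj_p = p, method_id = "m", stringsAsFactors = FALSE)
  ids <- c("g1", "g2", "g3", "g4")
  t1 <- mk(ids, c(0.001, 0.001, 0.2, 0.001), c(1, 1, 1, -2))
  t2 <- mk(ids, c(0.002, 0.3, 0.001, 0.004), c(2, 1, 1, -1))
  t3 <- mk(ids, c(0.010, 0.2, 0.001, 0.003), c(1.5, 1, -1, -1))

  one <- consensus_de(list(t1), alpha = 0.05)
  expect_setequal(one$gene_id, c("g1", "g2", "g4"))

  # g3 significant in 2/3 but with opposite signs: excluded
  res <- consensus_de(list(t1, t2, t3), alpha = 0.05, min_methods = 2)
  expect_setequal(res$gene_id, c("g1", "g4"))
  expect_equal(res$direction[res$gene_id == "g4"], "down")

  # brute-force set algebra over all 3 tables at min_methods = 3
  sig <- function(t) t$gene_id[t$adj_p < 0.05]
  expected <- Reduce(intersect, lapply(list(t1, t2, t3), sig))
  res3 <- consensus_de(list(t1, t2, t3), alpha = 0.05)
  expect_setequal(res3$gene_id, expected)

  # table order is irrelevant
  perm <- consensus_de(list(t3, t1, t2), alpha = 0.05, min_methods = 2)
  expect_setequal(perm$gene_id, res$gene_id)
  expect_error(consensus_de(list()), "empty")
})

test_that("lncRNA filters match hand enumeration and are idempotent", {
  ann <- tiny_annotation()
  res <- filter_lncrnas(ann$gene_id, ann, blacklist = "SEMA3B")
  survivors <- res$gene_id[res$keep]
  expect_setequal(survivors, c("T01", "T02", "T06", "T09", "T10"))
  expect_equal(res$filter_flags[res$gene_id == "T05"], "biotype")
  expect_equal(res$filter_flags[res$gene_id == "T07"], "length")
  expect_equal(res$filter_flags[res$gene_id == "T03"], "blacklist")
  expect_equal(res$filter_flags[res$gene_id == "T08"], "biotype")

  again <- filter_lncrnas(survivors, ann, blacklist = "SEMA3B")
  expect_true(all(again$keep))
  expect_error(filter_lncrnas("missing", ann), "missing")
})

test_that("RPKM follows its closed form and is homogeneous", {
  expect_equal(compute_rpkm(1000, 2, 10), 50)
  expect_equal(compute_rpkm(0, 2, 10), 0)
  expect_equal(compute_rpkm(2 * 123, 1.7, 8), 2 * compute_rpkm(123, 1.7, 8))
})

test_that("time-point combination uses Fisher's method", {
  mk <- function(p, lfc) data.frame(gene_id = "g1", p_value = p,
                                    log2_fc = lfc)
  flat <- combine_timepoints(list(mk(1, 0), mk(1, 0)))
  expect_equal(flat$combined_p, 1)
  expect_false(flat$de)

  res <- combine_timepoints(list(mk(0.05, 2), mk(0.05, 4)))
  X <- -2 * (log(0.05) + log(0.05))
  closed_form <- exp(-X / 2) * (1 + X / 2)  # chi-squared(4) survival
  expect_equal(res$combined_p, closed_form, tolerance = 1e-6)
  expect_equal(res$log2_fc, 3)
  expect_false(res$de)  # strict threshold: min p = alpha is not DE
  called <- combine_timepoints(list(mk(0.04, 2), mk(0.5, 4)))
  expect_true(called$de)

  expect_warning(z <- combine_timepoints(list(mk(0, 1), mk(0.5, 1))),
                 "clamped")
  expect_gt(z$combined_p, 0)
})

test_that("the consensus catalog carries filters and RPKM", {
  cfg <- sim_config(seed = 21, n_genes = 300, lfc = 3)
  ann <- gen_annotation(cfg)
  sim <- gen_counts(ann, cfg)
  tabs <- lapply(c("max", "common"), function(mo)
    de_test(sim$counts, dispersion_mode = mo, method_id = mo))
  cat <- build_catalog(tabs, ann, sim$counts)
  expect_gt(nrow(cat), 0)
  expect_true(all(cat$direction %in% c("down", "up")))
  expect_true(all(cat$rpkm_A >= 0))
  in_truth <- mean(cat$gene_id %in% sim$truth$gene_id)
  expect_gt(in_truth, 0.9)
})
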