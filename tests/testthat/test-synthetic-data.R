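test_that("generators are pure functions of the seed", {
  cfg <- sim_config(seed = 4, n_genes = 80)
  a1 <- gen_annotation(cfg); a2 <- gen_annotation(cfg)
  expect_identical(a1, a2)
  c1 <- gen_counts(a1, cfg); c2 <- gen_counts(a1, cfg)
  expect_identical(c1$counts$counts, c2$counts$counts)
  expect_identical(c1$truth, c2$truth)
  regions <- data.frame(region_id = "r1", chrom = "chr1", pos = 5e4,
                        strand = "+")
  t1 <- gen_chip_tags(regions, "promoter", 500L, seed = 9)
  t2 <- gen_chip_tags(regions, "promoter", 500L, seed = 9)
  expect_identical(t1, t2)
})

test_that("annotation respects biotype fractions and spacing limits", {
  cfg <- sim_config(seed = 2, n_genes = 100,
                    biotype_fractions = c(lincRNA = 0.5, antisense = 0.5))
  ann <- gen_annotation(cfg)
  expect_equal(as.integer(table(ann$biotype)[c("antisense", "lincRNA")]),
               c(50L, 50L))
  expect_true(all(diff(sort(ann$tss[ann$chrom == "chr1"])) >= 1000))
  # pigeonhole: 1,000 genes cannot sit at >= 1 kb spacing on 1 Mb
  expect_error(gen_annotation(sim_config(seed = 1, n_genes = 1000,
                                         n_chromosomes = 1,
                                         chrom_length = 1e6)),
               "too short")
})

test_that("binding sites land at TSSs when the proximity scale is zero", {
  cfg <- sim_config(seed = 6, n_genes = 50, proximity_scale = 0,
                    n_background_sites = 0L)
  ann <- gen_annotation(cfg)
  targets <- ann$gene_id[1:10]
  sites <- gen_binding_sites(ann, targets, cfg)
  expect_equal(nrow(sites), 10)
  expect_setequal(sites$summit, ann$tss[match(targets, ann$gene_id)])
  expect_error(gen_binding_sites(ann, "nope", cfg), "nope")
})

test_that("planted site offsets average to the proximity scale", {
  cfg <- sim_config(seed = 8, n_genes = 20, n_chromosomes = 1,
                    chrom_length = 1e8, proximity_scale = 1e4,
                    n_background_sites = 0L)
  ann <- gen_annotation(cfg)
  # plant 10,000 sites on one gene so every |summit - TSS| is one draw of
  # the exponential offset; the empirical mean obeys the law of large
  # numbers (relative SE ~ 1%)
  sites <- gen_binding_sites(ann, rep(ann$gene_id[1L], 10000L), cfg)
  offs <- abs(sites$summit - ann$tss[1L])
  expect_lt(abs(mean(offs) - 1e4) / 1e4, 0.05)
})

test_that("count simulation plants the requested fold changes", {
  cfg0 <- sim_config(seed = 3, n_genes = 60, lfc = 0)
  ann <- gen_annotation(cfg0)
  expect_equal(nrow(gen_counts(ann, cfg0)$truth), 0)

  cfg <- sim_config(seed = 3, n_genes = 200, lfc = 4, n_reps = 50L,
                    dispersion = 0.05, lib_size = 1e5)
  ann <- gen_annotation(cfg)
  sim <- gen_counts(ann, cfg)
  expect_gt(nrow(sim$truth), 0)
  cm <- sim$counts
  g <- sim$truth$gene_id[which.max(rowMeans(
    cm$counts[sim$truth$gene_id, cm$condition == "ctrl", drop = FALSE]))]
  obs_lfc <- log2(mean(cm$counts[g, cm$condition == "kd"]) /
                  mean(cm$counts[g, cm$condition == "ctrl"]))
  expect_lt(abs(abs(obs_lfc) - 4), 0.3)
  expect_error(gen_counts(ann, sim_config(seed = 1, n_reps = 1L)),
               ">= 2")
})

test_that("panel design is honored and the luminal contrast is strong", {
  cfg <- panel_cfg(1, effect = 3)
  gp <- gen_panel(gen_annotation(cfg), cfg)
  expect_equal(ncol(gp$panel$values), 55)
  expect_equal(as.integer(table(gp$panel$subtype)[c("basal", "claudin_low",
                                                    "luminal",
                                                    "normal_like")]),
               c(14L, 14L, 14L, 13L))
  expect_equal(nrow(gp$panel$values), 130)
  expect_equal(nrow(gp$truth), 30)
  # with effect 3 sd, a two-sample t on each signature gene (luminal 14
  # vs rest 41) rejects at alpha = 0.001 nearly always
  rej <- sapply(1:100, function(s) {
    cfg <- panel_cfg(s, effect = 3)
    gp <- gen_panel(gen_annotation(cfg), cfg)
    g <- gp$truth$gene_id[1L]
    x <- log10(gp$panel$values[g, ])
    lum <- gp$panel$subtype == "luminal"
    stats::t.test(x[lum], x[!lum])$p.value < 0.001
  })
  expect_gte(sum(rej), 99)
  expect_error(gen_panel(gen_annotation(cfg),
                         panel_cfg(1, effect = 3) |>
                           (\(x) { x$signature_size <- 500L; x })()),
               "signature_size")
})

test_that("null panels show no luminal shift in expectation", {
  cfg <- panel_cfg(2, effect = 0)
  gp <- gen_panel(gen_annotation(cfg), cfg)
  g <- gp$truth$gene_id[1L]
  x <- log10(gp$panel$values[g, ])
  lum <- gp$panel$subtype == "luminal"
  expect_lt(abs(mean(x[lum]) - mean(x[!lum])), 0.5)
})

test_that("chip tag tracks carry the configured mark ratio", {
  regions <- data.frame(region_id = sprintf("r%d", 1:5), chrom = "chr1",
                        pos = seq(1e5, 5e5, length.out = 5), strand = "+")
  empty <- gen_chip_tags(regions, "promoter", 0L, seed = 1)
  expect_equal(nrow(empty$markA), 0)
  expect_equal(nrow(empty$markB), 0)

  tags <- gen_chip_tags(regions, "promoter", 10000L, seed = 2)
  sa <- bin_signal(tags$markA, regions)
  sb <- bin_signal(tags$markB, regions)
  ratio <- mean(sa) / mean(sb)
  expect_gte(ratio, 3); expect_lte(ratio, 5)
})

test_that("qRT-PCR runs reproduce the configured sizes and calibrate", {
  cfg <- sim_config(seed = 1)
  ct <- gen_ct(cfg)$series
  expect_equal(as.integer(table(ct$run_id)), c(22L, 20L))
  expect_equal(sum(ct$group == "ER_pos"), 26)
  expect_equal(sum(ct$group == "ER_neg"), 16)
  expect_true(all(ct$target_ct > 0 & ct$target_ct <= 45))

  # with no batch effect the two runs are exchangeable: KS p uniform
  ks_p <- sapply(1:60, function(s) {
    cfg <- sim_config(seed = s, ct_shift = c(a = 0, b = 1), group_delta = 0)
    ct <- gen_ct(cfg)$series
    v <- delta_ct(ct)
    suppressWarnings(stats::ks.test(v[ct$run_id == 1], v[ct$run_id == 2]))$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(ks_p, "punif"))$p.value, 0.01)

  # with no group effect the Wilcoxon p is uniform
  w_p <- sapply(1:60, function(s) {
    cfg <- sim_config(seed = s + 500, ct_shift = c(a = 0, b = 1),
                      group_delta = 0)
    ct <- gen_ct(cfg)$series
    group_difference(delta_ct(ct), ct$group)$wilcoxon_p
  })
  expect_gt(suppressWarnings(stats::ks.test(w_p, "punif"))$p.value, 0.01)
})
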