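# End-to-end pipeline on synthetic data: configuration, validation,
# demo run and artifact manifest.

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: distance cap 1,000
#' kb, domain window 100 kb, 1,000 random sets, 50 bp bins with 200 bp
#' read extension over a +/- 1 kb window, 10 cross-validation folds,
#' merit threshold 15, co-expression thresholds |r| >= 0.7 and
#' p < 0.001, and 200 bootstrap iterations.  `run_demo()` scales
#' `n_sets` down by default to keep the demo quick; every value can be
#' overridden.
#'
#' @param seed integer seed, mandatory for the stochastic stages.
#' @return named list of parameters.
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed), cap = 1e6, window = 1e5, n_sets = 1000L,
       half_window = 1000L, bin_size = 50L, extension = 200L,
       folds = 10L, merit_threshold = 15, r_min = 0.7, p_max = 0.001,
       n_boot = 200L, alpha = 0.05)
}

#' Validate a pipeline configuration
#'
#' @param config a list as from [default_config()], possibly modified.
#' @return the config, invisibly; stops on the first violated range.
#' @export
validate_config <- function(config) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1L, "seed required")
  chk(config$cap > 0, "cap must be > 0")
  chk(config$window > 0, "window must be > 0")
  chk(config$n_sets >= 1, "n_sets must be >= 1")
  chk(config$half_window > 0 && config$bin_size > 0 &&
        (2 * config$half_window) %% config$bin_size == 0,
      "bin_size must divide the signal window")
  chk(config$extension > 0, "extension must be > 0")
  chk(config$folds >= 2, "folds must be >= 2")
  chk(config$merit_threshold >= 0, "merit_threshold must be >= 0")
  chk(config$r_min > 0 && config$r_min <= 1, "r_min in (0, 1]")
  chk(config$p_max > 0 && config$p_max <= 1, "p_max in (0, 1]")
  chk(config$n_boot >= 1, "n_boot must be >= 1")
  chk(config$alpha > 0 && config$alpha < 1, "alpha in (0, 1)")
  invisible(config)
}

#' Run the full pipeline on synthetic data
#'
#' Generates every input (annotation, counts, binding sites, panel, tag
#' tracks, two qRT-PCR runs) from one seed, runs every analysis stage in
#' dependency order, writes all artifacts as provenance-headed TSV/GTF/
#' BED/JSON under `outdir`, and returns a manifest of outputs with MD5
#' checksums.  Re-running with the same seed reproduces the manifest
#' bit-identically.
#'
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @param config pipeline parameters, see [default_config()].
#' @param n_sets random sets for the distance null in the demo (default
#'   200, a scaled-down run of the standard 1,000).
#' @param sim simulation settings, see [sim_config()]; defaults to
#'   `sim_config(seed)`.
#' @return invisibly, a list with `manifest` (data frame file, md5) and
#'   `summary` (per-stage headline numbers).
#' @export
run_demo <- function(seed = 1L, outdir = file.path(tempdir(), "aerlnc_demo"),
                     config = default_config(seed), n_sets = 200L,
                     sim = sim_config(seed = seed)) {
  config$n_sets <- as.integer(n_sets)
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)

  ## inputs
  ann <- gen_annotation(sim)
  write_gtf(ann, out("annotation.gtf"), seed = seed)
  cnt <- gen_counts(ann, sim)
  write_count_table(cnt$counts, out("counts.tsv"), seed = seed)
  write_truth(cnt$truth, out("counts_truth.json"), seed = seed)

  ## DE catalog: three dispersion-stabilization variants, consensus,
  ## lncRNA filters, RPKM
  tabs <- lapply(c("max", "per_gene", "common"), function(mode)
    de_test(cnt$counts, alpha = config$alpha, dispersion_mode = mode,
            method_id = paste0("nbwald_", mode)))
  catalog <- build_catalog(tabs, ann, cnt$counts, alpha = config$alpha)
  write_tsv(catalog, out("catalog.tsv"), seed = seed,
            params = list(alpha = config$alpha))

  ## binding sites planted at down-regulated genes; distance enrichment
  ## tested separately for down- and up-regulated genes
  down <- cnt$truth$gene_id[cnt$truth$direction == "down"]
  sites <- gen_binding_sites(ann, down, sim)
  write_bed(sites, out("sites.bed"), seed = seed)
  lnc_pool <- ann[ann$biotype %in% LNCRNA_BIOTYPES, , drop = FALSE]
  enrich_one <- function(ids) {
    if (length(ids) < 3L) return(NULL)
    obs_genes <- ann[match(ids, ann$gene_id), , drop = FALSE]
    obs <- nearest_site_distance(obs_genes, sites, cap = config$cap)
    comp <- table(obs_genes$biotype)
    sets <- matched_random_sets(lnc_pool, comp, n_sets = config$n_sets,
                                seed = config$seed, exclude = ids)
    pool_d <- nearest_site_distance(lnc_pool, sites, cap = config$cap)
    nulls <- lapply(sets, function(s)
      pool_d[match(s, pool_d$gene_id), , drop = FALSE])
    distance_enrichment_test(obs, nulls, cap = config$cap)
  }
  in_cat <- intersect(catalog$gene_id, cnt$truth$gene_id)
  dirs <- cnt$truth$direction[match(in_cat, cnt$truth$gene_id)]
  enr_down <- enrich_one(in_cat[dirs == "down"])
  enr_up <- enrich_one(in_cat[dirs == "up"])
  dist_report <- data.frame(
    group = c("down", "up"),
    wilcoxon_p = c(enr_down$wilcoxon_p %||% NA, enr_up$wilcoxon_p %||% NA),
    empirical_p = c(enr_down$empirical_p %||% NA, enr_up$empirical_p %||% NA),
    median_observed = c(enr_down$median_observed %||% NA,
                        enr_up$median_observed %||% NA),
    median_null = c(enr_down$median_null %||% NA, enr_up$median_null %||% NA))
  write_tsv(dist_report, out("distance_report.tsv"), seed = seed,
            params = list(cap = config$cap, n_sets = config$n_sets))

  ## promoter/enhancer profiling at catalog TSSs
  n_reg <- min(nrow(catalog), 30L)
  anchors <- data.frame(region_id = catalog$gene_id[seq_len(n_reg)],
                        chrom = ann$chrom[match(catalog$gene_id[seq_len(n_reg)],
                                                ann$gene_id)],
                        pos = ann$tss[match(catalog$gene_id[seq_len(n_reg)],
                                            ann$gene_id)],
                        strand = ann$strand[match(catalog$gene_id[seq_len(n_reg)],
                                                  ann$gene_id)],
                        stringsAsFactors = FALSE)
  tags <- gen_chip_tags(anchors, "promoter", n_tags = 50000L,
                        seed = config$seed)
  sigA <- bin_signal(tags$markA, anchors, half_window = config$half_window,
                     bin_size = config$bin_size, extension = config$extension)
  sigB <- bin_signal(tags$markB, anchors, half_window = config$half_window,
                     bin_size = config$bin_size, extension = config$extension)
  calls <- promoter_enhancer_call(sigA, sigB)
  write_tsv(calls, out("signal_calls.tsv"), seed = seed,
            params = list(bin = config$bin_size, extension = config$extension))

  ## luminal signature: merit, selection, classification, clustering, PCA
  pan <- gen_panel(ann, sim)
  write_panel(pan$panel, out("panel.tsv"), out("panel_labels.tsv"),
              seed = seed)
  merit <- chi2_merit(pan$panel, folds = config$folds, seed = config$seed)
  write_tsv(as.data.frame(merit), out("merit.tsv"), seed = seed,
            params = list(folds = config$folds))
  signature <- select_signature(merit, threshold = config$merit_threshold)
  clf <- if (length(signature) >= 2L)
    crossval_classify(pan$panel, genes = signature, folds = config$folds,
                      seed = config$seed)
  clus <- if (length(signature) >= 2L)
    hierarchical_cluster(pan$panel, genes = signature,
                         k = length(unique(pan$panel$subtype)))
  pca <- if (length(signature) >= 2L) pca_panel(pan$panel, genes = signature)
  sig_report <- data.frame(
    signature_size = length(signature),
    classifier_accuracy = clf$accuracy %||% NA,
    cluster_purity = clus$purity %||% NA,
    pc1_variance_ratio = if (is.null(pca)) NA else pca$explained_variance[1L])
  write_tsv(sig_report, out("signature_report.tsv"), seed = seed,
            params = list(merit_threshold = config$merit_threshold))

  ## guilt-by-association around the top signature gene
  coex <- if (length(signature))
    pearson_screen(pan$panel, signature[1L], r_min = config$r_min,
                   p_max = config$p_max)
  else data.frame(gene_id = character(0), r = numeric(0),
                  p_value = numeric(0), direction = character(0))
  write_tsv(coex, out("coexpression.tsv"), seed = seed,
            params = list(r_min = config$r_min, p_max = config$p_max))

  ## two-run qRT-PCR harmonization and ER-status group test
  ct <- gen_ct(sim)
  write_ct(ct$series, out("ct.tsv"), seed = seed)
  v1 <- delta_ct(ct$series[ct$series$run_id == 1L, ])
  v2 <- delta_ct(ct$series[ct$series$run_id == 2L, ])
  harm <- harmonize_runs(v1, v2, n_boot = config$n_boot, seed = config$seed)
  merged <- c(v1, harm$adjusted)
  groups <- ct$series$group
  gd <- group_difference(merged, groups)
  qpcr_report <- data.frame(alpha_hat = harm$model$alpha_hat,
                            beta_hat = harm$model$beta_hat,
                            boot_mse = harm$model$boot_mse,
                            wilcoxon_p = gd$wilcoxon_p,
                            shapiro_p_ER_neg = gd$shapiro_p[["ER_neg"]],
                            shapiro_p_ER_pos = gd$shapiro_p[["ER_pos"]])
  write_tsv(qpcr_report, out("qpcr_report.tsv"), seed = seed,
            params = list(n_boot = config$n_boot))

  ## manifest
  files <- sort(setdiff(list.files(outdir), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, out("manifest.tsv"), seed = seed)
  invisible(list(manifest = manifest,
                 summary = list(catalog_size = nrow(catalog),
                                n_down = sum(catalog$direction == "down"),
                                n_up = sum(catalog$direction == "up"),
                                distance_wilcoxon_p_down = enr_down$wilcoxon_p %||% NA,
                                promoter_fraction = mean(calls$label == "promoter_like"),
                                signature_size = length(signature),
                                classifier_accuracy = clf$accuracy %||% NA,
                                cluster_purity = clus$purity %||% NA,
                                n_coexpressed = nrow(coex),
                                qpcr_wilcoxon_p = gd$wilcoxon_p)))
}
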