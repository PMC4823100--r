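# Synthetic-data generators.  Every generator is a pure function of
# (cfg, seed): it resets the RNG from the config seed (possibly offset per
# generator argument) and returns its planted ground truth alongside the
# data, so downstream recovery is testable.

#' Simulation configuration
#'
#' Encodes the generative assumptions the pipeline's analyses target: a
#' two-condition negative-binomial count experiment with planted
#' regulated lncRNAs, a Gencode-like biotype mixture, binding sites
#' planted near regulated genes, a 55-sample 4-subtype expression panel
#' with a planted luminal signature, promoter-like vs enhancer-like tag
#' pileups, and two qRT-PCR runs differing by a location/scale batch
#' effect with an ER-status group effect.
#'
#' @param seed integer seed; all generators derive their randomness from it.
#' @param n_genes number of genes in the annotation.
#' @param biotype_fractions named proportions summing to 1.
#' @param n_chromosomes,chrom_length chromosome count and length (bp).
#' @param de_fraction fraction of lncRNA-biotype genes planted as
#'   differentially expressed.
#' @param lfc log2 fold-change magnitude of planted genes (0 = null).
#' @param down_fraction fraction of planted genes regulated downward upon
#'   receptor knockdown (default 0.65, echoing the observed 86/133 down
#'   vs 47/133 up split).
#' @param dispersion NB dispersion phi, with Var = mu + phi mu^2.
#' @param lib_size expected reads per sample.
#' @param n_reps replicates per condition (>= 2).
#' @param subtype_design named sample counts per subtype.
#' @param signature_size number of planted luminal-signature genes.
#' @param signature_effect luminal mean shift of signature genes, in
#'   units of the per-gene log-expression standard deviation.
#' @param signature_up_fraction fraction of signature genes shifted
#'   upward in luminal samples (default 0.75; most signature lncRNAs are
#'   luminal-overexpressed, a minority move the other way).
#' @param proximity_scale mean (bp) of the exponential TSS offset of
#'   planted binding sites.
#' @param n_background_sites binding sites placed uniformly at random.
#' @param ct_runs sample sizes of the two qRT-PCR runs (default 22, 20).
#' @param ct_pos_counts ER-positive sample counts per run (default 14,
#'   12, for overall margins 26 ER+ vs 16 ER-).
#' @param ct_shift location `a` and scale `b` of the run-2 batch effect
#'   on the log scale.
#' @param ct_sigma within-group SD of the log delta-Ct values.
#' @param group_delta ER+ minus ER- mean difference of log delta-Ct.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 600L,
                       biotype_fractions = c(protein_coding = 0.40,
                                             lincRNA = 0.25,
                                             antisense = 0.20,
                                             processed_transcript = 0.05,
                                             pseudogene = 0.10),
                       n_chromosomes = 3L,
                       chrom_length = 3e7,
                       de_fraction = 0.2,
                       lfc = 2,
                       down_fraction = 0.65,
                       dispersion = 0.05,
                       lib_size = 2e5,
                       n_reps = 3L,
                       subtype_design = c(luminal = 14L, basal = 14L,
                                          claudin_low = 14L, normal_like = 13L),
                       signature_size = 30L,
                       signature_effect = 3,
                       signature_up_fraction = 0.75,
                       proximity_scale = 1e4,
                       n_background_sites = 500L,
                       ct_runs = c(22L, 20L),
                       ct_pos_counts = c(14L, 12L),
                       ct_shift = c(a = 0.5, b = 1.2),
                       ct_sigma = 0.25,
                       group_delta = 0.5) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              biotype_fractions = biotype_fractions,
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, de_fraction = de_fraction,
              lfc = lfc, down_fraction = down_fraction,
              dispersion = dispersion, lib_size = lib_size,
              n_reps = as.integer(n_reps), subtype_design = subtype_design,
              signature_size = as.integer(signature_size),
              signature_effect = signature_effect,
              signature_up_fraction = signature_up_fraction,
              proximity_scale = proximity_scale,
              n_background_sites = as.integer(n_background_sites),
              ct_runs = as.integer(ct_runs),
              ct_pos_counts = as.integer(ct_pos_counts),
              ct_shift = ct_shift, ct_sigma = ct_sigma,
              group_delta = group_delta)
  if (abs(sum(cfg$biotype_fractions) - 1) > 1e-9)
    stop("biotype_fractions must sum to 1")
  if (any(cfg$biotype_fractions < 0)) stop("negative biotype fraction")
  if (cfg$n_genes <= 0 || cfg$n_chromosomes <= 0 || cfg$n_reps <= 0)
    stop("all counts must be > 0")
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) stop("de_fraction in [0,1]")
  if (cfg$proximity_scale < 0) stop("proximity_scale must be >= 0")
  if (any(cfg$ct_pos_counts >= cfg$ct_runs))
    stop("each run needs at least one ER-negative sample")
  class(cfg) <- "sim_config"
  cfg
}

# largest-remainder apportionment of n among fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a gene annotation with a lncRNA biotype mixture
#'
#' Genes are placed on TSS slots at >= 1 kb spacing, uniformly at random
#' per chromosome; each gene gets 1-4 single-exon transcripts of 150-3000
#' bp.  Biotype counts match `biotype_fractions` to rounding.
#'
#' @param cfg a [sim_config()].
#' @return a `gene_annotation` with attributes `chrom_lengths` (named
#'   vector) recording the simulated chromosome sizes.
#' @export
gen_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set_rng(cfg$seed)
  spacing <- 1000
  margin <- 5000
  capacity <- floor((cfg$chrom_length - 2 * margin) / spacing)
  per_chrom <- apportion(cfg$n_genes, rep(1 / cfg$n_chromosomes,
                                          cfg$n_chromosomes))
  if (any(per_chrom > capacity))
    stop("chromosome too short to place genes at >= 1 kb spacing")
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  chrom <- rep(chrom_names, per_chrom)
  tss <- unlist(lapply(per_chrom, function(k)
    margin + sort(sample.int(capacity, k)) * spacing), use.names = FALSE)
  n <- cfg$n_genes
  strand <- sample(c("+", "-"), n, replace = TRUE)
  counts <- apportion(n, cfg$biotype_fractions)
  biotype <- sample(rep(names(cfg$biotype_fractions), counts))
  n_tx <- sample.int(4L, n, replace = TRUE)
  lens <- lapply(n_tx, function(k) sample(150:3000, k, replace = TRUE))
  ann <- gene_annotation(gene_id = sprintf("G%04d", seq_len(n)),
                         symbol = sprintf("G%04d", seq_len(n)),
                         chrom = chrom, strand = strand, tss = tss,
                         biotype = biotype, transcript_lengths = lens)
  attr(ann, "chrom_lengths") <- stats::setNames(rep(cfg$chrom_length,
                                                    cfg$n_chromosomes),
                                                chrom_names)
  ann
}

#' Generate binding sites planted near target genes
#'
#' One 200-bp site per target gene, centered at the TSS plus a signed
#' offset with `|offset| ~ Exponential(mean = proximity_scale)`, plus
#' `n_background_sites` sites placed uniformly over the chromosomes.
#'
#' @param annotation a `gene_annotation` (from [gen_annotation()]).
#' @param target_genes gene ids receiving a proximal site.
#' @param cfg a [sim_config()].
#' @return a `binding_sites` set; attribute `planted` marks, per site (in
#'   sorted order), whether it was planted at a target gene.
#' @export
gen_binding_sites <- function(annotation, target_genes, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  missing <- setdiff(target_genes, annotation$gene_id)
  if (length(missing))
    stop("target gene(s) not in annotation: ", paste(missing, collapse = ", "))
  set_rng(cfg$seed + 1L)
  chrom_lengths <- attr(annotation, "chrom_lengths") %||%
    tapply(annotation$tss + 5000, annotation$chrom, max)
  idx <- match(target_genes, annotation$gene_id)
  k <- length(idx)
  mag <- if (cfg$proximity_scale > 0)
    rexp(k, rate = 1 / cfg$proximity_scale) else numeric(k)
  offs <- round(mag) * sample(c(-1, 1), k, replace = TRUE)
  center <- pmax(annotation$tss[idx] + offs, 100)
  chrom <- annotation$chrom[idx]
  planted <- rep(TRUE, k)
  nb <- cfg$n_background_sites
  if (nb > 0) {
    bchrom <- sample(names(chrom_lengths), nb, replace = TRUE)
    bcenter <- floor(runif(nb, 100, chrom_lengths[bchrom] - 100))
    chrom <- c(chrom, bchrom)
    center <- c(center, bcenter)
    planted <- c(planted, rep(FALSE, nb))
  }
  sites <- binding_sites(chrom, center - 100, center + 100, summit = center)
  ord <- order(chrom, center)
  attr(sites, "planted") <- planted[ord]
  sites
}

#' Generate a two-condition NB count experiment with planted DE lncRNAs
#'
#' Baseline means are log-normal, scaled to `lib_size` expected reads per
#' sample; `de_fraction` of lncRNA-biotype genes are planted at +/-`lfc`
#' log2 fold change (downward with probability `down_fraction`) in the
#' knockdown condition; counts are NB with `Var = mu + phi mu^2` and
#' sample-specific depth factors.
#'
#' @param annotation a `gene_annotation`.
#' @param cfg a [sim_config()].
#' @return list with `counts` (a `count_matrix`; conditions `ctrl` and
#'   `kd`) and `truth` (data frame of planted gene_id, direction, lfc;
#'   empty when `lfc = 0`).
#' @export
gen_counts <- function(annotation, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_reps < 2L) stop("n_reps must be >= 2 per condition")
  set_rng(cfg$seed + 2L)
  n <- nrow(annotation)
  base <- exp(rnorm(n, log(300), 0.8))
  base <- base * cfg$lib_size / sum(base)
  lnc <- which(annotation$biotype %in% LNCRNA_BIOTYPES)
  if (cfg$lfc > 0) {
    n_de <- round(cfg$de_fraction * length(lnc))
    de_idx <- lnc[sample.int(length(lnc), n_de)]
    down <- rbinom(n_de, 1L, cfg$down_fraction) == 1L
    sign_de <- ifelse(down, -1, 1)
    truth <- data.frame(gene_id = annotation$gene_id[de_idx],
                        direction = ifelse(down, "down", "up"),
                        lfc = sign_de * cfg$lfc, stringsAsFactors = FALSE)
  } else {
    de_idx <- integer(0)
    truth <- data.frame(gene_id = character(0), direction = character(0),
                        lfc = numeric(0), stringsAsFactors = FALSE)
  }
  mu_kd <- base
  if (length(de_idx)) mu_kd[de_idx] <- base[de_idx] * 2^truth$lfc
  sf <- runif(2L * cfg$n_reps, 0.75, 1.3)
  mu <- cbind(matrix(rep(base, cfg$n_reps), n),
              matrix(rep(mu_kd, cfg$n_reps), n))
  mu <- sweep(mu, 2L, sf, "*")
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion), n)
  storage.mode(cnt) <- "integer"
  rownames(cnt) <- annotation$gene_id
  colnames(cnt) <- c(sprintf("ctrl_%d", seq_len(cfg$n_reps)),
                     sprintf("kd_%d", seq_len(cfg$n_reps)))
  cond <- stats::setNames(rep(c("ctrl", "kd"), each = cfg$n_reps),
                          colnames(cnt))
  list(counts = count_matrix(cnt, cond), truth = truth)
}

#' Generate a subtype-labeled expression panel with a planted luminal
#' signature
#'
#' Abundances are log10-normal (per-gene log10 mean ~ N(1, 0.5), SD 0.5);
#' signature genes are shifted by `signature_effect` within-gene SDs in
#' luminal samples, upward for `signature_up_fraction` of them and
#' downward for the rest.  Each non-luminal subtype additionally gets an
#' independent half-magnitude shift per signature gene (drawn from
#' -1/2, 0, +1/2 times the effect), so subtypes carry distinguishable
#' profiles while luminal vs non-luminal remains the dominant contrast.
#' Luminal samples are labeled ER-positive.
#'
#' @param annotation a `gene_annotation`; signature genes are drawn from
#'   its lncRNA-biotype genes.
#' @param cfg a [sim_config()].
#' @return list with `panel` (an `expression_panel`) and `truth` (data
#'   frame of signature gene_id and direction).
#' @export
gen_panel <- function(annotation, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set_rng(cfg$seed + 3L)
  lnc <- which(annotation$biotype %in% LNCRNA_BIOTYPES)
  if (cfg$signature_size > length(lnc))
    stop("signature_size exceeds the number of lncRNA genes")
  genes <- annotation$gene_id[lnc]
  n <- length(genes)
  design <- cfg$subtype_design
  samples <- unlist(lapply(names(design), function(s)
    sprintf("%s_%02d", s, seq_len(design[[s]]))), use.names = FALSE)
  subtype <- stats::setNames(rep(names(design), design), samples)
  m <- length(samples)
  sd_log <- 0.5
  mu_g <- rnorm(n, 1, 0.5)
  logv <- matrix(rnorm(n * m, mean = mu_g, sd = sd_log), n, m)
  sig_idx <- sample.int(n, cfg$signature_size)
  up <- rbinom(cfg$signature_size, 1L, cfg$signature_up_fraction) == 1L
  shift <- ifelse(up, 1, -1) * cfg$signature_effect * sd_log
  lum <- subtype == "luminal"
  logv[sig_idx, lum] <- logv[sig_idx, lum] + shift
  for (s in setdiff(names(design), "luminal")) {
    sec <- sample(c(-0.5, 0, 0.5), cfg$signature_size, replace = TRUE) *
      cfg$signature_effect * sd_log
    in_s <- subtype == s
    logv[sig_idx, in_s] <- logv[sig_idx, in_s] + sec
  }
  values <- 10^logv
  rownames(values) <- genes
  colnames(values) <- samples
  receptor <- stats::setNames(ifelse(lum, "ER_pos", "ER_neg"), samples)
  truth <- data.frame(gene_id = genes[sig_idx],
                      direction = ifelse(up, "up", "down"),
                      stringsAsFactors = FALSE)
  list(panel = expression_panel(values, subtype, receptor), truth = truth)
}

#' Generate ChIP tag tracks with a promoter-like or enhancer-like mark
#' ratio
#'
#' Emits two tag tracks, mark A (H3K4me3-like) and mark B (H3K4me1-like),
#' modeled as equal-depth libraries of `n_tags` reads each, of which only
#' the in-region reads are emitted: the promoter profile allocates
#' in-region tags A:B = 4:1, the enhancer profile 1:4, so the binned CPM
#' ratio around the anchors reflects the local mark enrichment.  Tag
#' fragment centers are Gaussian around region anchors (`sd` bp); each
#' record is the 5' base of a read, on a random strand, positioned so
#' that a 200-bp extension covers the drawn center.
#'
#' @param regions data frame with columns `region_id`, `chrom`, `pos`
#'   (anchor bp) and `strand`.
#' @param profile `"promoter"` or `"enhancer"`.
#' @param n_tags total tag count over both marks.
#' @param seed integer seed.
#' @param sd Gaussian spread of fragment centers around the anchor (bp).
#' @return list of tag data frames `markA`, `markB` (columns chrom,
#'   start, end, strand; 0-based single-base records), each carrying a
#'   `total_tags` attribute equal to the library size `n_tags`.
#' @export
gen_chip_tags <- function(regions, profile = c("promoter", "enhancer"),
                          n_tags, seed = 1L, sd = 300) {
  profile <- match.arg(profile)
  set_rng(seed)
  n_a <- round(n_tags * if (profile == "promoter") 4 / 5 else 1 / 5)
  n_b <- n_tags - n_a
  draw <- function(k) {
    if (k == 0L) {
      return(structure(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), strand = character(0),
                                  stringsAsFactors = FALSE),
                       total_tags = as.integer(n_tags)))
    }
    ridx <- sample.int(nrow(regions), k, replace = TRUE)
    center <- round(rnorm(k, mean = regions$pos[ridx], sd = sd))
    strand <- sample(c("+", "-"), k, replace = TRUE)
    start <- ifelse(strand == "+", center - 100, center + 99)
    start <- pmax(start, 0)
    structure(data.frame(chrom = regions$chrom[ridx], start = start,
                         end = start + 1, strand = strand,
                         stringsAsFactors = FALSE),
              total_tags = as.integer(n_tags))
  }
  list(markA = draw(n_a), markB = draw(n_b))
}

#' Generate two qRT-PCR runs with a location/scale batch effect
#'
#' Run 1: log delta-Ct ~ N(mu_group, ct_sigma^2) with
#' `mu_ER+ - mu_ER- = group_delta`.  Run 2: independent draws from the
#' same group model, transformed by `x -> a + b x` on the log scale.
#' Reference Ct is ~N(15, 0.3); target Ct is derived so that the ratio
#' convention `reference_ct / target_ct` reproduces the drawn value.
#'
#' @param cfg a [sim_config()].
#' @return list with `series` (a `ct_series` covering both runs) and
#'   `truth` (list with the batch parameters and group effect).
#' @export
gen_ct <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set_rng(cfg$seed + 4L)
  a <- cfg$ct_shift[["a"]]; b <- cfg$ct_shift[["b"]]
  one_run <- function(run, n, n_pos, transform) {
    group <- c(rep("ER_pos", n_pos), rep("ER_neg", n - n_pos))
    mu <- ifelse(group == "ER_pos", cfg$group_delta / 2, -cfg$group_delta / 2)
    logv <- rnorm(n, mu, cfg$ct_sigma)
    if (transform) logv <- a + b * logv
    v <- exp(logv)
    ref <- rnorm(n, 15, 0.3)
    ct_series(sample_id = sprintf("run%d_s%02d", run, seq_len(n)),
              target_ct = ref / v, reference_ct = ref,
              run_id = run, group = group)
  }
  s1 <- one_run(1L, cfg$ct_runs[1L], cfg$ct_pos_counts[1L], FALSE)
  s2 <- one_run(2L, cfg$ct_runs[2L], cfg$ct_pos_counts[2L], TRUE)
  series <- rbind(s1, s2)
  class(series) <- c("ct_series", "data.frame")
  list(series = series,
       truth = list(a = a, b = b, group_delta = cfg$group_delta))
}

#' Write planted ground truth as a JSON sidecar
#'
#' @param truth list or data frame of planted ground truth.
#' @param path output path.
#' @param seed seed recorded alongside.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, seed = NULL) {
  payload <- list(aerlnc = PKG_VERSION, seed = seed, truth = truth)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
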