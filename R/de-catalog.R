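# Differential-expression calls, cross-method consensus, lncRNA filters,
# RPKM conversion and time-point p-value combination.

#' Minimal negative-binomial Wald differential-expression test
#'
#' Normalizes by median-of-ratios size factors (computed over genes with
#' all-positive counts), estimates per-gene NB dispersion by the method
#' of moments pooled across the two conditions, and tests the log2 ratio
#' of normalized condition means (pseudo-count 0.5) with a Wald
#' statistic.  Dispersions are stabilized across genes before testing:
#' `"max"` (default) takes the maximum of the per-gene estimate and the
#' median estimate over well-expressed genes — the conservative sharing
#' that keeps the test calibrated at 2-3 replicates; `"per_gene"` uses
#' the raw moment estimate; `"common"` uses the median for every gene.
#' All dispersions are floored at 1e-8.  All-zero genes get p = 1 and
#' lfc = 0.  P-values are Benjamini-Hochberg adjusted within the table.
#'
#' @param cm a `count_matrix` with exactly two conditions, each with >= 2
#'   replicates.
#' @param alpha significance level recorded with the result (used by
#'   downstream consensus).
#' @param dispersion_mode dispersion stabilization, see above.
#' @param method_id label stored in the result table.
#' @return a `DE result` data frame: gene_id, per-condition base means,
#'   `log2_fc`, `p_value`, `adj_p`, `method_id`.
#' @export
de_test <- function(cm, alpha = 0.05,
                    dispersion_mode = c("max", "per_gene", "common"),
                    method_id = "nbwald") {
  stopifnot(inherits(cm, "count_matrix"))
  dispersion_mode <- match.arg(dispersion_mode)
  cond <- factor(cm$condition)
  if (nlevels(cond) != 2L)
    stop("exactly two conditions required, got ", nlevels(cond))
  if (any(table(cond) < 2L))
    stop("each condition needs >= 2 replicates")
  counts <- cm$counts
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  A <- which(cond == levels(cond)[1L]); B <- which(cond == levels(cond)[2L])
  nA <- length(A); nB <- length(B)
  mA <- rowMeans(norm[, A, drop = FALSE])
  mB <- rowMeans(norm[, B, drop = FALSE])
  vA <- apply(norm[, A, drop = FALSE], 1L, var)
  vB <- apply(norm[, B, drop = FALSE], 1L, var)
  m <- rowMeans(norm)
  v <- (vA * (nA - 1) + vB * (nB - 1)) / (nA + nB - 2)
  phi_g <- (v - m) / m^2
  phi_g[!is.finite(phi_g)] <- NA_real_
  common <- median(phi_g[m > 5], na.rm = TRUE)
  if (!is.finite(common)) common <- 0
  phi <- switch(dispersion_mode,
                max = pmax(phi_g, common, 1e-8),
                per_gene = pmax(phi_g, 1e-8),
                common = rep(max(common, 1e-8), length(phi_g)))
  phi[is.na(phi)] <- max(common, 1e-8)
  lfc <- log2((mB + 0.5) / (mA + 0.5))
  se2 <- ((mA + phi * mA^2) / nA) / ((mA + 0.5)^2 * log(2)^2) +
         ((mB + phi * mB^2) / nB) / ((mB + 0.5)^2 * log(2)^2)
  z <- lfc / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  zero <- m == 0
  p[zero] <- 1; lfc[zero] <- 0
  p[!is.finite(p)] <- 1
  data.frame(gene_id = rownames(counts),
             base_mean_A = mA, base_mean_B = mB,
             log2_fc = lfc, p_value = p,
             adj_p = p.adjust(p, method = "BH"),
             method_id = method_id,
             stringsAsFactors = FALSE)
}

#' Median-of-ratios size factors
#'
#' @param counts genes x samples count matrix.
#' @return one positive factor per sample.
#' @export
size_factors <- function(counts) {
  ok <- rowSums(counts == 0) == 0L
  if (!any(ok)) {
    warning("no gene with all-positive counts; falling back to library-size factors")
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  lg <- log(counts[ok, , drop = FALSE])
  loggeo <- rowMeans(lg)
  exp(apply(lg - loggeo, 2L, median))
}

#' Consensus of differential-expression calls across methods
#'
#' A gene enters the consensus iff it is significant (`adj_p < alpha`) in
#' at least `min_methods` tables and the sign of its log2 fold change is
#' identical in all supporting tables.
#'
#' @param results list of DE result tables (as from [de_test()]) sharing
#'   a gene universe.
#' @param alpha adjusted-p significance threshold.
#' @param min_methods minimum number of supporting tables; defaults to
#'   all provided (intersection).
#' @return data frame gene_id, direction (`down`/`up`),
#'   `n_methods_supporting`.
#' @export
consensus_de <- function(results, alpha = 0.05, min_methods = NULL) {
  if (!length(results)) stop("empty DE table list")
  min_methods <- min_methods %||% length(results)
  genes <- results[[1L]]$gene_id
  sig <- sapply(results, function(t) {
    stopifnot(setequal(t$gene_id, genes))
    t <- t[match(genes, t$gene_id), ]
    t$adj_p < alpha
  })
  sgn <- sapply(results, function(t) {
    t <- t[match(genes, t$gene_id), ]
    sign(t$log2_fc)
  })
  sig <- matrix(sig, nrow = length(genes))
  sgn <- matrix(sgn, nrow = length(genes))
  n_sup <- rowSums(sig)
  concord <- vapply(seq_along(genes), function(i) {
    s <- sgn[i, sig[i, ]]
    length(s) > 0L && all(s == s[1L]) && s[1L] != 0
  }, logical(1))
  keep <- n_sup >= min_methods & concord
  dir_sign <- vapply(seq_along(genes), function(i)
    if (keep[i]) sgn[i, which(sig[i, ])[1L]] else NA_real_, numeric(1))
  data.frame(gene_id = genes[keep],
             direction = ifelse(dir_sign[keep] < 0, "down", "up"),
             n_methods_supporting = n_sup[keep],
             stringsAsFactors = FALSE)
}

#' Apply the lncRNA catalog filters
#'
#' Keeps genes whose biotype is a lncRNA class (antisense, lincRNA,
#' processed_transcript, sense_intronic, sense_overlapping), whose
#' longest transcript is at least `min_length_bp`, and which are not
#' blacklisted as ambiguous annotations.  Protein-coding genes,
#' pseudogenes and unknown biotypes are dropped (unknowns conservatively,
#' since their noncoding status is unverified).
#'
#' @param genes character vector of gene ids, all present in `annotation`.
#' @param annotation a `gene_annotation`.
#' @param min_length_bp transcript length threshold (default 200).
#' @param blacklist gene ids (or symbols) to exclude.
#' @return data frame gene_id, keep, filter_flags (comma-joined names of
#'   failed filters, empty when the gene passes all).
#' @export
filter_lncrnas <- function(genes, annotation, min_length_bp = 200,
                           blacklist = character()) {
  idx <- match(genes, annotation$gene_id)
  if (anyNA(idx))
    stop("gene id absent from annotation: ", genes[which(is.na(idx))[1L]])
  bio_ok <- annotation$biotype[idx] %in% LNCRNA_BIOTYPES
  len_ok <- vapply(annotation$transcript_lengths[idx], max, numeric(1)) >=
    min_length_bp
  bl_ok <- !(genes %in% blacklist | annotation$symbol[idx] %in% blacklist)
  flags <- mapply(function(b, l, k)
    paste(c(if (!b) "biotype", if (!l) "length", if (!k) "blacklist"),
          collapse = ","),
    bio_ok, len_ok, bl_ok)
  data.frame(gene_id = genes, keep = bio_ok & len_ok & bl_ok,
             filter_flags = unname(flags), stringsAsFactors = FALSE)
}

#' Convert normalized counts to RPKM
#'
#' `RPKM = normalized count / (longest isoform length in kb x million
#' mapped reads)`.
#'
#' @param norm_count normalized read counts (>= 0).
#' @param longest_isoform_kb transcript length in kb (> 0).
#' @param million_reads mapped reads in millions (> 0).
#' @return RPKM values, recycled elementwise.
#' @export
compute_rpkm <- function(norm_count, longest_isoform_kb, million_reads) {
  stopifnot(all(norm_count >= 0), all(longest_isoform_kb > 0),
            all(million_reads > 0))
  norm_count / (longest_isoform_kb * million_reads)
}

#' Combine per-time-point DE results
#'
#' A gene is called differentially expressed iff its p-value is below
#' `alpha` in at least one time point.  The reported fold change is the
#' arithmetic mean of per-time-point log2 fold changes; p-values are
#' combined by Fisher's method (X = -2 sum log p ~ chi-squared with 2k
#' df).  Zero p-values are clamped to 1e-300 with a warning.
#'
#' @param per_timepoint list of DE tables with columns gene_id, p_value,
#'   log2_fc.
#' @param alpha per-time-point significance threshold.
#' @return data frame gene_id, de (logical), min_p, combined_p, log2_fc.
#' @export
combine_timepoints <- function(per_timepoint, alpha = 0.05) {
  if (!length(per_timepoint)) stop("empty table list")
  genes <- per_timepoint[[1L]]$gene_id
  pm <- sapply(per_timepoint, function(t) t[match(genes, t$gene_id), "p_value"])
  fm <- sapply(per_timepoint, function(t) t[match(genes, t$gene_id), "log2_fc"])
  pm <- matrix(pm, nrow = length(genes))
  fm <- matrix(fm, nrow = length(genes))
  if (any(pm == 0, na.rm = TRUE)) {
    warning("zero p-value(s) clamped to 1e-300")
    pm[pm == 0] <- 1e-300
  }
  X <- -2 * rowSums(log(pm))
  data.frame(gene_id = genes,
             de = apply(pm, 1L, min) < alpha,
             min_p = apply(pm, 1L, min),
             combined_p = pchisq(X, df = 2 * ncol(pm), lower.tail = FALSE),
             log2_fc = rowMeans(fm),
             stringsAsFactors = FALSE)
}

#' Build a consensus lncRNA catalog with filters and RPKM
#'
#' Integrates DE tables by [consensus_de()], applies [filter_lncrnas()],
#' and attaches per-condition RPKM computed from the first table's
#' normalized base means and the per-condition mean library sizes.
#'
#' @param de_tables list of DE result tables.
#' @param annotation a `gene_annotation`.
#' @param cm the `count_matrix` the tables came from (for library sizes).
#' @param alpha,min_methods consensus parameters (see [consensus_de()]).
#' @param blacklist ambiguous-annotation ids to exclude.
#' @return the consensus catalog: gene_id, direction,
#'   n_methods_supporting, filter_flags, rpkm_A, rpkm_B.
#' @export
build_catalog <- function(de_tables, annotation, cm, alpha = 0.05,
                          min_methods = NULL, blacklist = character()) {
  cons <- consensus_de(de_tables, alpha = alpha, min_methods = min_methods)
  if (!nrow(cons)) return(cbind(cons, filter_flags = character(0),
                                rpkm_A = numeric(0), rpkm_B = numeric(0)))
  flt <- filter_lncrnas(cons$gene_id, annotation, blacklist = blacklist)
  cons$filter_flags <- flt$filter_flags
  cons <- cons[flt$keep, , drop = FALSE]
  t1 <- de_tables[[1L]]
  i <- match(cons$gene_id, t1$gene_id)
  kb <- annotation$longest_isoform_kb[match(cons$gene_id,
                                            annotation$gene_id)]
  cond <- factor(cm$condition)
  mil <- tapply(cm$lib_sizes, cond, mean) / 1e6
  cons$rpkm_A <- compute_rpkm(t1$base_mean_A[i], kb, mil[[1L]])
  cons$rpkm_B <- compute_rpkm(t1$base_mean_B[i], kb, mil[[2L]])
  rownames(cons) <- NULL
  cons
}
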