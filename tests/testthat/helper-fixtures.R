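# Fixtures and independent brute-force oracles used across test files.

tiny_annotation <- function() {
  gene_annotation(
    gene_id = sprintf("T%02d", 1:10),
    symbol  = c("A1", "A2", "SEMA3B", "A4", "A5",
                "A6", "A7", "A8", "A9", "A10"),
    chrom   = rep(c("chr1", "chr2"), each = 5),
    strand  = rep(c("+", "-"), 5),
    tss     = c(1000, 5000, 9000, 20000, 41000,
                1500, 7000, 12000, 30000, 60000),
    biotype = c("lincRNA", "antisense", "lincRNA", "protein_coding",
                "pseudogene", "processed_transcript", "lincRNA", "unknown",
                "antisense", "lincRNA"),
    transcript_lengths = list(c(300, 1500), 250, 800, 2000, 5000,
                              400, 150, 900, 1000, c(180, 220)))
}

mk_panel <- function(values, subtype) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  expression_panel(values, stats::setNames(subtype, colnames(values)))
}

# O(n*m) all-pairs nearest TSS-to-summit distance
brute_nearest <- function(genes, sites, cap = 1e6) {
  d <- vapply(seq_len(nrow(genes)), function(i) {
    s <- sites$summit[sites$chrom == genes$chrom[i]]
    if (!length(s)) return(NA_real_)
    min(abs(genes$tss[i] - s))
  }, numeric(1))
  d[!is.na(d) & d > cap] <- NA_real_
  d
}

brute_domain <- function(gene, sites, window = 1e5) {
  keep <- sites$chrom == gene$chrom[[1L]] &
    abs(sites$summit - gene$tss[[1L]]) <= window
  sites[keep, , drop = FALSE]
}

# naive per-(tag, bin) interval-intersection count for one anchor
brute_bin <- function(tags, anchor, hw = 1000, bin = 50, ext = 200) {
  nb <- 2 * hw / bin
  cnt <- integer(nb)
  ts <- ifelse(tags$strand == "-", tags$end - ext, tags$start)
  te <- ts + ext
  for (k in seq_len(nb)) {
    b0 <- anchor$pos - hw + (k - 1) * bin
    b1 <- b0 + bin
    cnt[k] <- sum(tags$chrom == anchor$chrom & ts < b1 & te > b0)
  }
  if (anchor$strand == "-") cnt <- rev(cnt)
  cnt
}

# manual Lance-Williams agglomeration with squared-distance update and
# heights reported on the distance scale
ward_lw_heights <- function(points) {
  n <- nrow(points)
  D2 <- as.matrix(dist(points))^2
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(sizes)
    best <- c(Inf, 0, 0)
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k))
      if (D2[i, j] < best[1]) best <- c(D2[i, j], i, j)
    i <- best[2]; j <- best[3]
    heights[step] <- sqrt(best[1])
    merges[[step]] <- sort(c(members[[i]], members[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    newd <- vapply(seq_len(k), function(m) {
      if (m == i || m == j) return(NA_real_)
      nm <- sizes[m]
      ((ni + nm) * D2[i, m] + (nj + nm) * D2[j, m] - nm * D2[i, j]) /
        (ni + nj + nm)
    }, numeric(1))
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- rbind(cbind(D2[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
  }
  list(heights = heights, merges = merges)
}

# config for a 130-lncRNA-gene annotation (panel of 130 genes, 55 samples)
panel_cfg <- function(seed, effect = 3) {
  sim_config(seed = seed, n_genes = 260L,
             biotype_fractions = c(protein_coding = 0.5, lincRNA = 0.3,
                                   antisense = 0.2),
             signature_size = 30L, signature_effect = effect)
}
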