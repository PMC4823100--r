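# Guilt-by-association co-expression screening.

#' Pearson co-expression screen around a focal gene
#'
#' Computes the Pearson correlation of every panel gene with the focal
#' gene across all samples (by default on `log10(x + 0.01)` abundances),
#' with the t-transform p-value `t = r sqrt((n-2)/(1-r^2))`, two-sided,
#' n-2 df.  Hits are the genes (excluding the focal gene) with
#' `|r| >= r_min` and `p < p_max` jointly, sorted by `|r|` descending.
#'
#' @param panel an `expression_panel` with >= 4 samples.
#' @param focal focal gene id; must be present and non-constant.
#' @param r_min absolute-correlation threshold (default 0.7).
#' @param p_max p-value threshold (default 0.001).
#' @param log_transform correlate on log10-transformed abundances
#'   (default TRUE; set FALSE for the raw scale).
#' @param pseudo pseudo-count for the log transform.
#' @return data frame gene_id, r, p_value, direction (`correlated` /
#'   `anti_correlated`); attribute `screened` gives the number of genes
#'   tested.
#' @export
pearson_screen <- function(panel, focal, r_min = 0.7, p_max = 0.001,
                           log_transform = TRUE, pseudo = 0.01) {
  stopifnot(inherits(panel, "expression_panel"))
  m <- panel$values
  n <- ncol(m)
  if (n < 4L) stop("need >= 4 samples")
  if (!focal %in% rownames(m)) stop("focal gene not in panel: ", focal)
  if (log_transform) m <- log10(m + pseudo)
  x <- m[focal, ]
  if (sd(x) == 0) stop("focal gene is constant")
  others <- setdiff(rownames(m), focal)
  sds <- apply(m[others, , drop = FALSE], 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) skipped")
    others <- others[sds > 0]
  }
  r <- as.vector(cor(t(m[others, , drop = FALSE]), x))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  hit <- abs(r) >= r_min & p < p_max
  out <- data.frame(gene_id = others[hit], r = r[hit], p_value = p[hit],
                    direction = ifelse(r[hit] >= 0, "correlated",
                                       "anti_correlated"),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screened") <- length(others)
  out
}
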