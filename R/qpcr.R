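# Delta-Ct summaries, two-run harmonization and group testing.

#' Per-sample delta-Ct expression values
#'
#' Default convention is the literal cycle-number ratio
#' `reference_ct / target_ct`; the conventional exponential form
#' `2^(reference_ct - target_ct)` is selectable.  Under both, a lower
#' target Ct (more transcript) gives a larger value.  The convention
#' used is recorded as an attribute.
#'
#' @param series a `ct_series`.
#' @param convention `"ratio"` (default) or `"power"`.
#' @return named numeric vector (by sample id) with attribute
#'   `convention`.
#' @export
delta_ct <- function(series, convention = c("ratio", "power")) {
  stopifnot(inherits(series, "ct_series"))
  convention <- match.arg(convention)
  if (any(series$target_ct <= 0)) stop("target_ct must be > 0")
  if (any(series$reference_ct <= 0)) stop("reference_ct must be > 0")
  v <- switch(convention,
              ratio = series$reference_ct / series$target_ct,
              power = 2^(series$reference_ct - series$target_ct))
  structure(stats::setNames(v, series$sample_id), convention = convention)
}

#' Harmonize a second qRT-PCR run onto the scale of the first
#'
#' Both series are log-transformed; the order statistics of series 2 are
#' paired with the matching (type-7 interpolated) quantiles of series 1;
#' a standardized-major-axis line of series-1 quantiles on series-2
#' quantiles is fitted (slope = SD ratio through the means — both
#' quantile vectors carry sampling noise, so ordinary least squares
#' would attenuate the scale estimate); and among `n_boot` bootstrap
#' refits of the paired quantiles the one with the smallest out-of-bag
#' mean squared error is retained.
#' Adjusted values are `exp(alpha_hat + beta_hat * log(series2))` — a
#' monotone transform, so the within-run rank order of series 2 is
#' preserved exactly.
#'
#' @param series1,series2 positive numeric vectors (length >= 5), e.g.
#'   [delta_ct()] values of the two runs.
#' @param n_boot bootstrap iterations (default 200).
#' @param seed integer seed.
#' @return list with `model` (a `harmonization_model`: alpha_hat,
#'   beta_hat, boot_mse, n_boot, seed) and `adjusted` (series 2 on the
#'   series-1 scale).
#' @export
harmonize_runs <- function(series1, series2, n_boot = 200L, seed = 1L) {
  if (length(series1) < 5L || length(series2) < 5L)
    stop("both series need >= 5 points")
  if (any(series1 <= 0) || any(series2 <= 0))
    stop("non-positive value: log transform undefined")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  l1 <- log(series1)
  l2 <- log(series2)
  n2 <- length(l2)
  x <- sort(l2)
  probs <- (seq_len(n2) - 1) / (n2 - 1)
  y <- quantile(l1, probs = probs, type = 7, names = FALSE)
  sma_fit <- function(xi, yi) {
    sx <- sd(xi)
    if (sx == 0) return(NULL)
    b <- sign(cov(xi, yi)) * sd(yi) / sx
    if (b == 0) b <- sd(yi) / sx
    c(a = mean(yi) - b * mean(xi), b = b)
  }
  set_rng(seed)
  best <- NULL
  best_mse <- Inf
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n2, replace = TRUE)
    oob <- setdiff(seq_len(n2), idx)
    fit <- sma_fit(x[idx], y[idx])
    if (is.null(fit) || !length(oob)) next
    mse <- mean((y[oob] - fit[["a"]] - fit[["b"]] * x[oob])^2)
    if (mse < best_mse) {
      best <- fit
      best_mse <- mse
    }
  }
  if (is.null(best)) {
    best <- sma_fit(x, y) %||% c(a = mean(y) - mean(x), b = 1)
    best_mse <- mean((y - best[["a"]] - best[["b"]] * x)^2)
  }
  model <- structure(list(alpha_hat = unname(best[["a"]]),
                          beta_hat = unname(best[["b"]]),
                          boot_mse = best_mse, n_boot = n_boot,
                          seed = seed),
                     class = "harmonization_model")
  list(model = model,
       adjusted = exp(model$alpha_hat + model$beta_hat * l2))
}

#' Group difference of expression values with normality check
#'
#' Two-sided Wilcoxon rank-sum p-value between the two groups, with a
#' per-group Shapiro-Wilk normality p-value reported alongside.
#'
#' @param values per-sample expression values (e.g. harmonized delta-Ct).
#' @param groups two-level group labels (e.g. ER status), same length.
#' @return list with `wilcoxon_p` and `shapiro_p` (named per group; NA
#'   for groups with < 3 samples or zero variance).
#' @export
group_difference <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) == 0L)) stop("both groups must be non-empty")
  g1 <- values[groups == levels(groups)[1L]]
  g2 <- values[groups == levels(groups)[2L]]
  w <- wilcox.test(g1, g2, alternative = "two.sided", exact = FALSE)
  shap <- vapply(list(g1, g2), function(v) {
    if (length(v) < 3L || sd(v) == 0) return(NA_real_)
    shapiro.test(v)$p.value
  }, numeric(1))
  list(wilcoxon_p = unname(w$p.value),
       shapiro_p = stats::setNames(shap, levels(groups)))
}
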