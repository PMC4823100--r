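# Chi-squared attribute merit, signature selection, cross-validated
# classification, Ward clustering and PCA over an expression panel.

#' Per-gene z-scores across samples
#'
#' `(x - mean) / sd` per gene row, with the sample (n-1) standard
#' deviation.  Constant genes become all-zero rows with a warning.
#'
#' @param panel an `expression_panel` (or a genes x samples matrix).
#' @return object of the same shape with z-scored rows.
#' @export
zscore_panel <- function(panel) {
  m <- if (inherits(panel, "expression_panel")) panel$values else panel
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) z-scored to zero")
    s[const] <- 1
  }
  z <- (m - mu) / s
  if (inherits(panel, "expression_panel")) {
    panel$values <- z
    panel
  } else z
}

#' Equal-frequency discretization cut-points
#'
#' Cut-points computed on training values only: the sorted training
#' vector is split into `n_bins` groups of (as near as possible) equal
#' size; ties sit in the lowest compatible bin.  New values map to bin
#' `1 + #\{cuts < value\}`, so a held-out value below all cut-points
#' falls in the first bin.
#'
#' @param x numeric training values.
#' @param n_bins number of bins (default 4).
#' @return numeric cut-points (length `n_bins - 1`), for [apply_bins()].
#' @export
equal_freq_cuts <- function(x, n_bins = 4L) {
  s <- sort(x)
  idx <- round(seq_len(n_bins - 1L) * length(x) / n_bins)
  idx <- pmin(pmax(idx, 1L), length(x))
  s[idx]
}

#' @rdname equal_freq_cuts
#' @param v values to discretize.
#' @param cuts cut-points from [equal_freq_cuts()].
#' @return integer bin labels in `1..n_bins`.
#' @export
apply_bins <- function(v, cuts) {
  vapply(v, function(val) 1L + sum(val > cuts), integer(1))
}

#' Cross-validated chi-squared attribute merit
#'
#' For each of `folds` stratified folds, each gene's expression is
#' discretized into equal-frequency bins on the training portion, a
#' bin x class contingency table is formed, and the chi-squared statistic
#' `sum (O - E)^2 / E` over non-empty cells is computed.  The merit of a
#' gene is the mean of its per-fold chi-squared values; larger merit
#' means stronger association with the class labels.
#'
#' @param panel an `expression_panel`.
#' @param labels class labels; defaults to the panel's subtype labels.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling the fold partition.
#' @param n_bins discretization bins (default 4).
#' @return a `merit_table` data frame: gene_id, merit, rank (1 =
#'   highest merit, ties broken by gene_id), with the per-fold
#'   chi-squared matrix as attribute `per_fold`.
#' @export
chi2_merit <- function(panel, labels = NULL, folds = 10L, seed = 1L,
                       n_bins = 4L) {
  stopifnot(inherits(panel, "expression_panel"))
  labels <- factor(labels %||% panel$subtype)
  m <- panel$values
  if (ncol(m) < folds) stop("need at least `folds` samples")
  if (min(table(labels)) < folds)
    stop("a class has fewer than `folds` samples; use fewer folds")
  fold <- stratified_folds(labels, folds, seed)
  per_fold <- matrix(NA_real_, nrow(m), folds,
                     dimnames = list(rownames(m), NULL))
  for (f in seq_len(folds)) {
    train <- fold != f
    lab <- labels[train]
    for (g in seq_len(nrow(m))) {
      x <- m[g, train]
      b <- apply_bins(x, equal_freq_cuts(x, n_bins))
      O <- table(b, lab)
      E <- outer(rowSums(O), colSums(O)) / sum(O)
      nz <- E > 0
      per_fold[g, f] <- sum((O[nz] - E[nz])^2 / E[nz])
    }
  }
  merit <- rowMeans(per_fold)
  ord <- order(-merit, rownames(m))
  rank <- integer(length(merit))
  rank[ord] <- seq_along(merit)
  out <- data.frame(gene_id = rownames(m), merit = unname(merit),
                    rank = rank, stringsAsFactors = FALSE)
  attr(out, "per_fold") <- per_fold
  class(out) <- c("merit_table", "data.frame")
  out
}

#' Select a signature by merit threshold
#'
#' Genes with merit strictly above `threshold`, ordered by merit
#' descending with ties broken by gene_id.
#'
#' @param merit_table a `merit_table` from [chi2_merit()].
#' @param threshold merit cut-off (default 15).
#' @return character vector of gene ids, with the merits as attribute
#'   `merit`.
#' @export
select_signature <- function(merit_table, threshold = 15.0) {
  sel <- merit_table[merit_table$merit > threshold, , drop = FALSE]
  sel <- sel[order(-sel$merit, sel$gene_id), , drop = FALSE]
  structure(sel$gene_id, merit = sel$merit)
}

#' Cross-validated perceptron classification of panel samples
#'
#' A single-hidden-layer feed-forward network (softmax output) is
#' trained per stratified fold on log10-transformed (by default),
#' z-scored features and evaluated on the held-out fold; accuracy is
#' pooled correct/total over all folds.  The log transform matters for
#' abundance panels: z-scores of raw FPKM-like values are dominated by
#' the log-normal upper tail.
#'
#' @param panel an `expression_panel`.
#' @param labels class labels; defaults to the panel's subtype labels.
#' @param genes feature subset (default: all panel genes).
#' @param folds number of folds (default 10).
#' @param seed integer seed (fold partition and weight initialization).
#' @param hidden_units hidden-layer size; default
#'   `ceiling((n_features + n_classes) / 2)`.
#' @param decay,maxit weight decay and iteration cap passed to the
#'   network optimizer.
#' @param log_transform log10-transform abundances before z-scoring
#'   (default TRUE; set FALSE for panels already on a log or z scale).
#' @param pseudo pseudo-count for the log transform.
#' @return list with `accuracy`, `confusion` (true x predicted table)
#'   and `predicted` (named by sample).
#' @export
crossval_classify <- function(panel, labels = NULL, genes = NULL,
                              folds = 10L, seed = 1L, hidden_units = NULL,
                              decay = 5e-4, maxit = 300L,
                              log_transform = TRUE, pseudo = 0.01) {
  stopifnot(inherits(panel, "expression_panel"))
  labels <- factor(labels %||% panel$subtype)
  m <- panel$values
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (any(!is.finite(m))) stop("non-finite feature value")
  if (log_transform) m <- log10(m + pseudo)
  X <- t(m)
  K <- nlevels(labels)
  h <- hidden_units %||% ceiling((ncol(X) + K) / 2)
  fold <- stratified_folds(labels, folds, seed)
  pred <- character(nrow(X))
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    s <- apply(X[tr, , drop = FALSE], 2L, sd)
    s[s == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, s, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, mu), 2L, s, "/")
    set_rng(seed * 1000L + f)
    fit <- nnet::nnet(x = Xtr, y = nnet::class.ind(labels[tr]), size = h,
                      softmax = TRUE, decay = decay, maxit = maxit,
                      trace = FALSE, MaxNWts = 100000L)
    pr <- stats::predict(fit, Xte)
    pred[!tr] <- colnames(pr)[max.col(pr, ties.method = "first")]
  }
  names(pred) <- rownames(X)
  confusion <- table(true = labels, predicted = factor(pred,
                                                       levels = levels(labels)))
  list(accuracy = mean(pred == as.character(labels)),
       confusion = confusion, predicted = pred)
}

#' Ward hierarchical clustering of panel samples
#'
#' Samples are clustered on `log10(x + pseudo)`-transformed expression of
#' the given genes, with Euclidean distance and Ward.D2 agglomeration
#' (squared distances inside the Lance-Williams update, heights on the
#' distance scale).  Purity is
#' `sum_c max_class |c intersect class| / N` against the panel's subtype
#' labels.
#'
#' @param panel an `expression_panel`.
#' @param genes gene subset (default: all).
#' @param k number of clusters to cut.
#' @param log_transform log10-transform abundances first (default TRUE).
#' @param pseudo pseudo-count for the log transform (default 0.01).
#' @return list with `tree` (hclust), `clusters` (named assignment) and
#'   `purity`.
#' @export
hierarchical_cluster <- function(panel, genes = NULL, k = 2L,
                                 log_transform = TRUE, pseudo = 0.01) {
  stopifnot(inherits(panel, "expression_panel"))
  m <- panel$values
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (log_transform) m <- log10(m + pseudo)
  hc <- hclust(dist(t(m)), method = "ward.D2")
  cl <- cutree(hc, k = k)
  tab <- table(cl, panel$subtype)
  purity <- sum(apply(tab, 1L, max)) / ncol(m)
  list(tree = hc, clusters = cl, purity = purity)
}

#' Principal component analysis of panel samples
#'
#' Column-centered (per gene), SVD-based PCA of samples.  Explained
#' variance ratios sum to 1.  Sign convention: within each component the
#' largest-magnitude gene loading is positive.
#'
#' @param panel an `expression_panel`.
#' @param genes gene subset (default: all).
#' @param log_transform log10-transform abundances first (default FALSE).
#' @param pseudo pseudo-count for the log transform.
#' @return list with `scores` (samples x PCs), `rotation` (genes x PCs)
#'   and `explained_variance` ratios.
#' @export
pca_panel <- function(panel, genes = NULL, log_transform = FALSE,
                      pseudo = 0.01) {
  stopifnot(inherits(panel, "expression_panel"))
  m <- panel$values
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (log_transform) m <- log10(m + pseudo)
  pr <- prcomp(t(m), center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  list(scores = pr$x, rotation = pr$rotation,
       explained_variance = pr$sdev^2 / sum(pr$sdev^2))
}
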