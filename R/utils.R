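`%||%` <- function(x, y) if (is.null(x)) y else x

PKG_VERSION <- "0.1.0"

# RNG setup shared by every stochastic entry point, so results only depend
# on the integer seed, not on the caller's RNG state or kind.
set_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  invisible(seed)
}

provenance_lines <- function(seed = NULL, params = list()) {
  lines <- sprintf("# aerlnc %s", PKG_VERSION)
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed=%d", as.integer(seed)))
  if (length(params)) {
    kv <- vapply(names(params), function(k)
      sprintf("%s=%s", k, paste(format(params[[k]], trim = TRUE), collapse = ",")),
      character(1))
    lines <- c(lines, paste0("# ", paste(kv, collapse = " ")))
  }
  lines
}

#' Write a table as tab-separated UTF-8 with a provenance header
#'
#' All pipeline writers emit a commented header recording tool version,
#' seed and parameters, followed by a tab-separated table with column
#' names.  [read_tsv()] skips the comment lines.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @param seed optional integer seed recorded in the header.
#' @param params named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, seed = NULL, params = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_lines(seed, params), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so every training fold contains every class whenever
# each class has >= folds members.
stratified_folds <- function(labels, folds, seed) {
  set_rng(seed)
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}
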