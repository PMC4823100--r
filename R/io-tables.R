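# Count-matrix, expression-panel and Ct-series containers and their TSV I/O.

#' Construct a count matrix with condition labels
#'
#' @param counts integer matrix, genes x samples, with row and column
#'   names.
#' @param condition named character vector mapping every sample to its
#'   condition label.
#' @return a `count_matrix` list with elements `counts`, `condition` and
#'   `lib_sizes` (column sums).
#' @export
count_matrix <- function(counts, condition) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicated gene id")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  missing <- setdiff(colnames(counts), names(condition))
  if (length(missing))
    stop("sample(s) absent from design: ", paste(missing, collapse = ", "))
  condition <- condition[colnames(counts)]
  structure(list(counts = counts, condition = condition,
                 lib_sizes = colSums(counts)),
            class = "count_matrix")
}

#' Read a gene-level count table
#'
#' TSV with gene ids in the first column and one integer column per
#' sample.  Every sample must appear in `design`.
#'
#' @param path TSV file path.
#' @param design named character vector (sample -> condition) or a data
#'   frame with columns `sample` and `condition`.
#' @return a `count_matrix`.
#' @export
read_count_table <- function(path, design) {
  if (is.data.frame(design)) {
    design <- stats::setNames(as.character(design$condition),
                              as.character(design$sample))
  }
  tab <- tryCatch(read_tsv(path), error = function(e)
    stop("no data rows in ", path, call. = FALSE))
  if (!nrow(tab)) stop("no data rows in ", path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated gene id: ", ids[duplicated(ids)][1L])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count column in ", path)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at gene %s, sample %s",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  count_matrix(m, design)
}

#' @rdname read_count_table
#' @param cm a `count_matrix`.
#' @param seed,params recorded in the provenance header.
#' @export
write_count_table <- function(cm, path, seed = NULL, params = list()) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, seed = seed, params = params)
}

#' Construct an expression panel with subtype labels
#'
#' @param values numeric matrix of abundances (FPKM-like or z-scores),
#'   genes x samples, no missing values.
#' @param subtype named character vector mapping every sample to a tumor
#'   subtype label.
#' @param receptor_status optional named character vector of receptor
#'   status labels (e.g. `ER_pos` / `ER_neg`).
#' @return an `expression_panel` list.
#' @export
expression_panel <- function(values, subtype, receptor_status = NULL) {
  stopifnot(is.matrix(values), !anyNA(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (!all(colnames(values) %in% names(subtype)))
    stop("subtype labels must cover all samples")
  subtype <- subtype[colnames(values)]
  if (!is.null(receptor_status)) receptor_status <- receptor_status[colnames(values)]
  structure(list(values = values, subtype = subtype,
                 receptor_status = receptor_status),
            class = "expression_panel")
}

#' Read / write an expression panel
#'
#' The panel is stored as two TSVs: a values table (first column
#' `gene_id`) and a labels table with columns `sample`, `subtype` and
#' optionally `receptor_status`.
#'
#' @param path,labels_path value/label TSV paths.
#' @return an `expression_panel`.
#' @export
read_panel <- function(path, labels_path) {
  tab <- read_tsv(path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  lab <- read_tsv(labels_path)
  subtype <- stats::setNames(as.character(lab$subtype), as.character(lab$sample))
  rs <- if ("receptor_status" %in% names(lab))
    stats::setNames(as.character(lab$receptor_status), as.character(lab$sample))
  expression_panel(m, subtype, rs)
}

#' @rdname read_panel
#' @param panel an `expression_panel`.
#' @param seed recorded in the provenance header.
#' @export
write_panel <- function(panel, path, labels_path, seed = NULL) {
  stopifnot(inherits(panel, "expression_panel"))
  df <- data.frame(gene_id = rownames(panel$values), panel$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, seed = seed)
  lab <- data.frame(sample = colnames(panel$values),
                    subtype = unname(panel$subtype),
                    stringsAsFactors = FALSE)
  if (!is.null(panel$receptor_status))
    lab$receptor_status <- unname(panel$receptor_status)
  write_tsv(lab, labels_path, seed = seed)
  invisible(path)
}

#' Construct a qRT-PCR Ct series
#'
#' @param sample_id sample identifiers.
#' @param target_ct,reference_ct cycle-threshold values in (0, 45].
#' @param run_id run identifier, 1 or 2.
#' @param group sample group, `"ER_pos"` or `"ER_neg"`.
#' @return a `ct_series` data frame.
#' @export
ct_series <- function(sample_id, target_ct, reference_ct, run_id, group) {
  stopifnot(all(target_ct > 0), all(target_ct <= 45),
            all(reference_ct > 0), all(reference_ct <= 45),
            all(run_id %in% c(1L, 2L)), !anyNA(group))
  out <- data.frame(sample_id = as.character(sample_id),
                    target_ct = as.numeric(target_ct),
                    reference_ct = as.numeric(reference_ct),
                    run_id = as.integer(run_id),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  class(out) <- c("ct_series", "data.frame")
  out
}

#' @rdname ct_series
#' @param path TSV path.
#' @export
read_ct <- function(path) {
  tab <- read_tsv(path)
  ct_series(tab$sample_id, tab$target_ct, tab$reference_ct, tab$run_id,
            tab$group)
}

#' @rdname ct_series
#' @param series a `ct_series`.
#' @param seed recorded in the provenance header.
#' @export
write_ct <- function(series, path, seed = NULL) {
  stopifnot(inherits(series, "ct_series"))
  write_tsv(as.data.frame(series), path, seed = seed)
}
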