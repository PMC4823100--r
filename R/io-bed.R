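# Binding-site and tag-track I/O.  BED coordinates are 0-based half-open.

#' Construct a binding-site set
#'
#' Genomic intervals with one summit per site.  Sites are kept sorted by
#' (chrom, summit); the summit defaults to the interval midpoint,
#' `floor((start + end) / 2)`, matching distance measurement to the
#' center of a binding site.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds (`end > start`).
#' @param summit optional summit positions; defaults to the floor midpoint.
#' @param strand optional strand, `"+"`, `"-"` or `"."`.
#' @return a `binding_sites` data frame sorted by (chrom, summit).
#' @export
binding_sites <- function(chrom, start, end, summit = NULL, strand = NULL) {
  stopifnot(all(nzchar(chrom)), all(start >= 0), all(end > start))
  if (is.null(summit)) summit <- floor((start + end) / 2)
  if (is.null(strand)) strand <- rep(".", length(chrom))
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), summit = as.numeric(summit),
                    strand = as.character(strand), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$summit), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binding_sites", "data.frame")
  out
}

#' Read a BED3+ file of binding sites
#'
#' Accepts BED3, BED3 plus a numeric summit column, or BED6.  Records
#' with `end <= start` are rejected with a warning.  Comment (`#`),
#' `track` and `browser` lines are skipped.
#'
#' @param path BED file path.
#' @return a `binding_sites` data frame.
#' @export
read_bed <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#") &
             !startsWith(raw, "track") & !startsWith(raw, "browser")]
  if (!length(raw)) stop("no data rows in ", path)
  fields <- strsplit(raw, "[ \t]+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3L)) stop("BED record with fewer than 3 fields at data line ",
                         which(nf < 3L)[1L])
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- as.numeric(vapply(fields, `[`, character(1), 2L))
  end <- as.numeric(vapply(fields, `[`, character(1), 3L))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinate")
  bad <- end <= start
  if (any(bad)) {
    warning(sum(bad), " BED record(s) with end <= start rejected")
    chrom <- chrom[!bad]; start <- start[!bad]; end <- end[!bad]
    fields <- fields[!bad]; nf <- nf[!bad]
  }
  if (!length(chrom)) stop("no valid BED records in ", path)
  summit <- NULL
  if (all(nf >= 4L)) {
    col4 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4L)))
    if (!anyNA(col4)) summit <- col4
  }
  strand <- NULL
  if (all(nf >= 6L)) {
    col6 <- vapply(fields, `[`, character(1), 6L)
    if (all(col6 %in% c("+", "-", "."))) strand <- col6
  }
  binding_sites(chrom, start, end, summit = summit, strand = strand)
}

#' Write a binding-site set as BED (chrom, start, end, summit)
#'
#' @param sites a `binding_sites` data frame.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path, seed = NULL) {
  stopifnot(inherits(sites, "binding_sites"))
  lines <- c(provenance_lines(seed),
             sprintf("%s\t%d\t%d\t%d", sites$chrom, as.integer(sites$start),
                     as.integer(sites$end), as.integer(sites$summit)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Tag tracks (single-base 5' read positions with strand) reuse the BED
# dialect: chrom, start, end, name, score, strand.
write_tag_bed <- function(tags, path, seed = NULL) {
  lines <- c(provenance_lines(seed),
             sprintf("%s\t%d\t%d\t.\t0\t%s", tags$chrom,
                     as.integer(tags$start), as.integer(tags$end), tags$strand))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
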