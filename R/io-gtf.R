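# Gene annotation I/O.  Coordinate conventions: GTF is 1-based inclusive,
# BED is 0-based half-open; conversion happens only inside the readers and
# writers, never downstream.

LNCRNA_BIOTYPES <- c("antisense", "lincRNA", "processed_transcript",
                     "sense_intronic", "sense_overlapping")
KNOWN_BIOTYPES <- c("protein_coding", LNCRNA_BIOTYPES, "pseudogene", "unknown")

#' Construct a gene annotation table
#'
#' One row per gene: transcription start site (1-based, strand aware),
#' biotype from a closed vocabulary, and per-transcript exonic lengths.
#' `longest_isoform_kb` is the longest transcript's exonic length in kb,
#' the length used for RPKM conversion.
#'
#' @param gene_id,symbol character vectors.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param tss 1-based transcription start sites.
#' @param biotype one of `r paste(KNOWN_BIOTYPES, collapse = ", ")`.
#' @param transcript_lengths list of integer vectors, exonic bp per
#'   transcript (every length >= 1).
#' @return a `gene_annotation` data frame.
#' @export
gene_annotation <- function(gene_id, symbol, chrom, strand, tss, biotype,
                            transcript_lengths) {
  stopifnot(!anyDuplicated(gene_id), all(nzchar(chrom)),
            all(strand %in% c("+", "-")), all(tss >= 1))
  biotype[!biotype %in% KNOWN_BIOTYPES] <- "unknown"
  stopifnot(all(vapply(transcript_lengths, function(l)
    length(l) >= 1L && all(l >= 1), logical(1))))
  out <- data.frame(gene_id = as.character(gene_id),
                    symbol = as.character(symbol),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    tss = as.numeric(tss),
                    biotype = as.character(biotype),
                    stringsAsFactors = FALSE)
  out$transcript_lengths <- lapply(transcript_lengths, as.numeric)
  out$longest_isoform_kb <-
    vapply(out$transcript_lengths, max, numeric(1)) / 1000
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Read a Gencode-dialect GTF into a gene annotation table
#'
#' Parses gene/transcript/exon records (via rtracklayer).  The TSS of a
#' gene is the gene record's start on the + strand and its end on the -
#' strand (1-based).  Transcript lengths are exon-length sums per
#' transcript; a gene carrying no transcript record falls back to the
#' gene span as its sole isoform, with a warning.  Records missing a
#' `gene_type`/`gene_biotype` attribute get biotype `"unknown"` with a
#' warning.
#'
#' @param path GTF file path.
#' @return a `gene_annotation` data frame (see [gene_annotation()]).
#' @export
read_gtf <- function(path) {
  raw <- readLines(path, warn = FALSE)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  nfield <- vapply(strsplit(raw[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nfield < 9L]
  if (length(bad))
    stop("malformed GTF attribute field at line ", bad[1L])
  g <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  g$seqnames <- as.character(g$seqnames)
  g$strand <- as.character(g$strand)
  genes <- g[g$type == "gene", , drop = FALSE]
  if (!nrow(genes)) stop("no gene records in ", path)
  bt <- if ("gene_type" %in% names(g)) genes$gene_type
        else if ("gene_biotype" %in% names(g)) genes$gene_biotype
        else rep(NA_character_, nrow(genes))
  if (anyNA(bt)) {
    warning(sum(is.na(bt)), " gene(s) lack a biotype attribute; set to 'unknown'")
    bt[is.na(bt)] <- "unknown"
  }
  bt[!bt %in% KNOWN_BIOTYPES] <- "unknown"
  sym <- if ("gene_name" %in% names(g)) genes$gene_name else genes$gene_id
  sym[is.na(sym)] <- genes$gene_id[is.na(sym)]

  exons <- g[g$type == "exon", , drop = FALSE]
  txlen <- if (nrow(exons))
    tapply(exons$width, exons$transcript_id, sum) else numeric(0)
  tx2gene <- if (nrow(exons))
    tapply(exons$gene_id, exons$transcript_id, `[`, 1L) else character(0)
  lens <- lapply(genes$gene_id, function(gid) {
    ids <- names(tx2gene)[tx2gene == gid]
    unname(txlen[ids])
  })
  no_tx <- lengths(lens) == 0L
  if (any(no_tx)) {
    warning(sum(no_tx), " gene(s) without transcripts; gene span used as sole isoform")
    lens[no_tx] <- as.list(genes$width[no_tx])
  }
  gene_annotation(gene_id = genes$gene_id, symbol = sym,
                  chrom = genes$seqnames, strand = genes$strand,
                  tss = ifelse(genes$strand == "-", genes$end, genes$start),
                  biotype = bt, transcript_lengths = lens)
}

#' Write a gene annotation table as GTF
#'
#' Emits one gene record plus one single-exon transcript record per
#' isoform, so exon-length sums round-trip exactly through [read_gtf()].
#'
#' @param annotation a `gene_annotation` data frame.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, seed = NULL) {
  stopifnot(inherits(annotation, "gene_annotation"))
  lines <- sub("^#", "##", provenance_lines(seed))
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    lens <- a$transcript_lengths[[1L]]
    gmax <- max(lens)
    gs <- if (a$strand == "+") a$tss else a$tss - gmax + 1
    ge <- if (a$strand == "+") a$tss + gmax - 1 else a$tss
    attr_g <- sprintf('gene_id "%s"; gene_type "%s"; gene_name "%s";',
                      a$gene_id, a$biotype, a$symbol)
    lines <- c(lines, paste(a$chrom, "aerlnc", "gene", gs, ge, ".",
                            a$strand, ".", attr_g, sep = "\t"))
    for (t in seq_along(lens)) {
      ts <- if (a$strand == "+") a$tss else a$tss - lens[t] + 1
      te <- if (a$strand == "+") a$tss + lens[t] - 1 else a$tss
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t%d"; gene_type "%s"; gene_name "%s";',
                        a$gene_id, a$gene_id, t, a$biotype, a$symbol)
      lines <- c(lines,
                 paste(a$chrom, "aerlnc", "transcript", ts, te, ".",
                       a$strand, ".", attr_t, sep = "\t"),
                 paste(a$chrom, "aerlnc", "exon", ts, te, ".",
                       a$strand, ".", attr_t, sep = "\t"))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
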