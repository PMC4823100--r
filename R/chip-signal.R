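# Binned ChIP signal matrices and promoter/enhancer calls.

#' Bin ChIP tags around anchors into a CPM signal matrix
#'
#' Each tag is extended to `extension` bp from its 5' end in its strand
#' direction; a tag increments every bin it overlaps within the window of
#' `half_window` bp either side of the anchor, split into `bin_size` bp
#' bins.  Counts are converted to counts per million,
#' `CPM = count x 1e6 / total_tags`.  Rows are oriented 5' to 3' of the
#' anchor's strand (bins of minus-strand anchors are reversed).
#'
#' @param tags tag data frame (chrom, start, end, strand; 0-based
#'   single-base 5' records, as written by [gen_chip_tags()] or read from
#'   a tag BED).
#' @param anchors data frame with columns `region_id`, `chrom`, `pos`
#'   (anchor bp, 0-based) and `strand`.
#' @param half_window window half-width in bp (default 1 kb).
#' @param bin_size bin width in bp (default 50; must divide the window).
#' @param extension read extension in bp (default 200).
#' @param total_tags library size used for CPM; defaults to the tag
#'   track's `total_tags` attribute, else `nrow(tags)`.  Must be > 0.
#' @param chrom_sizes optional named vector of chromosome lengths;
#'   windows reaching beyond a chromosome are clipped with a warning
#'   (out-of-bounds bins stay zero).
#' @return a `signal_matrix`: regions x bins CPM matrix with attributes
#'   `counts` (raw overlap counts), `bin_size`, `half_window`,
#'   `extension`, `total_tags`.
#' @export
bin_signal <- function(tags, anchors, half_window = 1000, bin_size = 50,
                       extension = 200, total_tags = NULL,
                       chrom_sizes = NULL) {
  total_tags <- total_tags %||% attr(tags, "total_tags") %||% nrow(tags)
  if (is.null(total_tags) || total_tags <= 0) stop("total_tags must be > 0")
  if ((2 * half_window) %% bin_size != 0)
    stop("bin_size must divide the window")
  nb <- as.integer(2 * half_window / bin_size)
  ts <- ifelse(tags$strand == "-", tags$end - extension, tags$start)
  te <- ts + extension
  counts <- matrix(0L, nrow(anchors), nb,
                   dimnames = list(anchors$region_id,
                                   sprintf("bin%02d", seq_len(nb))))
  for (i in seq_len(nrow(anchors))) {
    w0 <- anchors$pos[i] - half_window
    w1 <- anchors$pos[i] + half_window
    if (!is.null(chrom_sizes)) {
      lim <- chrom_sizes[[anchors$chrom[i]]]
      if (!is.null(lim) && (w0 < 0 || w1 > lim))
        warning("window for region ", anchors$region_id[i],
                " extends beyond chromosome bounds; clipped")
    }
    sel <- which(tags$chrom == anchors$chrom[i] & te > w0 & ts < w1)
    if (!length(sel)) next
    k0 <- pmax(floor((ts[sel] - w0) / bin_size), 0)
    k1 <- pmin(ceiling((te[sel] - w0) / bin_size) - 1, nb - 1)
    d <- tabulate(k0 + 1L, nbins = nb + 1L) -
      tabulate(k1 + 2L, nbins = nb + 1L)
    counts[i, ] <- cumsum(d)[seq_len(nb)]
    if (anchors$strand[i] == "-") counts[i, ] <- rev(counts[i, ])
  }
  cpm <- counts * 1e6 / total_tags
  structure(cpm, counts = counts, bin_size = bin_size,
            half_window = half_window, extension = extension,
            total_tags = total_tags, class = c("signal_matrix", "matrix",
                                               "array"))
}

#' Promoter/enhancer call from the mark-A / mark-B signal ratio
#'
#' Per region, `ratio = (mean CPM_A + pseudo) / (mean CPM_B + pseudo)`;
#' regions with ratio strictly above 1 are labeled promoter-like (high
#' H3K4me3/H3K4me1 ratio), the rest enhancer-like.  The pseudo-count
#' keeps zero-signal regions at ratio 1 without division errors.
#'
#' @param signal_a,signal_b `signal_matrix` objects over the same
#'   regions (mark A = H3K4me3-like, mark B = H3K4me1-like).
#' @param pseudo pseudo-count added to both mean CPMs.
#' @return data frame region_id, ratio, label.
#' @export
promoter_enhancer_call <- function(signal_a, signal_b, pseudo = 1.0) {
  stopifnot(nrow(signal_a) == nrow(signal_b))
  ratio <- (rowMeans(signal_a) + pseudo) / (rowMeans(signal_b) + pseudo)
  data.frame(region_id = rownames(signal_a), ratio = unname(ratio),
             label = ifelse(ratio > 1, "promoter_like", "enhancer_like"),
             stringsAsFactors = FALSE)
}
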