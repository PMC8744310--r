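# CAGE-based validation of putative novel transcription start sites.

#' Read CAGE peaks from a BED file
#'
#' @param path BED (3+ columns). Strand, when present, is kept but ignored by
#'   default during intersection (FANTOM5-style coordinate BED).
#' @return data.frame of class `cage_peaks` with `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"*"` when absent).
#' @export
read_cage_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  cage_peaks(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1,
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE))
}

#' Construct a CAGE peak set
#' @param d data.frame with chrom, start, end and optionally strand.
#' @return Sorted data.frame of class `cage_peaks`.
#' @export
cage_peaks <- function(d) {
  stopifnot(all(c("chrom", "start", "end") %in% names(d)),
            all(d$start < d$end))
  if (is.null(d$strand)) d$strand <- "*"
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("cage_peaks", "data.frame")
  d
}

#' Window around a transcript's TSS
#'
#' In `upstream` mode the window runs from the TSS `w` bases upstream
#' (strand-aware) and includes the TSS base; in `symmetric` mode it spans
#' `w` bases either side. Clamped at position 0.
#'
#' @param t A `transcript_model`.
#' @param mode `"upstream"` or `"symmetric"`.
#' @param w Window size in bp (>= 0).
#' @return Named numeric `c(start =, end =)`, 0-based half-open.
#' @export
tss_window <- function(t, mode = c("symmetric", "upstream"), w = 500) {
  mode <- match.arg(mode)
  stopifnot(w >= 0)
  tss <- unname(tx_tss(t))
  win <- if (mode == "symmetric") {
    c(tss - w, tss + w + 1)
  } else if (t$strand == "+") {
    c(tss - w, tss + 1)
  } else {
    c(tss, tss + w + 1)
  }
  c(start = max(0, win[1L]), end = win[2L])
}

#' Intersect TSS windows with CAGE peaks
#'
#' Overlap is non-empty interval intersection under half-open semantics (a
#' peak ending exactly where a window starts does not overlap). Backed by
#' `GenomicRanges::countOverlaps`.
#'
#' @param windows data.frame with `transcript_id`, `chrom`, `start`, `end`
#'   (0-based half-open windows).
#' @param peaks A `cage_peaks`.
#' @param match_strand If `TRUE`, also require equal strand (needs `strand`
#'   in both inputs); default `FALSE`.
#' @return List with `per_id` (data.frame transcript_id, n_peaks) and
#'   `summary` (`n_novel_tss_transcripts`, `n_supported_transcripts`,
#'   `n_overlapping_peaks`).
#' @export
intersect_cage <- function(windows, peaks, match_strand = FALSE) {
  if (nrow(windows) == 0L) {
    return(list(per_id = data.frame(transcript_id = character(),
                                    n_peaks = integer()),
                summary = list(n_novel_tss_transcripts = 0L,
                               n_supported_transcripts = 0L,
                               n_overlapping_peaks = 0L)))
  }
  wgr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$start + 1, end = windows$end),
    strand = if (match_strand && !is.null(windows$strand))
      windows$strand else "*")
  pgr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1, end = peaks$end),
    strand = if (match_strand) peaks$strand else "*")
  n <- GenomicRanges::countOverlaps(wgr, pgr,
                                    ignore.strand = !match_strand)
  per_id <- data.frame(transcript_id = windows$transcript_id,
                       n_peaks = as.integer(n))
  list(per_id = per_id,
       summary = list(n_novel_tss_transcripts = nrow(windows),
                      n_supported_transcripts = sum(n > 0L),
                      n_overlapping_peaks = as.integer(sum(n))))
}
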