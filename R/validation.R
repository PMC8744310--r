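# Orthogonal-evidence validation filters: short-read exon coverage,
# split-read junction support, expression counts, internal-priming check.

#' Validation parameter set
#'
#' Defaults: novel exons need depth >= 15 reads over >= 75% of their length
#' (both thresholds inclusive); junctions need >= 3 split reads; transcripts
#' need >= 5 counts in >= 3 samples; internal priming is flagged when the
#' 20 bp genomic window immediately 3' of the transcript end is >= 50% A on
#' the sense strand.
#'
#' @param min_depth,min_fraction Exon-coverage rule.
#' @param junction_min_reads Split-read support threshold.
#' @param expr_min_count,expr_min_samples Expression filter (N reads in K
#'   samples).
#' @param t_window,a_fraction Internal-priming window size (bp) and A-fraction
#'   threshold.
#' @return Named list of class `validation_params`.
#' @export
validation_params <- function(min_depth = 15, min_fraction = 0.75,
                              junction_min_reads = 3,
                              expr_min_count = 5, expr_min_samples = 3,
                              t_window = 20, a_fraction = 0.5) {
  stopifnot(min_depth >= 0, min_fraction >= 0, min_fraction <= 1,
            junction_min_reads >= 0, expr_min_count >= 0,
            expr_min_samples >= 0, t_window >= 0,
            a_fraction >= 0, a_fraction <= 1)
  structure(list(min_depth = min_depth, min_fraction = min_fraction,
                 junction_min_reads = junction_min_reads,
                 expr_min_count = expr_min_count,
                 expr_min_samples = expr_min_samples,
                 t_window = t_window, a_fraction = a_fraction),
            class = "validation_params")
}

#' Construct a run-length coverage track
#'
#' @param segments data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `depth`. Segments are sorted and must not overlap within a
#'   chromosome; any base outside a segment has depth 0.
#' @return A `coverage_track` (list of per-chrom sorted segment tables).
#' @export
coverage_track <- function(segments) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(segments)),
            all(segments$depth >= 0), all(segments$start < segments$end))
  by_chrom <- split(segments[c("start", "end", "depth")], segments$chrom)
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping coverage segments")
    d
  })
  structure(by_chrom, class = "coverage_track")
}

#' Read a 4-column BedGraph into a coverage track
#' @param path BedGraph path (0-based half-open intervals, 4th column depth).
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path) {
  d <- data.table::fread(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "start", "end", "depth"),
                         data.table = FALSE, skip = "\t")
  coverage_track(d)
}

#' Write a coverage track as BedGraph
#' @param cov A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path) {
  rows <- lapply(names(cov), function(ch) {
    d <- cov[[ch]]
    if (!nrow(d)) return(NULL)
    data.frame(chrom = ch, d)
  })
  d <- do.call(rbind, rows)
  d <- d[order(d$chrom, d$start), ]
  data.table::fwrite(d, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# Bases of [s, e) with depth >= min_depth, from the RLE segments.
bases_at_depth <- function(cov, chrom, s, e, min_depth) {
  d <- cov[[chrom]]
  if (is.null(d) || !nrow(d)) return(0)
  hit <- d$start < e & d$end > s & d$depth >= min_depth
  if (!any(hit)) return(0)
  sum(pmin(d$end[hit], e) - pmax(d$start[hit], s))
}

#' Exon coverage pass/fail
#'
#' Passes iff the fraction of exon bases with depth at least `min_depth` is at
#' least `min_fraction`; both thresholds inclusive.
#'
#' @param exon Length-2 numeric (start, end), 0-based half-open.
#' @param chrom Chromosome of the exon.
#' @param cov A `coverage_track`.
#' @param p A `validation_params`.
#' @return Logical.
#' @export
exon_coverage_pass <- function(exon, chrom, cov, p = validation_params()) {
  len <- exon[2L] - exon[1L]
  stopifnot(len >= 1)
  bases_at_depth(cov, chrom, exon[1L], exon[2L], p$min_depth) / len >=
    p$min_fraction
}

#' Remove novel transcripts whose novel exons fail coverage validation
#'
#' A novel transcript is removed iff any of its novel exons (cassette exons or
#' exons with both boundaries novel, from its novelty report) fails
#' [exon_coverage_pass()]. Reference transcripts are never removed; genes left
#' with zero transcripts are dropped.
#'
#' @param ann `annotation` containing the candidates.
#' @param reports List of `novelty_report` covering all novel transcripts.
#' @param cov A `coverage_track`.
#' @param p A `validation_params`.
#' @return List with `annotation` (filtered) and `removed_ids`.
#' @export
filter_by_exon_coverage <- function(ann, reports, cov,
                                    p = validation_params()) {
  names(reports) <- vapply(reports, `[[`, "", "transcript_id")
  removed <- character()
  for (t in ann$transcripts) {
    if (t$source != "novel") next
    r <- reports[[t$transcript_id]]
    if (is.null(r))
      stop("no novelty report for novel transcript ", t$transcript_id)
    novel_exons <- rbind(r$cassette_exons, r$both_novel_intervals)
    if (!nrow(novel_exons)) next
    ok <- vapply(seq_len(nrow(novel_exons)), function(i)
      exon_coverage_pass(novel_exons[i, ], t$chrom, cov, p), NA)
    if (!all(ok)) removed <- c(removed, t$transcript_id)
  }
  keep <- setdiff(names(ann$transcripts), removed)
  bt <- vapply(ann$genes, `[[`, "", "biotype")
  out <- annotation(ann$transcripts[keep], gene_biotype = bt)
  list(annotation = out, removed_ids = removed)
}

#' Junction support from a split-read table
#'
#' @param path TSV with columns chrom, intron_start (0-based), intron_end
#'   (exclusive), strand, read_count.
#' @return A `junction_support` (named numeric vector keyed
#'   `"chrom|strand|start:end"`).
#' @export
read_junction_table <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  stopifnot(all(c("chrom", "intron_start", "intron_end", "strand",
                  "read_count") %in% names(d)),
            all(d$read_count >= 0))
  junction_support(d)
}

#' Construct junction support from a data.frame
#' @param d data.frame with chrom, intron_start, intron_end, strand,
#'   read_count.
#' @return Named numeric vector of class `junction_support`.
#' @export
junction_support <- function(d) {
  v <- d$read_count
  names(v) <- paste(d$chrom, d$strand,
                    jx_key(d$intron_start, d$intron_end), sep = "|")
  structure(v, class = "junction_support")
}

#' Is a junction validated by split reads?
#'
#' True iff the split-read count for exactly matching intron coordinates is at
#' least `junction_min_reads` (inclusive); a junction absent from the table
#' counts 0.
#'
#' @param chrom,strand,intron_start,intron_end Junction coordinates.
#' @param sup A `junction_support`.
#' @param p A `validation_params`.
#' @return Logical.
#' @export
junction_validated <- function(chrom, strand, intron_start, intron_end, sup,
                               p = validation_params()) {
  key <- paste(chrom, strand, jx_key(intron_start, intron_end), sep = "|")
  cnt <- if (key %in% names(sup)) unname(sup[[key]]) else 0
  cnt >= p$junction_min_reads
}

#' Expression filter: N reads in K samples
#'
#' @param counts Integer matrix, features x samples.
#' @param p A `validation_params` (`expr_min_count`, `expr_min_samples`).
#' @return Character vector of retained feature ids (rownames).
#' @export
expression_filter <- function(counts, p = validation_params()) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  keep <- rowSums(counts >= p$expr_min_count) >= p$expr_min_samples
  rownames(counts)[keep]
}

#' Internal-priming flag at a transcript 3' end
#'
#' Examines the `t_window` genomic bases immediately 3' of the transcript end
#' on the sense strand (reverse-complemented on `-`); flags the site when the
#' A fraction is at least `a_fraction`. A window running past the chromosome
#' end is truncated.
#'
#' @param three_prime_pos 0-based position of the transcript's last base.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param genome Named `DNAStringSet` (or named character vector of
#'   sequences).
#' @param p A `validation_params`.
#' @return Logical.
#' @export
internal_priming_flag <- function(three_prime_pos, chrom, strand, genome,
                                  p = validation_params()) {
  seqs <- as_genome_charset(genome)
  s <- seqs[[chrom]]
  L <- nchar(s)
  stopifnot(three_prime_pos >= 0, three_prime_pos < L)
  if (strand == "+") {
    from <- three_prime_pos + 2          # 1-based, first base after the end
    to <- min(L, three_prime_pos + 1 + p$t_window)
    if (from > to) return(FALSE)
    win <- substr(s, from, to)
  } else {
    to <- three_prime_pos                # 1-based base before the end
    from <- max(1, three_prime_pos - p$t_window + 1)
    if (to < 1) return(FALSE)
    win <- revcomp(substr(s, from, to))
  }
  n <- nchar(win)
  if (n == 0L) return(FALSE)
  a <- lengths(regmatches(win, gregexpr("A", win, fixed = TRUE)))
  a / n >= p$a_fraction
}

as_genome_charset <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    as.list(out)
  } else as.list(genome)
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}
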