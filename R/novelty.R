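# Novelty classification of candidate transcripts against a reference
# annotation. Categories follow the disjoint partition used for reporting:
# a cassette exon contributes to no splice-site tally, and an exon with both
# boundaries novel is counted once as "both novel", not in the single-site
# tallies.

empty_index_entry <- function()
  list(donors = numeric(), acceptors = numeric(), junctions = character(),
       tss = numeric(), tts = numeric(), exons = matrix(numeric(), ncol = 2L))

index_for <- function(reference, chrom, strand) {
  e <- reference$index[[paste(chrom, strand, sep = "|")]]
  if (is.null(e)) NULL else e
}

overlaps_any <- function(exons, s, e) {
  nrow(exons) > 0L && any(exons[, 1L] < e & exons[, 2L] > s)
}

#' Classify the novel features of one candidate transcript
#'
#' Compares a transcript's exons, splice sites, junctions and end sites with
#' the reference indexes on the same (chromosome, strand), genome-wide.
#' A cassette exon is an internal exon overlapping no reference exon of any
#' gene on the same strand. For exons that do overlap reference exons, each
#' splice-site boundary is tested against the strand-aware donor/acceptor
#' sets: one novel boundary feeds the novel donor (5') or acceptor (3') tally,
#' both novel boundaries count once as a both-novel exon. A junction whose two
#' sites are both annotated but whose pairing is absent is a novel junction
#' between known sites.
#'
#' @param t A `transcript_model` (normally `source == "novel"`).
#' @param reference Reference `annotation` with built indexes.
#' @param tolerance_bp TSS/TTS matching tolerance passed to
#'   [classify_end_sites()]; default 0 (exact).
#' @return A `novelty_report`: list with `transcript_id`, `cassette_exons`
#'   (interval matrix), `novel_donor_sites`, `novel_acceptor_sites`,
#'   `both_novel_exons` (count), `novel_junctions_known_sites` (data.frame),
#'   `novel_tss`, `novel_tts`, `antisense_duplicate`, `no_reference_context`.
#' @export
classify_transcript <- function(t, reference, tolerance_bp = 0) {
  idx <- index_for(reference, t$chrom, t$strand)
  no_ctx <- is.null(idx)
  if (no_ctx) idx <- empty_index_entry()
  n <- nrow(t$exons)
  cassette <- matrix(numeric(), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  both_mat <- cassette
  donors <- numeric(); acceptors <- numeric(); both <- 0L
  # strand-aware role of an exon boundary: on +, exon start is an acceptor
  # and exon end a donor; on -, reversed.
  site_known <- function(pos, role) {
    set <- if (role == "donor") idx$donors else idx$acceptors
    pos %in% set
  }
  for (i in seq_len(n)) {
    s <- unname(t$exons[i, 1L]); e <- unname(t$exons[i, 2L])
    internal <- i > 1L && i < n
    ov <- overlaps_any(idx$exons, s, e)
    if (internal && !ov) {
      cassette <- rbind(cassette, c(s, e))
      next
    }
    # boundaries that are splice sites: start unless first exon, end unless last
    bnd <- list()
    if (i > 1L)
      bnd[[length(bnd) + 1L]] <-
        list(pos = s, role = if (t$strand == "+") "acceptor" else "donor")
    if (i < n)
      bnd[[length(bnd) + 1L]] <-
        list(pos = e, role = if (t$strand == "+") "donor" else "acceptor")
    novel <- vapply(bnd, function(b) !site_known(b$pos, b$role), NA)
    if (internal && ov && length(novel) == 2L && all(novel)) {
      both <- both + 1L
      both_mat <- rbind(both_mat, c(s, e))
    } else {
      for (k in seq_along(bnd)) if (novel[k]) {
        if (bnd[[k]]$role == "donor") donors <- c(donors, bnd[[k]]$pos)
        else acceptors <- c(acceptors, bnd[[k]]$pos)
      }
    }
  }
  jx <- transcript_junctions(t)
  njks <- jx[0, ]
  if (nrow(jx)) {
    for (r in seq_len(nrow(jx))) {
      ds <- if (t$strand == "+") jx$intron_start[r] else jx$intron_end[r]
      as_ <- if (t$strand == "+") jx$intron_end[r] else jx$intron_start[r]
      if (site_known(ds, "donor") && site_known(as_, "acceptor") &&
          !(jx_key(jx$intron_start[r], jx$intron_end[r]) %in% idx$junctions))
        njks <- rbind(njks, jx[r, ])
    }
  }
  ends <- classify_end_sites(t, reference, tolerance_bp)
  structure(list(transcript_id = t$transcript_id,
                 cassette_exons = cassette,
                 novel_donor_sites = donors,
                 novel_acceptor_sites = acceptors,
                 both_novel_exons = both,
                 both_novel_intervals = both_mat,
                 novel_junctions_known_sites = njks,
                 novel_tss = ends[["novel_tss"]],
                 novel_tts = ends[["novel_tts"]],
                 antisense_duplicate = FALSE,
                 no_reference_context = no_ctx),
            class = "novelty_report")
}

#' Flag novel antisense transcripts that perfectly mirror reference models
#'
#' A transcript is flagged iff a reference transcript exists with identical
#' chromosome and identical exon interval chain but the opposite strand.
#' Matching is exact: a 1 bp boundary difference is not a duplicate.
#'
#' @param novel,reference `annotation` objects.
#' @return Character vector of flagged novel transcript ids.
#' @export
detect_antisense_duplicates <- function(novel, reference) {
  chain_key <- function(t)
    paste(t$chrom, paste(t$exons[, 1L], t$exons[, 2L], sep = "-",
                         collapse = ","), sep = "|")
  ref_keys <- split(vapply(reference$transcripts, chain_key, ""),
                    vapply(reference$transcripts, `[[`, "", "strand"))
  flagged <- character()
  for (t in novel$transcripts) {
    opp <- if (t$strand == "+") "-" else "+"
    if (chain_key(t) %in% ref_keys[[opp]])
      flagged <- c(flagged, t$transcript_id)
  }
  flagged
}

#' Test transcript end sites for novelty
#'
#' The strand-aware 5' end (TSS) is novel iff no reference TSS on the same
#' (chromosome, strand) lies within `tolerance_bp`; symmetric for the TTS.
#'
#' @param t A `transcript_model`.
#' @param reference Reference `annotation`.
#' @param tolerance_bp Non-negative matching tolerance in bp (default 0).
#' @return Named logical vector `c(novel_tss =, novel_tts =)`.
#' @export
classify_end_sites <- function(t, reference, tolerance_bp = 0) {
  stopifnot(tolerance_bp >= 0)
  idx <- index_for(reference, t$chrom, t$strand)
  if (is.null(idx)) idx <- empty_index_entry()
  near <- function(pos, set)
    length(set) > 0L && min(abs(set - pos)) <= tolerance_bp
  c(novel_tss = !near(tx_tss(t), idx$tss),
    novel_tts = !near(tx_tts(t), idx$tts))
}

#' Aggregate novelty reports into a feature catalog
#'
#' Element-wise sums over reports, mirroring the category breakdown boxes;
#' both per-transcript tallies and unique-site counts are reported because it
#' is unstated in the field whether published site counts de-duplicate sites
#' shared by several novel transcripts.
#'
#' @param reports List of `novelty_report` objects.
#' @return Named list of counts (`n_transcripts`, `n_cassette_exons`,
#'   `n_novel_donor`, `n_novel_acceptor`, `n_both_novel`,
#'   `n_novel_junctions_known_sites`, `n_novel_tss`, `n_novel_tts`,
#'   `n_antisense`, plus unique-site variants `n_unique_novel_donor`,
#'   `n_unique_novel_acceptor`).
#' @export
aggregate_catalog <- function(reports) {
  list(
    n_transcripts = length(reports),
    n_cassette_exons = sum(vapply(reports, function(r)
      nrow(r$cassette_exons), 0L)),
    n_novel_donor = sum(vapply(reports, function(r)
      length(r$novel_donor_sites), 0L)),
    n_novel_acceptor = sum(vapply(reports, function(r)
      length(r$novel_acceptor_sites), 0L)),
    n_both_novel = sum(vapply(reports, function(r)
      r$both_novel_exons, 0L)),
    n_novel_junctions_known_sites = sum(vapply(reports, function(r)
      nrow(r$novel_junctions_known_sites), 0L)),
    n_novel_tss = sum(vapply(reports, function(r) r$novel_tss, NA)),
    n_novel_tts = sum(vapply(reports, function(r) r$novel_tts, NA)),
    n_antisense = sum(vapply(reports, function(r) r$antisense_duplicate, NA)),
    n_unique_novel_donor = length(unique(unlist(lapply(reports, `[[`,
      "novel_donor_sites")))),
    n_unique_novel_acceptor = length(unique(unlist(lapply(reports, `[[`,
      "novel_acceptor_sites"))))
  )
}

#' Tabulate novelty reports as one row per transcript
#'
#' @param reports List of `novelty_report` objects.
#' @return data.frame with per-category counts and flags.
#' @export
novelty_table <- function(reports) {
  data.frame(
    transcript_id = vapply(reports, `[[`, "", "transcript_id"),
    n_cassette = vapply(reports, function(r) nrow(r$cassette_exons), 0L),
    n_novel_donor = vapply(reports, function(r)
      length(r$novel_donor_sites), 0L),
    n_novel_acceptor = vapply(reports, function(r)
      length(r$novel_acceptor_sites), 0L),
    n_both_novel = vapply(reports, function(r) r$both_novel_exons, 0L),
    n_novel_junction_known = vapply(reports, function(r)
      nrow(r$novel_junctions_known_sites), 0L),
    novel_tss = vapply(reports, function(r) r$novel_tss, NA),
    novel_tts = vapply(reports, function(r) r$novel_tts, NA),
    antisense_duplicate = vapply(reports, function(r)
      r$antisense_duplicate, NA),
    row.names = NULL
  )
}
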