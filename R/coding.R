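# Coding-status assessment: ORF scanning, frame-conservation test against the
# best-matching reference isoform, Fickett TESTCODE, hexamer usage bias, and a
# CPAT-style logistic coding-potential model.

#' Spliced sense-strand sequence of a transcript
#'
#' @param t A `transcript_model`.
#' @param genome Named `DNAStringSet` or named character vector.
#' @return Character scalar (5' to 3' sense sequence).
#' @export
transcript_sequence <- function(t, genome) {
  seqs <- as_genome_charset(genome)
  s <- seqs[[t$chrom]]
  if (is.null(s)) stop("genome sequence missing for chromosome ", t$chrom)
  parts <- vapply(seq_len(nrow(t$exons)), function(i)
    substr(s, t$exons[i, 1L] + 1, t$exons[i, 2L]), "")
  out <- paste(parts, collapse = "")
  if (t$strand == "-") out <- revcomp(out)
  toupper(out)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest ATG-initiated open reading frame
#'
#' Scans the three forward frames of a sense-strand sequence. The longest ORF
#' wins; ties break to the smaller start. An ORF may run off the 3' end
#' without a stop codon (`complete = FALSE`); its length is truncated to whole
#' codons.
#'
#' @param seq Nucleotide string over A/C/G/T/N.
#' @return `NULL` if no ATG, else list with `start`, `end` (0-based half-open
#'   transcript coordinates), `frame`, `length` (nt, multiple of 3) and
#'   `complete`.
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  L <- nchar(seq)
  best <- NULL
  for (f in 0:2) {
    if (L - f < 3) next
    starts <- seq.int(f + 1, L - 2, by = 3)
    codons <- substring(seq, starts, starts + 2)
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stops <- which(codons %in% STOP_CODONS)
    for (i in atg) {
      j <- stops[stops > i]
      if (length(j)) {
        j <- j[1L]
        len <- 3 * (j - i + 1)
        complete <- TRUE
      } else {
        len <- 3 * (length(codons) - i + 1)
        complete <- FALSE
      }
      cand <- list(start = f + 3 * (i - 1), end = f + 3 * (i - 1) + len,
                   frame = f, length = len, complete = complete)
      if (is.null(best) || cand$length > best$length ||
          (cand$length == best$length && cand$start < best$start))
        best <- cand
    }
  }
  best
}

# Fickett (1982) TESTCODE lookup tables, as used by CPAT: probability of
# coding per parameter bin, and per-base weights.
FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_POSITION_LIMITS <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
FICKETT_CONTENT_LIMITS <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                            0.17, 0)

fickett_lookup <- function(value, limits, probs) {
  probs[which(value >= limits)[1L]]
}

#' Fickett TESTCODE score
#'
#' Combines the four positional-asymmetry parameters (max/min codon-position
#' usage per base) and four composition parameters through the published
#' lookup tables and weights. Deterministic; higher values indicate
#' protein-coding-like periodicity.
#'
#' @param seq Nucleotide string, length >= 2.
#' @return Numeric score.
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  L <- nchar(seq)
  stopifnot(L >= 2)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  phase <- (seq_len(L) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(chars == b & phase == p), 0)
    posval <- max(cnt) / (min(cnt) + 1)
    score <- score +
      fickett_lookup(posval, FICKETT_POSITION_LIMITS,
                     FICKETT_POSITION_PROB[[b]]) *
        FICKETT_POSITION_WEIGHT[[b]] +
      fickett_lookup(sum(chars == b) / L, FICKETT_CONTENT_LIMITS,
                     FICKETT_CONTENT_PROB[[b]]) *
        FICKETT_CONTENT_WEIGHT[[b]]
  }
  unname(score)
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  do.call(paste0, g)
}

count_hexamers <- function(seqs, step = 1L) {
  counts <- integer(4096)
  names(counts) <- all_hexamers()
  for (s in seqs) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < 6) next
    starts <- seq.int(1, L - 5, by = step)
    h <- substring(s, starts, starts + 5)
    h <- h[!grepl("N", h, fixed = TRUE)]
    tab <- table(h)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

#' Build a hexamer usage-bias table
#'
#' Log ratio of hexamer frequencies between a coding and a noncoding training
#' set, with a pseudocount of one occurrence per hexamer class; identical
#' training sets give an all-zero table.
#'
#' @param coding_seqs,noncoding_seqs Non-empty character vectors of training
#'   sequences (coding sequences are typically CDS/ORFs).
#' @param pseudocount Added occurrences per hexamer (default 1).
#' @return Named numeric vector over the 4096 hexamers.
#' @export
build_hexamer_table <- function(coding_seqs, noncoding_seqs,
                                pseudocount = 1) {
  stopifnot(length(coding_seqs) > 0, length(noncoding_seqs) > 0)
  cc <- count_hexamers(coding_seqs) + pseudocount
  nc <- count_hexamers(noncoding_seqs) + pseudocount
  log((cc / sum(cc)) / (nc / sum(nc)))
}

#' Hexamer score of an (ORF) sequence
#'
#' Mean log-ratio over the in-frame hexamers (frame 0, step 3) of the supplied
#' sequence.
#'
#' @param seq Nucleotide string, length >= 6.
#' @param table Output of [build_hexamer_table()].
#' @return Numeric score.
#' @export
hexamer_score <- function(seq, table) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 6) stop("sequence_too_short: hexamer score needs >= 6 nt")
  starts <- seq.int(1, L - 5, by = 3)
  h <- substring(seq, starts, starts + 5)
  h <- h[h %in% names(table)]
  if (!length(h)) return(0)
  mean(table[h])
}

coding_features <- function(seq, hex_table) {
  orf <- longest_orf(seq)
  L <- nchar(seq)
  if (is.null(orf)) {
    hex <- 0; ol <- 0; cov <- 0
  } else {
    ol <- orf$length
    cov <- ol / L
    oseq <- substr(seq, orf$start + 1, orf$end)
    hex <- if (nchar(oseq) >= 6) hexamer_score(oseq, hex_table) else 0
  }
  c(orf_length = ol, orf_coverage = cov, fickett = fickett_score(seq),
    hexamer = hex)
}

#' Train a CPAT-style logistic coding-potential model
#'
#' Fits a logistic regression of coding status on four sequence features: ORF
#' length, ORF coverage (ORF length / transcript length), Fickett TESTCODE
#' score, and hexamer usage bias. The model ships no pre-trained human
#' weights; it is trained on user-supplied or synthetic labelled sequences.
#'
#' @param coding_seqs,noncoding_seqs Training sequences, >= 20 per class.
#' @param threshold Coding-probability cutoff (default 0.364); a transcript at
#'   exactly the threshold is called coding (inclusive).
#' @return List of class `coding_model`: `hexamer_table`, `coefficients`,
#'   `threshold`.
#' @export
train_coding_model <- function(coding_seqs, noncoding_seqs,
                               threshold = 0.364) {
  stopifnot(length(coding_seqs) >= 20, length(noncoding_seqs) >= 20,
            threshold > 0, threshold < 1)
  hex <- build_hexamer_table(coding_seqs, noncoding_seqs)
  feats <- t(vapply(c(coding_seqs, noncoding_seqs), coding_features,
                    numeric(4), hex_table = hex))
  y <- rep(c(1, 0), c(length(coding_seqs), length(noncoding_seqs)))
  df <- data.frame(y = y, feats)
  fit <- suppressWarnings(
    stats::glm(y ~ orf_length + orf_coverage + fickett + hexamer,
               family = stats::binomial(), data = df))
  structure(list(hexamer_table = hex,
                 coefficients = stats::coef(fit),
                 threshold = threshold),
            class = "coding_model")
}

#' Coding probability of a transcript sequence
#'
#' @param seq Nucleotide string.
#' @param model A `coding_model`.
#' @return Probability in `[0, 1]`.
#' @export
coding_probability <- function(seq, model) {
  f <- coding_features(seq, model$hexamer_table)
  eta <- model$coefficients[[1L]] + sum(model$coefficients[-1L] * f)
  stats::plogis(eta)
}

splice_affecting <- function(report) {
  nrow(report$cassette_exons) > 0L ||
    length(report$novel_donor_sites) > 0L ||
    length(report$novel_acceptor_sites) > 0L ||
    report$both_novel_exons > 0L ||
    nrow(report$novel_junctions_known_sites) > 0L
}

#' Frame-conservation test against the best-matching reference isoform
#'
#' The anchor isoform is the CDS-bearing reference transcript of the same gene
#' sharing the most junctions with the candidate (ties to the longest CDS).
#' The net change in exonic length overlapping the anchor's CDS genomic span
#' is computed; the candidate is frame-conserving iff that change is a
#' multiple of 3. Changes confined to UTRs change nothing inside the CDS span
#' and therefore conserve frame.
#'
#' @param t A novel `transcript_model`.
#' @param report Its `novelty_report`.
#' @param reference Reference `annotation`.
#' @return `TRUE`/`FALSE`, or `NA` when not applicable (no CDS-bearing
#'   reference isoform in the gene, or no splice-affecting novel feature so
#'   the decision defers to the coding-potential model).
#' @export
frame_conservation <- function(t, report, reference) {
  g <- reference$genes[[t$gene_id]]
  if (is.null(g)) return(NA)
  cands <- Filter(function(r) !is.null(r$cds),
                  reference$transcripts[g$transcript_ids])
  if (!length(cands)) return(NA)
  if (!splice_affecting(report)) return(NA)
  tkeys <- with(transcript_junctions(t), jx_key(intron_start, intron_end))
  shared <- vapply(cands, function(r) {
    rk <- with(transcript_junctions(r), jx_key(intron_start, intron_end))
    length(intersect(tkeys, rk))
  }, 0L)
  cds_len <- vapply(cands, function(r)
    sum(apply(intersect_intervals(r$exons, r$cds[1L], r$cds[2L]), 1L,
              diff)), 0)
  best <- cands[[order(-shared, -cds_len)[1L]]]
  span <- best$cds
  exonic_in_span <- function(x) {
    seg <- intersect_intervals(x$exons, span[1L], span[2L])
    if (!nrow(seg)) 0 else sum(seg[, 2L] - seg[, 1L])
  }
  diff_len <- exonic_in_span(t) - exonic_in_span(best)
  diff_len %% 3 == 0
}

#' Coding/noncoding decision for a validated novel transcript
#'
#' Decision order: (1) noncoding parent gene -> noncoding
#' (`noncoding_parent`); (2) frame-conservation test where applicable ->
#' `frameshift` (noncoding) or `frame_conserving` (coding); (3) otherwise the
#' CPAT-style model on the spliced transcript sequence -> `cpat_coding` or
#' `cpat_noncoding` at the model threshold (inclusive).
#'
#' @param t A `transcript_model`.
#' @param report Its `novelty_report`.
#' @param reference Reference `annotation` (gene biotypes, anchor isoforms).
#' @param model A `coding_model`, required only when the decision reaches the
#'   model.
#' @param genome Genome sequences, required only when the decision reaches the
#'   model.
#' @return List of class `coding_call`: `transcript_id`, `status`, `reason`,
#'   `probability` (NA unless the model decided).
#' @export
classify_coding_status <- function(t, report, reference, model = NULL,
                                   genome = NULL) {
  g <- reference$genes[[t$gene_id]]
  if (!is.null(g) && identical(g$biotype, "noncoding"))
    return(coding_call(t$transcript_id, "noncoding", "noncoding_parent"))
  fc <- frame_conservation(t, report, reference)
  if (isFALSE(fc))
    return(coding_call(t$transcript_id, "noncoding", "frameshift"))
  if (isTRUE(fc))
    return(coding_call(t$transcript_id, "coding", "frame_conserving"))
  if (is.null(model))
    stop("coding model required for transcript ", t$transcript_id)
  if (is.null(genome))
    stop("genome sequence required for transcript ", t$transcript_id)
  p <- coding_probability(transcript_sequence(t, genome), model)
  if (p >= model$threshold)
    coding_call(t$transcript_id, "coding", "cpat_coding", p)
  else
    coding_call(t$transcript_id, "noncoding", "cpat_noncoding", p)
}

coding_call <- function(id, status, reason, probability = NA_real_) {
  structure(list(transcript_id = id, status = status, reason = reason,
                 probability = probability), class = "coding_call")
}

#' Tabulate coding calls
#' @param calls List of `coding_call`.
#' @return data.frame (transcript_id, status, reason, probability).
#' @export
coding_calls_table <- function(calls) {
  data.frame(transcript_id = vapply(calls, `[[`, "", "transcript_id"),
             status = vapply(calls, `[[`, "", "status"),
             reason = vapply(calls, `[[`, "", "reason"),
             probability = vapply(calls, `[[`, 0, "probability"),
             row.names = NULL)
}
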