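# Independent brute-force oracles. These recompute expected values from the
# definitions, without going through the package's index structures or
# closed-form shortcuts.

# --- novelty: naive membership tests over enumerated reference features ----
oracle_novelty <- function(t, ref) {
  same <- Filter(function(r) r$chrom == t$chrom && r$strand == t$strand,
                 ref$transcripts)
  ref_ex <- do.call(rbind, lapply(same, function(r) r$exons))
  donors <- acceptors <- numeric(); jx_keys <- character()
  tss_set <- tts_set <- numeric()
  for (r in same) {
    n <- nrow(r$exons)
    if (n > 1) {
      istart <- r$exons[-n, 2]; iend <- r$exons[-1, 1]
      if (r$strand == "+") { donors <- c(donors, istart); acceptors <- c(acceptors, iend) }
      else { donors <- c(donors, iend); acceptors <- c(acceptors, istart) }
      jx_keys <- c(jx_keys, paste(istart, iend))
    }
    tss_set <- c(tss_set, if (r$strand == "+") r$exons[1, 1] else r$exons[n, 2] - 1)
    tts_set <- c(tts_set, if (r$strand == "+") r$exons[n, 2] - 1 else r$exons[1, 1])
  }
  n <- nrow(t$exons)
  out <- list(cassette = 0, donor = 0, acceptor = 0, both = 0, jknown = 0)
  for (i in seq_len(n)) {
    s <- t$exons[i, 1]; e <- t$exons[i, 2]
    ov <- !is.null(ref_ex) && nrow(ref_ex) > 0 &&
      any(ref_ex[, 1] < e & ref_ex[, 2] > s)
    internal <- i > 1 && i < n
    if (internal && !ov) { out$cassette <- out$cassette + 1; next }
    novel_s <- novel_e <- FALSE; has_s <- i > 1; has_e <- i < n
    if (has_s) {
      role_set <- if (t$strand == "+") acceptors else donors
      novel_s <- !(s %in% role_set)
    }
    if (has_e) {
      role_set <- if (t$strand == "+") donors else acceptors
      novel_e <- !(e %in% role_set)
    }
    if (internal && ov && novel_s && novel_e) out$both <- out$both + 1
    else {
      if (has_s && novel_s) {
        if (t$strand == "+") out$acceptor <- out$acceptor + 1
        else out$donor <- out$donor + 1
      }
      if (has_e && novel_e) {
        if (t$strand == "+") out$donor <- out$donor + 1
        else out$acceptor <- out$acceptor + 1
      }
    }
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      is_ <- t$exons[i, 2]; ie <- t$exons[i + 1, 1]
      d <- if (t$strand == "+") is_ else ie
      a <- if (t$strand == "+") ie else is_
      if (d %in% donors && a %in% acceptors && !(paste(is_, ie) %in% jx_keys))
        out$jknown <- out$jknown + 1
    }
  }
  tssp <- if (t$strand == "+") t$exons[1, 1] else t$exons[n, 2] - 1
  ttsp <- if (t$strand == "+") t$exons[n, 2] - 1 else t$exons[1, 1]
  out$novel_tss <- !(tssp %in% tss_set)
  out$novel_tts <- !(ttsp %in% tts_set)
  out
}

# --- coverage: naive per-base scan ----------------------------------------
oracle_coverage_pass <- function(exon, segs, min_depth, min_fraction) {
  depth <- rep(0, exon[2] - exon[1])
  for (i in seq_len(nrow(segs))) {
    lo <- max(segs$start[i], exon[1]); hi <- min(segs$end[i], exon[2])
    if (hi > lo) depth[(lo - exon[1] + 1):(hi - exon[1])] <- segs$depth[i]
  }
  mean(depth >= min_depth) >= min_fraction
}

# --- BH: literal step-up definition ---------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- rep(NA_real_, n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n * p[o[i]] / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# --- LOQ: exhaustive grid search with lm() --------------------------------
oracle_loq <- function(conc, ab, pseudo = 0.01) {
  x <- log2(conc); y <- log2(ab + pseudo)
  grid <- sort(unique(conc))
  sse <- function(fit) sum(stats::residuals(fit)^2)
  single <- sse(stats::lm(y ~ x))
  best_sse <- Inf; best_b <- NA
  for (cb in grid) {
    xb <- log2(cb)
    li <- x < xb; ri <- x >= xb
    if (sum(li) < 2 || sum(ri) < 2) next
    left <- min(sum((y[li] - mean(y[li]))^2),
                sse(stats::lm(y[li] ~ x[li])))
    right <- sse(stats::lm(y[ri] ~ x[ri]))
    if (left + right < best_sse - 1e-12) {
      best_sse <- left + right; best_b <- cb
    }
  }
  if (!is.finite(best_sse) || single <= best_sse + 1e-9)
    list(breakpoint = min(grid), sse = single)
  else list(breakpoint = best_b, sse = best_sse)
}

# --- Fickett TESTCODE: independent straight-from-tables implementation ----
oracle_fickett <- function(seq) {
  pp <- rbind(A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
              C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
              G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
              T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  cp <- rbind(A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
              C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
              G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
              T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  pw <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  cw <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  plim <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
  clim <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
  ch <- strsplit(toupper(seq), "")[[1]]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    at <- which(ch == b)
    byph <- tabulate(((at - 1) %% 3) + 1, 3)
    posv <- max(byph) / (min(byph) + 1)
    contv <- length(at) / length(ch)
    pi_ <- which(posv >= plim)[1]
    ci_ <- which(contv >= clim)[1]
    total <- total + pp[b, pi_] * pw[[b]] + cp[b, ci_] * cw[[b]]
  }
  unname(total)
}

# --- translation for the frame-conservation oracle ------------------------
CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(as.vector(outer(b, b, paste0)), b,
                            function(x, y) paste0(x, y)))
  # not needed in full detail: only identity of amino acids matters, so use
  # the codon string grouped by standard synonymous classes via Biostrings
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(codons)))
  stats::setNames(aa, codons)
})

oracle_translate <- function(seq) {
  n <- (nchar(seq) %/% 3) * 3
  if (n < 3) return("")
  starts <- seq(1, n - 2, by = 3)
  paste(CODON_TABLE[substring(seq, starts, starts + 2)], collapse = "")
}

# --- random RLE coverage tracks -------------------------------------------
random_track <- function(n_segs = 8) {
  gaps <- sample(0:20, n_segs, replace = TRUE)
  widths <- sample(1:30, n_segs, replace = TRUE)
  starts <- cumsum(gaps) + c(0, cumsum(widths[-n_segs]))
  data.frame(chrom = "c1", start = starts, end = starts + widths,
             depth = sample(0:30, n_segs, replace = TRUE))
}
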