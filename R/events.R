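# Alternative-splicing event classification between isoform pairs and
# differential transcript usage (isoform fractions, dIF, permutation switch
# test, functional consequences).

exon_keys <- function(ex) paste(ex[, 1L], ex[, 2L], sep = "-")

introns_of <- function(t) {
  jx <- transcript_junctions(t)
  cbind(start = jx$intron_start, end = jx$intron_end)
}

new_event <- function(type, gene_id, pair, coords, inclusion) {
  list(type = type, gene_id = gene_id, isoform_pair = pair,
       coords = coords, inclusion = inclusion)
}

#' Classify alternative-splicing events between two isoforms
#'
#' Strand-aware taxonomy over one unordered isoform pair:
#' \describe{
#'   \item{ES / MES}{one or (>= 2 consecutive) internal exon(s) of one isoform
#'     absent from the other, which bridges them with a junction sharing both
#'     flanking junction sites.}
#'   \item{IR}{an exon of one isoform fully contains an intron of the other
#'     (with its flanking exonic margins contiguous).}
#'   \item{A5 / A3}{two introns sharing one boundary with the other boundary
#'     shifted (donor side = A5, acceptor side = A3, by transcript strand),
#'     with the alternative exons overlapping each other.}
#'   \item{MEE}{two non-overlapping internal exons, each exclusive to one
#'     isoform, sharing both flanking junction partners.}
#'   \item{ATSS / ATTS}{non-identical 5' (3') terminal exons with the rest of
#'     the chain shared; the terminal introns they consume are excluded from
#'     A5/A3.}
#' }
#'
#' @param a,b `transcript_model` objects of the same gene, chromosome and
#'   strand.
#' @return List of events, each a list with `type`, `gene_id`,
#'   `isoform_pair`, `coords`, `inclusion` (the isoform carrying the event's
#'   inclusion form).
#' @export
pairwise_events <- function(a, b) {
  if (!identical(a$gene_id, b$gene_id) || !identical(a$chrom, b$chrom) ||
      !identical(a$strand, b$strand))
    stop("pairwise_events requires isoforms of one gene on one strand")
  pair <- c(a$transcript_id, b$transcript_id)
  events <- list()
  add <- function(ev) events[[length(events) + 1L]] <<- ev

  ia <- introns_of(a); ib <- introns_of(b)
  ikey <- function(m) if (nrow(m)) paste(m[, 1L], m[, 2L], sep = ":") else character()
  keys_a <- ikey(ia); keys_b <- ikey(ib)
  plus <- a$strand == "+"

  # --- ATSS / ATTS ------------------------------------------------------
  # 5'/3' terminal exon index in genomic order, by strand
  first_i <- function(t) if (plus) 1L else nrow(t$exons)
  last_i <- function(t) if (plus) nrow(t$exons) else 1L
  chain_minus <- function(t, drop_i) exon_keys(t$exons[-drop_i, , drop = FALSE])
  ends_consumed <- list(a = integer(), b = integer())
  overlap_ex <- function(u, v) u[1L] < v[2L] && v[1L] < u[2L]
  # a differing terminal exon is an alternative TSS/TTS event only when the
  # exons are truly alternative (non-overlapping) or when only the outer
  # (TSS/TTS) boundary moved; a moved splice-site boundary of an overlapping
  # terminal exon belongs to A5/A3 instead
  fa <- a$exons[first_i(a), ]; fb <- b$exons[first_i(b), ]
  inner_first_same <- if (plus) fa[2L] == fb[2L] else fa[1L] == fb[1L]
  atss <- !isTRUE(all.equal(unname(fa), unname(fb))) &&
    identical(chain_minus(a, first_i(a)), chain_minus(b, first_i(b))) &&
    (!overlap_ex(fa, fb) || inner_first_same)
  la <- a$exons[last_i(a), ]; lb <- b$exons[last_i(b), ]
  inner_last_same <- if (plus) la[1L] == lb[1L] else la[2L] == lb[2L]
  atts <- !isTRUE(all.equal(unname(la), unname(lb))) &&
    identical(chain_minus(a, last_i(a)), chain_minus(b, last_i(b))) &&
    (!overlap_ex(la, lb) || inner_last_same)
  terminal_intron <- function(t, which_end) {
    m <- introns_of(t)
    if (!nrow(m)) return(integer())
    i <- if ((which_end == "tss") == plus) 1L else nrow(m)
    i
  }
  if (atss) {
    add(new_event("ATSS", a$gene_id, pair, rbind(fa, fb),
                  inclusion = a$transcript_id))
    ends_consumed$a <- c(ends_consumed$a, terminal_intron(a, "tss"))
    ends_consumed$b <- c(ends_consumed$b, terminal_intron(b, "tss"))
  }
  if (atts) {
    add(new_event("ATTS", a$gene_id, pair, rbind(la, lb),
                  inclusion = a$transcript_id))
    ends_consumed$a <- c(ends_consumed$a, terminal_intron(a, "tts"))
    ends_consumed$b <- c(ends_consumed$b, terminal_intron(b, "tts"))
  }

  # --- exon skipping (ES / MES), both directions ------------------------
  skip_events <- function(x, y, inc_id) {
    ex <- x$exons; ey_keys <- exon_keys(y$exons)
    n <- nrow(ex)
    if (n < 3L) return()
    absent <- !(exon_keys(ex) %in% ey_keys)
    i <- 2L
    while (i <= n - 1L) {
      if (absent[i]) {
        j <- i
        while (j + 1L <= n - 1L && absent[j + 1L]) j <- j + 1L
        sL <- ex[i - 1L, 2L]; eR <- ex[j + 1L, 1L]
        if (paste(sL, eR, sep = ":") %in% ikey(introns_of(y)))
          add(new_event(if (j > i) "MES" else "ES", x$gene_id, pair,
                        ex[i:j, , drop = FALSE], inclusion = inc_id))
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  skip_events(a, b, a$transcript_id)
  skip_events(b, a, b$transcript_id)

  # --- intron retention (IR), both directions ---------------------------
  ir_events <- function(x, y, inc_id) {
    iy <- introns_of(y)
    if (!nrow(iy)) return()
    for (i in seq_len(nrow(x$exons))) {
      s <- x$exons[i, 1L]; e <- x$exons[i, 2L]
      if (exon_keys(x$exons[i, , drop = FALSE]) %in% exon_keys(y$exons))
        next
      for (r in seq_len(nrow(iy))) {
        if (s < iy[r, 1L] && iy[r, 2L] < e)
          add(new_event("IR", x$gene_id, pair,
                        rbind(c(iy[r, 1L], iy[r, 2L])), inclusion = inc_id))
      }
    }
  }
  ir_events(a, b, a$transcript_id)
  ir_events(b, a, b$transcript_id)

  # --- mutually exclusive exons (MEE) -----------------------------------
  if (nrow(a$exons) >= 3L && nrow(b$exons) >= 3L) {
    exa_keys <- exon_keys(a$exons); exb_keys <- exon_keys(b$exons)
    for (i in 2L:(nrow(a$exons) - 1L)) {
      ea <- a$exons[i, ]
      if (exon_keys(rbind(ea)) %in% exb_keys) next
      p <- a$exons[i - 1L, 2L]; q <- a$exons[i + 1L, 1L]
      for (j in 2L:(nrow(b$exons) - 1L)) {
        eb <- b$exons[j, ]
        if (exon_keys(rbind(eb)) %in% exa_keys) next
        if (b$exons[j - 1L, 2L] != p || b$exons[j + 1L, 1L] != q) next
        if (ea[2L] <= eb[1L] || eb[2L] <= ea[1L])   # non-overlapping
          add(new_event("MEE", a$gene_id, pair, rbind(ea, eb),
                        inclusion = a$transcript_id))
      }
    }
  }

  # --- alternative donor / acceptor (A5 / A3) ---------------------------
  if (nrow(ia) && nrow(ib)) {
    keep_a <- setdiff(seq_len(nrow(ia)), ends_consumed$a)
    keep_b <- setdiff(seq_len(nrow(ib)), ends_consumed$b)
    exon_ending_at <- function(t, pos) {
      k <- which(t$exons[, 2L] == pos); if (length(k)) t$exons[k[1L], ] else NULL
    }
    exon_starting_at <- function(t, pos) {
      k <- which(t$exons[, 1L] == pos); if (length(k)) t$exons[k[1L], ] else NULL
    }
    overlap <- function(u, v) !is.null(u) && !is.null(v) &&
      u[1L] < v[2L] && v[1L] < u[2L]
    for (i in keep_a) for (j in keep_b) {
      s1 <- ia[i, 1L]; e1 <- ia[i, 2L]; s2 <- ib[j, 1L]; e2 <- ib[j, 2L]
      if (s1 == s2 && e1 == e2) next
      if (e1 == e2 && s1 != s2) {
        ua <- exon_ending_at(a, s1); ub <- exon_ending_at(b, s2)
        if (overlap(ua, ub)) {
          type <- if (plus) "A5" else "A3"
          inc <- if ((plus && s1 > s2) || (!plus && s1 < s2))
            a$transcript_id else b$transcript_id
          add(new_event(type, a$gene_id, pair,
                        rbind(c(min(s1, s2), max(s1, s2))), inclusion = inc))
        }
      } else if (s1 == s2 && e1 != e2) {
        da <- exon_starting_at(a, e1); db <- exon_starting_at(b, e2)
        if (overlap(da, db)) {
          type <- if (plus) "A3" else "A5"
          inc <- if ((plus && e1 < e2) || (!plus && e1 > e2))
            a$transcript_id else b$transcript_id
          add(new_event(type, a$gene_id, pair,
                        rbind(c(min(e1, e2), max(e1, e2))), inclusion = inc))
        }
      }
    }
  }
  events
}

#' Isoform fractions from a count matrix
#'
#' `IF(i, s) = count(i, s) / gene_count(gene(i), s)`, missing where the gene
#' count is 0. Per expressed (gene, sample), fractions sum to 1.
#'
#' @param counts Feature x sample matrix with rownames.
#' @param tx2gene Named character vector `transcript_id -> gene_id` covering
#'   all rows.
#' @return Matrix of isoform fractions (NA where undefined), same dim as
#'   `counts`, with `tx2gene` attached as attribute `"tx2gene"`.
#' @export
isoform_fractions <- function(counts, tx2gene) {
  miss <- setdiff(rownames(counts), names(tx2gene))
  if (length(miss))
    stop("transcripts without gene mapping: ", paste(miss, collapse = ", "))
  genes <- tx2gene[rownames(counts)]
  gene_counts <- rowsum(counts, genes)
  denom <- gene_counts[genes, , drop = FALSE]
  ifm <- counts / denom
  ifm[denom == 0] <- NA_real_
  attr(ifm, "tx2gene") <- genes
  ifm
}

choose_arrangements <- function(n, k, n_perm, seed, exhaustive_cap = 10000) {
  total <- choose(n, k)
  if (total <= exhaustive_cap) {
    utils::combn(n, k)
  } else {
    with_seed(seed, {
      m <- matrix(0L, nrow = k, ncol = n_perm)
      for (i in seq_len(n_perm)) m[, i] <- sort(sample.int(n, k))
      m
    })
  }
}

# run code with a locally-set RNG seed, restoring global state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Differential transcript usage by the sum-of-|dIF| permutation test
#'
#' Per gene, dIF is the difference of condition means of per-sample isoform
#' fractions; the gene switch score is `sum(abs(dIF))` over its isoforms. The
#' p-value is the permutation probability (over condition-label arrangements,
#' exhaustive when there are at most 10000, else `n_perm` Monte-Carlo draws)
#' of a score at least as large; q-values are Benjamini-Hochberg across
#' genes.
#'
#' @param ifm Isoform-fraction matrix from [isoform_fractions()].
#' @param design Factor (or coercible) of two condition labels, one per
#'   sample column; both conditions need >= 2 samples.
#' @param n_perm Monte-Carlo permutations when not exhaustive.
#' @param seed RNG seed for Monte-Carlo arrangement sampling.
#' @return List: `genes` (data.frame gene_id, switch_score, p_value, q_value),
#'   `isoforms` (data.frame gene_id, transcript_id, dIF).
#' @export
dtu_switch_test <- function(ifm, design, n_perm = 2000, seed = 1) {
  design <- as.factor(design)
  stopifnot(nlevels(design) == 2L, length(design) == ncol(ifm))
  if (any(table(design) < 2L))
    stop("each condition needs >= 2 samples")
  n <- ncol(ifm)
  idx1 <- which(design == levels(design)[1L])
  arr <- choose_arrangements(n, length(idx1), n_perm, seed)
  genes <- attr(ifm, "tx2gene")
  if (is.null(genes)) stop("ifm must come from isoform_fractions()")
  gene_rows <- split(seq_len(nrow(ifm)), genes)
  score_for <- function(m, g1) {
    g2 <- setdiff(seq_len(n), g1)
    d <- rowMeans(m[, g1, drop = FALSE], na.rm = TRUE) -
      rowMeans(m[, g2, drop = FALSE], na.rm = TRUE)
    d[is.na(d)] <- 0
    d
  }
  out_g <- data.frame(gene_id = names(gene_rows), switch_score = NA_real_,
                      p_value = NA_real_)
  iso <- list()
  for (k in seq_along(gene_rows)) {
    m <- ifm[gene_rows[[k]], , drop = FALSE]
    d_obs <- score_for(m, idx1)
    obs <- sum(abs(d_obs))
    perm <- vapply(seq_len(ncol(arr)), function(c_)
      sum(abs(score_for(m, arr[, c_]))), 0)
    out_g$switch_score[k] <- obs
    out_g$p_value[k] <- mean(perm >= obs - 1e-12)
    iso[[k]] <- data.frame(gene_id = names(gene_rows)[k],
                           transcript_id = rownames(m), dIF = d_obs,
                           row.names = NULL)
  }
  out_g$q_value <- bh_adjust(out_g$p_value)
  list(genes = out_g, isoforms = do.call(rbind, iso))
}

#' Genome-wide alternative-splicing event usage summary
#'
#' Enumerates events over all isoform pairs per gene; per event, usage in a
#' condition is the mean (over that condition's samples) isoform fraction of
#' the event's inclusion isoform. The condition difference gets a permutation
#' p-value over condition-label arrangements.
#'
#' @param ann `annotation` (all isoforms quantified in `ifm`).
#' @param ifm Isoform-fraction matrix from [isoform_fractions()].
#' @param design Two-level condition factor.
#' @param n_perm,seed Permutation controls, as in [dtu_switch_test()].
#' @return List: `events` (per-event data.frame with usage difference and
#'   p-value) and `by_type` (aggregate data.frame: type, n_events,
#'   mean_abs_diff).
#' @export
gene_event_summary <- function(ann, ifm, design, n_perm = 2000, seed = 1) {
  design <- as.factor(design)
  n <- ncol(ifm)
  idx1 <- which(design == levels(design)[1L])
  arr <- choose_arrangements(n, length(idx1), n_perm, seed)
  rows <- list()
  for (gid in names(ann$genes)) {
    tids <- ann$genes[[gid]]$transcript_ids
    tids <- tids[tids %in% rownames(ifm)]
    if (length(tids) < 2L) next
    pairs <- utils::combn(tids, 2L)
    for (p_ in seq_len(ncol(pairs))) {
      a <- ann$transcripts[[pairs[1L, p_]]]
      b <- ann$transcripts[[pairs[2L, p_]]]
      for (ev in pairwise_events(a, b)) {
        u <- ifm[ev$inclusion, ]
        u1 <- mean(u[idx1], na.rm = TRUE)
        u2 <- mean(u[-idx1], na.rm = TRUE)
        obs <- u1 - u2
        perm <- vapply(seq_len(ncol(arr)), function(c_) {
          g1 <- arr[, c_]
          abs(mean(u[g1], na.rm = TRUE) - mean(u[-g1], na.rm = TRUE))
        }, 0)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, type = ev$type,
          isoform_a = ev$isoform_pair[1L], isoform_b = ev$isoform_pair[2L],
          inclusion = ev$inclusion, usage_cond1 = u1, usage_cond2 = u2,
          usage_diff = obs,
          p_value = mean(perm >= abs(obs) - 1e-12))
      }
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), type = character(),
               isoform_a = character(), isoform_b = character(),
               inclusion = character(), usage_cond1 = numeric(),
               usage_cond2 = numeric(), usage_diff = numeric(),
               p_value = numeric())
  by_type <- if (nrow(events)) {
    agg <- stats::aggregate(abs(events$usage_diff),
                            by = list(type = events$type), FUN = mean)
    cnt <- as.data.frame(table(events$type), stringsAsFactors = FALSE)
    names(cnt) <- c("type", "n_events")
    merge(cnt, stats::setNames(agg, c("type", "mean_abs_diff")), by = "type")
  } else data.frame(type = character(), n_events = integer(),
                    mean_abs_diff = numeric())
  list(events = events, by_type = by_type)
}

#' Putative functional consequences of isoform switches
#'
#' For each gene the dominant gaining (largest positive dIF) and losing (most
#' negative dIF) isoforms are compared: a coding/noncoding status change, an
#' ORF length change of at least 10%, and (when a feature table is supplied)
#' gain/loss of an annotated domain or signal peptide are flagged.
#'
#' @param switch Output of [dtu_switch_test()].
#' @param calls List of `coding_call` (or data.frame from
#'   [coding_calls_table()]) covering the isoforms.
#' @param annotations Optional data.frame with `transcript_id`, `orf_length`,
#'   and optionally `domains` (comma-separated) and `signal_peptide`
#'   (logical).
#' @return data.frame: gene_id, gaining, losing, consequences
#'   (comma-separated flags, `""` when none).
#' @export
functional_consequences <- function(switch, calls, annotations = NULL) {
  if (!is.data.frame(calls)) calls <- coding_calls_table(calls)
  status <- stats::setNames(calls$status, calls$transcript_id)
  out <- list()
  for (gid in unique(switch$isoforms$gene_id)) {
    iso <- switch$isoforms[switch$isoforms$gene_id == gid, ]
    if (nrow(iso) < 2L) next
    gain <- iso$transcript_id[which.max(iso$dIF)]
    lose <- iso$transcript_id[which.min(iso$dIF)]
    if (iso$dIF[iso$transcript_id == gain] <= 0 ||
        iso$dIF[iso$transcript_id == lose] >= 0) next
    flags <- character()
    sg <- status[gain]; sl <- status[lose]
    if (!is.na(sg) && !is.na(sl) && sg != sl)
      flags <- c(flags, if (sg == "coding") "coding_gain" else "coding_loss")
    if (!is.null(annotations) && "orf_length" %in% names(annotations)) {
      og <- annotations$orf_length[annotations$transcript_id == gain]
      ol <- annotations$orf_length[annotations$transcript_id == lose]
      if (length(og) == 1L && length(ol) == 1L && max(og, ol) > 0 &&
          abs(og - ol) / max(og, ol) >= 0.10)
        flags <- c(flags, "orf_length_change")
    }
    if (!is.null(annotations) && "domains" %in% names(annotations)) {
      dg <- annotations$domains[annotations$transcript_id == gain]
      dl <- annotations$domains[annotations$transcript_id == lose]
      if (length(dg) == 1L && length(dl) == 1L && !identical(dg, dl))
        flags <- c(flags, "domain_change")
    }
    if (!is.null(annotations) && "signal_peptide" %in% names(annotations)) {
      pg <- annotations$signal_peptide[annotations$transcript_id == gain]
      pl <- annotations$signal_peptide[annotations$transcript_id == lose]
      if (length(pg) == 1L && length(pl) == 1L && !identical(pg, pl))
        flags <- c(flags, "signal_peptide_change")
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gid, gaining = gain, losing = lose,
      consequences = paste(flags, collapse = ","))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), gaining = character(),
               losing = character(), consequences = character())
}
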