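# Ground-truth synthetic data generator for every pipeline stage: genome,
# reference annotation with CDS, injected novel features of each category,
# designed coverage tracks, NB counts with planted DE/DTU, spike-in mixes
# with a detection floor, and CAGE peaks. Every output is a pure function of
# (config, seed).

#' Simulation configuration
#'
#' Defaults describe a compact two-condition bulk experiment: 2 chromosomes
#' of 1 Mb, 150 multi-exon genes (~20% noncoding), 5 vs 5 samples,
#' negative-binomial counts with dispersion 0.1 around a log-normal baseline
#' mean of ~100, and novel-feature injections of every category. The
#' validation pass fraction and coding fraction default to the proportions
#' the pipeline is designed to report on real data-scale runs (2567/3274 and
#' 929/2567).
#'
#' @param seed Integer master seed; stage generators derive fixed offsets.
#' @param n_chroms,chrom_length,n_genes Genome scale.
#' @param noncoding_fraction Fraction of genes without CDS.
#' @param extra_isoform_fraction Fraction of genes receiving a second,
#'   annotated exon-skipping isoform.
#' @param make_genome Generate nucleotide sequence (disable for
#'   annotation-only runs).
#' @param injections Named list of injection counts: `cassette`,
#'   `frame_conserving` (subset of cassette), `donor`, `acceptor`, `both`,
#'   `junction_known`, `tss`, `antisense`.
#' @param pass_fraction Fraction of cassette transcripts designed to pass
#'   exon-coverage validation.
#' @param coding_n_among_pass Optional exact number of frame-conserving
#'   (hence coding) cassette transcripts drawn from the designed-pass subset;
#'   when set it overrides `injections$frame_conserving` and restricts
#'   cassette hosts to coding genes.
#' @param junction_valid_fraction Fraction of novel junctions given
#'   split-read support.
#' @param samples_per_condition Replicates per condition (default 5).
#' @param nb_dispersion NB dispersion for counts (default 0.1).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean counts.
#' @param n_de,de_logfc Planted differentially expressed transcripts and
#'   their true logFC.
#' @param n_dtu,dtu_dif Planted usage-switch genes and their per-isoform dIF.
#' @param n_sequins,sequin_cstar,sequin_scale,sequin_dispersion,sequin_noise
#'   Spike-in simulation controls (`sequin_cstar` is the detection floor
#'   concentration, attomol/ul).
#' @param cage_hit_fraction Fraction of novel-TSS transcripts given a CAGE
#'   peak inside the +/- 500 bp window.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 1e6, n_genes = 150,
                       noncoding_fraction = 0.2,
                       extra_isoform_fraction = 0.4,
                       make_genome = TRUE,
                       injections = list(cassette = 10, frame_conserving = 4,
                                         donor = 8, acceptor = 8, both = 6,
                                         junction_known = 6, tss = 8,
                                         antisense = 5),
                       pass_fraction = 2567 / 3274,
                       coding_n_among_pass = NULL,
                       junction_valid_fraction = 1019 / 1520,
                       samples_per_condition = 5,
                       nb_dispersion = 0.1,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       n_de = 30, de_logfc = 2,
                       n_dtu = 10, dtu_dif = 0.6,
                       n_sequins = 30, sequin_cstar = 0.08,
                       sequin_scale = 500, sequin_dispersion = 0.05,
                       sequin_noise = TRUE,
                       cage_hit_fraction = 0.4) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes > 0, cfg$pass_fraction >= 0, cfg$pass_fraction <= 1,
            cfg$cage_hit_fraction >= 0, cfg$cage_hit_fraction <= 1,
            cfg$samples_per_condition >= 2)
  class(cfg) <- "sim_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

# permutation of a vector that never falls into sample(n)'s scalar trap
shuffle <- function(x) x[sample.int(length(x))]

# pieces of [s, e) not covered by the (possibly overlapping) rows of `sub`
interval_subtract <- function(s, e, sub) {
  if (is.null(sub) || nrow(sub) == 0L) return(cbind(s, e))
  sub <- sub[order(sub[, 1L]), , drop = FALSE]
  out <- NULL
  cur <- s
  for (i in seq_len(nrow(sub))) {
    a <- max(s, sub[i, 1L]); b <- min(e, sub[i, 2L])
    if (b <= a) next
    if (a > cur) out <- rbind(out, c(cur, a))
    cur <- max(cur, b)
  }
  if (cur < e) out <- rbind(out, c(cur, e))
  if (is.null(out)) matrix(numeric(), ncol = 2L) else out
}

# map 1-based transcript coordinates to 1-based genomic positions (5'->3')
tx_to_genomic <- function(t) {
  g <- unlist(lapply(seq_len(nrow(t$exons)), function(i)
    seq.int(t$exons[i, 1L] + 1, t$exons[i, 2L])))
  if (t$strand == "-") rev(g) else g
}

#' Generate a reference genome and annotation
#'
#' Genes are laid out without overlap, 2-10 exons each (introns >= 200 bp,
#' inter-gene gaps >= 1.5 kb), random strand; ~`noncoding_fraction` of genes
#' lack a CDS. Coding genes carry a CDS that is a multiple of 3, starts ATG
#' and ends TAA (planted into the genome sequence). A fraction of genes get a
#' second annotated isoform skipping one internal exon. Deterministic per
#' (config, seed).
#'
#' @param cfg A `sim_config`.
#' @return List: `genome` (named character vector, `NULL` when
#'   `make_genome = FALSE`), `annotation`, `gene_biotype` (named vector).
#' @export
make_reference <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    genome <- if (cfg$make_genome)
      stats::setNames(lapply(chroms, function(ch)
        sample(BASES, cfg$chrom_length, replace = TRUE)), chroms)
    else NULL
    txs <- list()
    biotype <- character()
    cursor <- stats::setNames(rep(2000, cfg$n_chroms), chroms)
    reserve_tail <- 30000          # gene-free tail reserved for decoy peaks
    ci <- 1L
    for (g in seq_len(cfg$n_genes)) {
      placed <- FALSE
      for (try_ in seq_len(cfg$n_chroms)) {
        ch <- chroms[ci]
        n_ex <- sample(2:10, 1L)
        ex_len <- sample(90:250, n_ex, replace = TRUE)
        in_len <- if (n_ex > 1L) sample(600:1500, n_ex - 1L,
                                        replace = TRUE) else integer()
        span <- sum(ex_len) + sum(in_len)
        gap <- sample(1500:3000, 1L)
        if (cursor[ch] + span + gap <
            cfg$chrom_length - reserve_tail) {
          s <- cursor[ch]
          starts <- s + c(0, cumsum(ex_len[-n_ex] + in_len))
          exons <- cbind(starts, starts + ex_len)
          strand <- sample(c("+", "-"), 1L)
          gid <- sprintf("G%04d", g)
          coding <- stats::runif(1) > cfg$noncoding_fraction
          biotype[gid] <- if (coding) "coding" else "noncoding"
          cds <- NULL
          if (coding) {
            txlen <- sum(ex_len)
            s0 <- 31                      # 1-based tx coord of ATG
            cds_len <- ((txlen - s0 - 29) %/% 3) * 3
            if (cds_len >= 90) {
              tmp <- transcript_model("tmp", gid, ch, strand, exons)
              gpos <- tx_to_genomic(tmp)
              cds_pos <- gpos[s0:(s0 + cds_len - 1L)]
              cds <- c(min(cds_pos) - 1, max(cds_pos))
              if (cfg$make_genome) {
                write_codon <- function(tx_at, codon) {
                  pos <- gpos[tx_at:(tx_at + 2L)]
                  bases <- strsplit(codon, "")[[1L]]
                  if (strand == "-") bases <- chartr("ACGT", "TGCA", bases)
                  genome[[ch]][pos] <<- bases
                }
                write_codon(s0, "ATG")
                write_codon(s0 + cds_len - 3L, "TAA")
              }
            }
          }
          tid <- paste0(gid, ".T1")
          txs[[tid]] <- transcript_model(tid, gid, ch, strand, exons,
                                         cds = cds, source = "reference")
          if (n_ex >= 4L && stats::runif(1) < cfg$extra_isoform_fraction) {
            drop_i <- sample(2:(n_ex - 1L), 1L)
            tid2 <- paste0(gid, ".T2")
            txs[[tid2]] <- transcript_model(
              tid2, gid, ch, strand, exons[-drop_i, , drop = FALSE],
              source = "reference")
          }
          cursor[ch] <- s + span + gap
          placed <- TRUE
          break
        }
        ci <- if (ci == cfg$n_chroms) 1L else ci + 1L
      }
      if (!placed)
        stop("config error: genes do not fit the chromosomes")
      ci <- if (ci == cfg$n_chroms) 1L else ci + 1L
    }
    genome_str <- if (!is.null(genome))
      vapply(genome, paste, "", collapse = "") else NULL
    list(genome = genome_str,
         annotation = annotation(txs, gene_biotype = biotype),
         gene_biotype = biotype)
  })
}

all_sites <- function(idx_entry) c(idx_entry$donors, idx_entry$acceptors)

#' Inject novel features of every category into a reference
#'
#' Builds one novel transcript per injected feature: cassette exons placed in
#' intron interiors (frame-conserving ones are length-multiple-of-3 insertions
#' inside the CDS span of coding hosts, frameshifting ones are not),
#' donor/acceptor-side boundary shifts of internal exons, exons with both
#' boundaries shifted, exon-skipping junctions between annotated sites, novel
#' upstream TSS extensions, and exact antisense duplicates. The returned
#' TruthSet labels every injected transcript with its category, coding status
#' and (for cassette exons) the designed coverage pass/fail flag drawn with
#' `pass_fraction`.
#'
#' @param reference Output of [make_reference()].
#' @param cfg A `sim_config`.
#' @return List: `novel` (annotation of novel transcripts only) and `truth`
#'   (list with `transcripts` data.frame, `novel_exons` data.frame,
#'   `reference_exons`, and bookkeeping tables).
#' @export
inject_novel_features <- function(reference, cfg = sim_config()) {
  ref <- reference$annotation
  with_seed(cfg$seed + 1L, {
    idx <- ref$index
    inj <- cfg$injections
    site_taken <- new.env(parent = emptyenv())
    site_free <- function(key, pos) {
      e <- idx[[key]]
      k2 <- paste(key, pos)
      ok <- !(pos %in% all_sites(e)) &&
        !isTRUE(get0(k2, envir = site_taken))
      if (ok) assign(k2, TRUE, envir = site_taken)
      ok
    }
    primary <- Filter(function(t) endsWith(t$transcript_id, ".T1"),
                      ref$transcripts)
    coding_hosts <- Filter(function(t) !is.null(t$cds), primary)
    # slot allocator for cassette placement inside intron interiors
    slot_env <- new.env(parent = emptyenv())
    alloc_slot <- function(ch, is, ie, len, margin = 25L, spacer = 15L) {
      key <- paste(ch, is, ie)
      off <- get0(key, envir = slot_env, ifnotfound = is + margin)
      if (off + len + margin > ie) return(NULL)
      assign(key, off + len + spacer, envir = slot_env)
      c(off, off + len)
    }
    introns_in_cds <- function(t) {
      jx <- transcript_junctions(t)
      if (!nrow(jx) || is.null(t$cds)) return(jx[0, ])
      jx[jx$intron_start >= t$cds[1L] & jx$intron_end <= t$cds[2L], ,
         drop = FALSE]
    }
    nvt <- 0L
    new_id <- function() { nvt <<- nvt + 1L; sprintf("NVT%05d", nvt) }
    txs <- list()
    tr_rows <- list()
    nx_rows <- list()
    record <- function(t, category, fc = NA, coding = NA_character_,
                       pass = NA, exon = NULL) {
      txs[[t$transcript_id]] <<- t
      tr_rows[[length(tr_rows) + 1L]] <<- data.frame(
        transcript_id = t$transcript_id, category = category,
        gene_id = t$gene_id, frame_conserving = fc, coding_status = coding,
        pass = pass)
      if (!is.null(exon))
        nx_rows[[length(nx_rows) + 1L]] <<- data.frame(
          transcript_id = t$transcript_id, chrom = t$chrom,
          start = exon[1L], end = exon[2L], pass = pass)
    }

    # ---- cassette exons -------------------------------------------------
    n_cass <- inj$cassette
    if (n_cass > 0) {
      n_pass <- round(cfg$pass_fraction * n_cass)
      pass_flag <- rep(FALSE, n_cass)
      pass_flag[sample.int(n_cass, n_pass)] <- TRUE
      fc_flag <- rep(FALSE, n_cass)
      if (!is.null(cfg$coding_n_among_pass)) {
        pick <- shuffle(which(pass_flag))[seq_len(cfg$coding_n_among_pass)]
        fc_flag[pick] <- TRUE
      } else {
        n_fc <- min(inj$frame_conserving, n_cass)
        if (n_fc > 0) fc_flag[sample.int(n_cass, n_fc)] <- TRUE
      }
      cds_hosts <- Filter(function(t) nrow(introns_in_cds(t)) > 0,
                          coding_hosts)
      if (!length(cds_hosts))
        stop("config error: no coding host genes with CDS-internal introns")
      host_cycle <- shuffle(rep_len(seq_along(cds_hosts),
                                    max(n_cass, length(cds_hosts))))
      for (i in seq_len(n_cass)) {
        fc <- fc_flag[i]
        # frame semantics need insertion inside a CDS-span intron, so every
        # cassette is hosted by a coding gene with CDS-internal introns
        host <- cds_hosts[[host_cycle[(i - 1L) %% length(host_cycle) + 1L]]]
        cand <- introns_in_cds(host)
        len <- if (fc) sample(c(57, 60, 63), 1L) else
          sample(c(58, 59, 61, 62), 1L)
        slot <- NULL
        for (r in shuffle(seq_len(nrow(cand)))) {
          slot <- alloc_slot(host$chrom, cand$intron_start[r],
                             cand$intron_end[r], len)
          if (!is.null(slot)) break
        }
        if (is.null(slot)) {
          # retry across remaining hosts before declaring a config error
          for (h2 in shuffle(seq_along(cds_hosts))) {
            host <- cds_hosts[[h2]]
            cand <- introns_in_cds(host)
            for (r in seq_len(nrow(cand))) {
              slot <- alloc_slot(host$chrom, cand$intron_start[r],
                                 cand$intron_end[r], len)
              if (!is.null(slot)) break
            }
            if (!is.null(slot)) break
          }
        }
        if (is.null(slot))
          stop("config error: insufficient intronic room for cassette exons")
        ex <- rbind(host$exons, slot)
        t <- transcript_model(new_id(), host$gene_id, host$chrom,
                              host$strand, ex, source = "novel")
        coding <- if (fc && identical(reference$gene_biotype[[host$gene_id]],
                                      "coding")) "coding" else "noncoding"
        record(t, "cassette", fc = fc, coding = coding, pass = pass_flag[i],
               exon = slot)
      }
    }

    # ---- single-site shifts (donor / acceptor / both) -------------------
    shiftable <- Filter(function(t) nrow(t$exons) >= 3L, primary)
    shift_exon <- function(host, side) {
      # side: "donor", "acceptor" or "both"; expand into the intron so the
      # exon keeps overlapping its reference exon
      n <- nrow(host$exons)
      key <- paste(host$chrom, host$strand, sep = "|")
      for (i in shuffle(2:(n - 1L))) {
        ex <- host$exons
        d1 <- sample(5:12, 1L); d2 <- sample(5:12, 1L)
        # genomic boundary carrying the donor role: end on +, start on -
        new_start <- ex[i, 1L] - d1
        new_end <- ex[i, 2L] + d2
        start_role <- if (host$strand == "+") "acceptor" else "donor"
        end_role <- if (host$strand == "+") "donor" else "acceptor"
        move_start <- side == "both" || side == start_role
        move_end <- side == "both" || side == end_role
        if (move_start && !site_free(key, new_start)) next
        if (move_end && !site_free(key, new_end)) next
        if (move_start) ex[i, 1L] <- new_start
        if (move_end) ex[i, 2L] <- new_end
        return(ex)
      }
      NULL
    }
    for (cat in c("donor", "acceptor", "both")) {
      k <- inj[[cat]]
      if (is.null(k) || k == 0) next
      pool <- shuffle(rep_len(seq_along(shiftable), max(k, 1L)))
      done <- 0L; p <- 1L
      while (done < k) {
        if (p > length(pool))
          pool <- c(pool, shuffle(seq_along(shiftable)))
        host <- shiftable[[pool[p]]]; p <- p + 1L
        ex <- shift_exon(host, cat)
        if (is.null(ex)) next
        t <- transcript_model(new_id(), host$gene_id, host$chrom,
                              host$strand, ex, source = "novel")
        # 'both' exons overlap reference exons with background coverage, so
        # they are designed to pass validation
        moved <- which(apply(ex != host$exons, 1L, any))[1L]
        record(t, cat, pass = if (cat == "both") TRUE else NA,
               exon = if (cat == "both") ex[moved, ] else NULL)
        done <- done + 1L
      }
    }

    # ---- novel junctions between known sites (exon skipping) ------------
    k <- inj$junction_known
    if (!is.null(k) && k > 0) {
      skippable <- Filter(function(t) nrow(t$exons) >= 4L, primary)
      done <- 0L
      pool <- shuffle(rep_len(seq_along(skippable), max(k, 1L)))
      p <- 1L
      used <- character()
      while (done < k) {
        if (p > length(pool)) pool <- c(pool, shuffle(seq_along(skippable)))
        host <- skippable[[pool[p]]]; p <- p + 1L
        n <- nrow(host$exons)
        ok <- FALSE
        for (i in shuffle(2:(n - 1L))) {
          js <- host$exons[i - 1L, 2L]; je <- host$exons[i + 1L, 1L]
          key <- paste(host$chrom, host$strand, jx_key(js, je), sep = "|")
          if (key %in% used) next
          if (jx_key(js, je) %in%
              idx[[paste(host$chrom, host$strand, sep = "|")]]$junctions)
            next
          used <- c(used, key)
          t <- transcript_model(new_id(), host$gene_id, host$chrom,
                                host$strand,
                                host$exons[-i, , drop = FALSE],
                                source = "novel")
          record(t, "junction_known")
          ok <- TRUE
          break
        }
        if (ok) done <- done + 1L
      }
    }

    # ---- novel TSS -------------------------------------------------------
    k <- inj$tss
    if (!is.null(k) && k > 0) {
      hosts <- shuffle(rep_len(seq_along(primary), k))
      for (i in seq_len(k)) {
        host <- primary[[hosts[i]]]
        delta <- sample(300:800, 1L)
        ex <- host$exons
        if (host$strand == "+") ex[1L, 1L] <- max(1, ex[1L, 1L] - delta)
        else ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] + delta
        t <- transcript_model(new_id(), host$gene_id, host$chrom,
                              host$strand, ex, source = "novel")
        record(t, "tss")
      }
    }

    # ---- antisense duplicates -------------------------------------------
    k <- inj$antisense
    if (!is.null(k) && k > 0) {
      hosts <- sample(seq_along(primary), k)
      for (i in hosts) {
        host <- primary[[i]]
        t <- transcript_model(new_id(), paste0(host$gene_id, "_AS"),
                              host$chrom,
                              if (host$strand == "+") "-" else "+",
                              host$exons, source = "novel")
        record(t, "antisense", coding = "noncoding")
      }
    }

    ref_ex <- do.call(rbind, lapply(ref$transcripts, function(t)
      data.frame(chrom = t$chrom, start = t$exons[, 1L],
                 end = t$exons[, 2L])))
    truth <- list(
      transcripts = do.call(rbind, tr_rows),
      novel_exons = if (length(nx_rows)) do.call(rbind, nx_rows) else
        data.frame(transcript_id = character(), chrom = character(),
                   start = numeric(), end = numeric(), pass = logical()),
      reference_exons = ref_ex)
    list(novel = annotation(txs), truth = truth)
  })
}

#' Realise designed coverage and junction support from truth labels
#'
#' Reference exons get background depth 30; designed-pass novel exons get
#' uniform depth 20; designed-fail exons get depth 20 over only half their
#' length (violating the 75% rule). Junction split-read counts are set above
#' or below the validation threshold according to `junction_valid_fraction`.
#'
#' @param novel Novel `annotation` from [inject_novel_features()].
#' @param truth Its TruthSet.
#' @param cfg A `sim_config`.
#' @return List: `coverage` (a `coverage_track`), `junctions` (a
#'   `junction_support`), `junction_truth` (data.frame with `validated`).
#' @export
simulate_coverage <- function(novel, truth, cfg = sim_config()) {
  with_seed(cfg$seed + 2L, {
    bg <- 30; hi <- 20
    segs <- list()
    add_seg <- function(chrom, s, e, d) {
      if (e > s)
        segs[[length(segs) + 1L]] <<- data.frame(chrom = chrom, start = s,
                                                 end = e, depth = d)
    }
    ref_ex <- truth$reference_exons
    # collapse overlapping reference exons (isoforms share exons)
    for (ch in unique(ref_ex$chrom)) {
      d <- ref_ex[ref_ex$chrom == ch, ]
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
      for (i in seq_along(ir))
        add_seg(ch, IRanges::start(ir)[i] - 1, IRanges::end(ir)[i], bg)
    }
    nx <- truth$novel_exons
    for (i in seq_len(nrow(nx))) {
      s <- nx$start[i]; e <- nx$end[i]
      # clip to the part outside reference exons ('both' exons overlap them)
      d <- ref_ex[ref_ex$chrom == nx$chrom[i] &
                    ref_ex$start < e & ref_ex$end > s, ]
      pieces <- interval_subtract(s, e, cbind(d$start, d$end))
      if (isTRUE(nx$pass[i])) {
        for (r in seq_len(nrow(pieces)))
          add_seg(nx$chrom[i], pieces[r, 1L], pieces[r, 2L], hi)
      } else {
        # cover only half of the exon so the 75% rule fails
        half <- floor((e - s) / 2)
        for (r in seq_len(nrow(pieces))) {
          cutoff <- min(pieces[r, 2L], s + half)
          add_seg(nx$chrom[i], pieces[r, 1L], cutoff, hi)
        }
      }
    }
    cov <- do.call(rbind, segs)
    # designed segments are disjoint by construction; collapse exact dups
    cov <- unique(cov)
    track <- coverage_track(cov)

    jx_rows <- list()
    p <- validation_params()
    for (t in novel$transcripts) {
      jx <- transcript_junctions(t)
      if (!nrow(jx)) next
      jx_rows[[length(jx_rows) + 1L]] <- jx
    }
    jx <- unique(do.call(rbind, jx_rows))
    validated <- stats::runif(nrow(jx)) < cfg$junction_valid_fraction
    jx$read_count <- ifelse(validated, p$junction_min_reads + 5, 0)
    list(coverage = track,
         junctions = junction_support(jx),
         junction_truth = cbind(jx, validated = validated))
  })
}

#' Simulate a transcript-by-sample count matrix with planted DE and DTU
#'
#' Negative-binomial counts around a log-normal baseline for a
#' `samples_per_condition` vs `samples_per_condition` two-condition design.
#' `n_de` single-isoform genes get a true logFC of `de_logfc` (split
#' symmetrically across conditions); `n_dtu` two-isoform genes get an
#' isoform-fraction switch of `dtu_dif` while the gene total stays constant
#' (differential usage without gene-level differential expression).
#'
#' @param ann `annotation` (reference or merged) whose transcripts to
#'   quantify.
#' @param cfg A `sim_config`.
#' @return List: `counts` (matrix), `samples` (data.frame sample, condition,
#'   mix), `tx2gene`, `truth_de` (feature, true_logfc), `truth_dtu`
#'   (gene_id, true_dif, isoform_up, isoform_down).
#' @export
simulate_counts <- function(ann, cfg = sim_config()) {
  with_seed(cfg$seed + 3L, {
    n <- cfg$samples_per_condition
    cond <- rep(c("undifferentiated", "differentiated"), each = n)
    mix <- c(rep_len(c("A", "B"), n), rep_len(c("B", "A"), n))
    samples <- data.frame(sample = sprintf("S%02d", seq_len(2 * n)),
                          condition = cond, mix = mix)
    tids <- names(ann$transcripts)
    tx2gene <- vapply(ann$transcripts, `[[`, "", "gene_id")
    base <- stats::rlnorm(length(tids), cfg$baseline_meanlog,
                          cfg$baseline_sdlog)
    names(base) <- tids
    mu <- matrix(base, nrow = length(tids), ncol = 2 * n,
                 dimnames = list(tids, samples$sample))
    # planted DE among single-isoform genes
    n_iso <- table(tx2gene)
    single <- tids[tx2gene[tids] %in% names(n_iso)[n_iso == 1]]
    de_feats <- if (cfg$n_de > 0 && length(single))
      sample(single, min(cfg$n_de, length(single))) else character()
    # balanced directions (real data show near-equal up/down counts); an
    # unbalanced design would be partly absorbed by the normalization
    dir_ <- rep_len(c(1, -1), length(de_feats))
    half <- 2^(dir_ %o% rep(cfg$de_logfc / 2, sum(cond == "undifferentiated")))
    mu[de_feats, cond == "undifferentiated"] <-
      mu[de_feats, cond == "undifferentiated"] * half
    mu[de_feats, cond == "differentiated"] <-
      mu[de_feats, cond == "differentiated"] / half
    # planted DTU among multi-isoform genes, gene totals held fixed
    multi <- names(n_iso)[n_iso >= 2]
    multi <- setdiff(multi, unique(tx2gene[de_feats]))
    dtu_genes <- if (cfg$n_dtu > 0 && length(multi))
      sample(multi, min(cfg$n_dtu, length(multi))) else character()
    dtu_rows <- list()
    hi_f <- 0.5 + cfg$dtu_dif / 2
    lo_f <- 0.5 - cfg$dtu_dif / 2
    for (g in dtu_genes) {
      iso <- tids[tx2gene[tids] == g][1:2]
      tot <- sum(base[iso])
      mu[iso[1L], cond == "undifferentiated"] <- tot * hi_f
      mu[iso[2L], cond == "undifferentiated"] <- tot * lo_f
      mu[iso[1L], cond == "differentiated"] <- tot * lo_f
      mu[iso[2L], cond == "differentiated"] <- tot * hi_f
      dtu_rows[[g]] <- data.frame(gene_id = g, true_dif = cfg$dtu_dif,
                                  isoform_up = iso[1L],
                                  isoform_down = iso[2L])
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$nb_dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    list(counts = counts, samples = samples, tx2gene = tx2gene,
         truth_de = data.frame(feature = de_feats,
                               true_logfc = dir_ * cfg$de_logfc),
         truth_dtu = if (length(dtu_rows)) do.call(rbind, dtu_rows) else
           data.frame(gene_id = character(), true_dif = numeric(),
                      isoform_up = character(), isoform_down = character()))
  })
}

#' Simulate sequin spike-in mixes and per-sample counts
#'
#' Concentrations form a two-fold ladder; mix B differs from mix A by ratios
#' in {1/4, 1/2, 1, 2, 4}. Counts are proportional to concentration above the
#' detection floor `sequin_cstar` and flat at the floor level below it, with
#' NB noise (or exact means when `sequin_noise = FALSE`). Mixes alternate
#' across samples within each condition, so both mixes occur in both
#' conditions.
#'
#' @param cfg A `sim_config`.
#' @return List: `mix` (a `sequin_mix`), `counts` (sequin x sample),
#'   `samples` (sample, condition, mix), `cstar`.
#' @export
simulate_sequins <- function(cfg = sim_config()) {
  with_seed(cfg$seed + 4L, {
    n <- cfg$samples_per_condition
    cond <- rep(c("undifferentiated", "differentiated"), each = n)
    mix_assign <- c(rep_len(c("A", "B"), n), rep_len(c("B", "A"), n))
    samples <- data.frame(sample = sprintf("S%02d", seq_len(2 * n)),
                          condition = cond, mix = mix_assign)
    ns <- cfg$n_sequins
    levels_ <- 0.01 * 2^(0:14)
    concA <- levels_[(seq_len(ns) - 1L) %% length(levels_) + 1L]
    ratio <- c(0.25, 0.5, 1, 2, 4)[(seq_len(ns) - 1L) %% 5L + 1L]
    mix <- sequin_mix(data.frame(
      sequin_id = sprintf("SQ%03d", seq_len(ns)),
      mixA_conc = concA, mixB_conc = concA * ratio,
      length = sample(500:2500, ns, replace = TRUE)))
    eff <- function(conc) pmax(conc, cfg$sequin_cstar)
    counts <- matrix(0, nrow = ns, ncol = 2 * n,
                     dimnames = list(mix$sequin_id, samples$sample))
    for (s in seq_len(2 * n)) {
      conc <- if (mix_assign[s] == "A") mix$mixA_conc else mix$mixB_conc
      m <- cfg$sequin_scale * eff(conc) * mix$length / 1000
      counts[, s] <- if (cfg$sequin_noise)
        stats::rnbinom(ns, mu = m, size = 1 / cfg$sequin_dispersion)
      else round(m)
    }
    list(mix = mix, counts = counts, samples = samples,
         cstar = cfg$sequin_cstar)
  })
}

#' Place CAGE peaks supporting a subset of novel TSS transcripts
#'
#' A `hit_fraction` subset of novel-TSS transcripts receives a 20 bp peak
#' inside its +/- 500 bp TSS window; decoy peaks are placed in the reserved
#' gene-free tail of each chromosome.
#'
#' @param novel Novel `annotation`.
#' @param truth TruthSet from [inject_novel_features()].
#' @param cfg A `sim_config`; `cage_hit_fraction` controls support.
#' @return List: `peaks` (a `cage_peaks`), `supported_ids` (character).
#' @export
make_cage_peaks <- function(novel, truth, cfg = sim_config()) {
  with_seed(cfg$seed + 5L, {
    tss_tx <- truth$transcripts$transcript_id[
      truth$transcripts$category == "tss"]
    k <- round(cfg$cage_hit_fraction * length(tss_tx))
    hit <- if (k > 0) sample(tss_tx, k) else character()
    rows <- list()
    for (id in hit) {
      t <- novel$transcripts[[id]]
      pos <- tx_tss(t)
      s <- max(0, pos - 100)
      rows[[length(rows) + 1L]] <- data.frame(chrom = t$chrom, start = s,
                                              end = s + 20, strand = t$strand)
    }
    chroms <- unique(vapply(novel$transcripts, `[[`, "", "chrom"))
    for (ch in chroms) {
      base <- cfg$chrom_length - 20000
      for (j in 1:10)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = base + j * 150, end = base + j * 150 + 20,
          strand = "*")
    }
    list(peaks = cage_peaks(do.call(rbind, rows)), supported_ids = hit)
  })
}

#' Write a synthetic FASTA genome
#' @param genome Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(unlist(genome))
  names(dss) <- names(genome)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- as.character(dss)
  names(out) <- sub("\\s.*$", "", names(dss))
  out
}

#' Synthetic labelled training sequences for the coding-potential model
#'
#' Coding-class sequences carry a long planted ORF (stop-free in frame, with
#' codon usage biased away from uniform); noncoding-class sequences are
#' uniform random nucleotides. Separable by design; used to train the default
#' pipeline model.
#'
#' @param n_per_class Sequences per class.
#' @param seed RNG seed.
#' @return List with `coding` and `noncoding` character vectors.
#' @export
make_training_sequences <- function(n_per_class = 40, seed = 1) {
  with_seed(seed, {
    codons <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
    sense <- setdiff(codons, STOP_CODONS)
    # biased codon usage for the coding class
    w <- stats::runif(length(sense))^2
    coding <- vapply(seq_len(n_per_class), function(i) {
      n_cod <- sample(120:260, 1L)
      orf <- paste0("ATG",
                    paste(sample(sense, n_cod, replace = TRUE, prob = w),
                          collapse = ""), "TAA")
      utr5 <- paste(sample(BASES, sample(20:80, 1L), replace = TRUE),
                    collapse = "")
      utr3 <- paste(sample(BASES, sample(20:80, 1L), replace = TRUE),
                    collapse = "")
      paste0(utr5, orf, utr3)
    }, "")
    noncoding <- vapply(seq_len(n_per_class), function(i)
      paste(sample(BASES, sample(400:900, 1L), replace = TRUE),
            collapse = ""), "")
    list(coding = coding, noncoding = noncoding)
  })
}
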