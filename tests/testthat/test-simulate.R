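test_that("generation is a pure function of (config, seed)", {
  cfg <- small_cfg(seed = 61)
  r1 <- make_reference(cfg)
  r2 <- make_reference(cfg)
  expect_identical(r1$genome, r2$genome)
  expect_true(annotation_equal(r1$annotation, r2$annotation))
  i1 <- inject_novel_features(r1, cfg)
  i2 <- inject_novel_features(r2, cfg)
  expect_true(annotation_equal(i1$novel, i2$novel))
  expect_identical(i1$truth$transcripts, i2$truth$transcripts)
  cfg_b <- small_cfg(seed = 62)
  expect_false(identical(make_reference(cfg_b)$genome, r1$genome))
})

test_that("reference CDS are codon-complete with ATG starts and stops", {
  cfg <- small_cfg(seed = 63)
  ref <- make_reference(cfg)
  genome <- ref$genome
  coding <- Filter(function(t) !is.null(t$cds), ref$annotation$transcripts)
  expect_gt(length(coding), 5)
  for (t in coding[seq_len(min(10, length(coding)))]) {
    seq <- transcript_sequence(t, genome)
    seg <- 0
    # locate CDS in transcript coordinates via the genomic span
    exonic_before <- function(gpos) {
      # exonic bases 5' of gpos (transcript orientation)
      if (t$strand == "+")
        sum(pmax(0, pmin(t$exons[, 2], gpos) - t$exons[, 1]))
      else
        sum(pmax(0, t$exons[, 2] - pmax(t$exons[, 1], gpos + 1)))
    }
    cds_start_g <- if (t$strand == "+") t$cds[1] else t$cds[2] - 1
    off <- exonic_before(cds_start_g)
    len <- sum(pmax(0, pmin(t$exons[, 2], t$cds[2]) -
                      pmax(t$exons[, 1], t$cds[1])))
    expect_equal(len %% 3, 0)
    cds_seq <- substr(seq, off + 1, off + len)
    expect_equal(substr(cds_seq, 1, 3), "ATG")
    expect_equal(substr(cds_seq, len - 2, len), "TAA")
  }
})

test_that("injected categories are recovered with precision = recall = 1", {
  cfg <- small_cfg(seed = 64)
  ref <- make_reference(cfg)
  inj <- inject_novel_features(ref, cfg)
  truth <- inj$truth$transcripts
  reports <- lapply(inj$novel$transcripts, classify_transcript,
                    reference = ref$annotation)
  tab <- novelty_table(reports)
  m <- merge(tab, truth, by = "transcript_id")
  expect_equal(nrow(m), nrow(truth))
  pure <- function(cat, col) {
    sub <- m[m$category == cat, ]
    others <- setdiff(c("n_cassette", "n_novel_donor", "n_novel_acceptor",
                        "n_both_novel", "n_novel_junction_known"), col)
    all(sub[[col]] == 1) && all(sub[others] == 0) &&
      !any(sub$novel_tss) && !any(sub$novel_tts)
  }
  expect_true(pure("cassette", "n_cassette"))
  expect_true(pure("donor", "n_novel_donor"))
  expect_true(pure("acceptor", "n_novel_acceptor"))
  expect_true(pure("both", "n_both_novel"))
  expect_true(pure("junction_known", "n_novel_junction_known"))
  tss_sub <- m[m$category == "tss", ]
  expect_true(all(tss_sub$novel_tss) && !any(tss_sub$novel_tts))
  expect_true(all(tss_sub[c("n_cassette", "n_novel_donor",
                            "n_novel_acceptor", "n_both_novel",
                            "n_novel_junction_known")] == 0))
  # no false novelty outside the injected category (precision); antisense
  # duplicates are excluded: they mirror reference models on the opposite
  # strand and are removed before classification in the pipeline
  non_cassette <- m[!(m$category %in% c("cassette", "antisense")), ]
  expect_true(all(non_cassette$n_cassette == 0))
  # antisense duplicates: all and only the injected ones
  found <- detect_antisense_duplicates(inj$novel, ref$annotation)
  expect_setequal(found, truth$transcript_id[truth$category == "antisense"])
})

test_that("designed coverage drives the filter to exactly the truth-pass set", {
  cfg <- small_cfg(seed = 65,
                   injections = list(cassette = 40, frame_conserving = 10,
                                     donor = 0, acceptor = 0, both = 5,
                                     junction_known = 0, tss = 0,
                                     antisense = 0),
                   pass_fraction = 0.7)
  ref <- make_reference(cfg)
  inj <- inject_novel_features(ref, cfg)
  cov <- simulate_coverage(inj$novel, inj$truth, cfg)
  reports <- lapply(inj$novel$transcripts, classify_transcript,
                    reference = ref$annotation)
  out <- filter_by_exon_coverage(inj$novel, reports, cov$coverage)
  truth <- inj$truth$transcripts
  expect_setequal(out$removed_ids,
                  truth$transcript_id[truth$category == "cassette" &
                                        !truth$pass])
  expect_equal(sum(truth$category == "cassette" & truth$pass), 28)
  # junction support realises the designed validation labels
  jt <- cov$junction_truth
  p <- validation_params()
  got <- vapply(seq_len(nrow(jt)), function(i)
    junction_validated(jt$chrom[i], jt$strand[i], jt$intron_start[i],
                       jt$intron_end[i], cov$junctions, p), NA)
  expect_equal(got, jt$validated)
})

test_that("planted counts: DE recovery, DTU without gene-level DE", {
  cfg <- small_cfg(seed = 66, n_de = 12, n_dtu = 6)
  ref <- make_reference(cfg)
  cnt <- simulate_counts(ref$annotation, cfg)
  design <- factor(cnt$samples$condition,
                   levels = c("undifferentiated", "differentiated"))
  m <- cnt$counts[rowSums(cnt$counts) > 0, ]
  res <- de_test(m, design, tmm_factors(m))
  truth <- cnt$truth_de
  got_lfc <- res$logFC[match(truth$feature, res$feature)]
  expect_true(all(abs(got_lfc - truth$true_logfc) < 1.0))
  expect_lt(mean(abs(got_lfc - truth$true_logfc)), 0.5)
  # DTU genes: usage switch detected, gene totals not DE
  ifm <- isoform_fractions(m, cnt$tx2gene)
  dtu <- dtu_switch_test(ifm, design, seed = 4)
  is_planted <- dtu$genes$gene_id %in% cnt$truth_dtu$gene_id
  # ranking by switch score recovers the planted genes (high AUC)
  r <- rank(dtu$genes$switch_score)
  auc <- (mean(r[is_planted]) - (sum(is_planted) + 1) / 2) /
    sum(!is_planted)
  expect_gt(auc, 0.9)
  expect_true(all(dtu$genes$p_value[is_planted] <= 0.1))
  g <- aggregate_gene_counts(m, cnt$tx2gene)
  gres <- de_test(g, design, tmm_factors(g))
  g_hits <- threshold_filter(gres)
  expect_false(any(cnt$truth_dtu$gene_id %in% g_hits$feature))
})

test_that("sequin generation: assignment, floor recovery, noise-free R2", {
  cfg <- small_cfg(seed = 67)
  sq <- simulate_sequins(cfg)
  expect_true(all(table(sq$samples$condition, sq$samples$mix) > 0))
  # LOQ recovery within one grid step per mix
  grid <- sort(unique(sq$mix$mixA_conc))
  tpm <- tpm_from_counts(sq$counts,
                         stats::setNames(sq$mix$length, sq$mix$sequin_id))
  for (mx in c("A", "B")) {
    cols <- sq$samples$sample[sq$samples$mix == mx]
    conc <- if (mx == "A") sq$mix$mixA_conc else sq$mix$mixB_conc
    obs <- as.vector(tpm[sq$mix$sequin_id, cols])
    fit <- estimate_loq(rep(conc, times = length(cols)), obs)
    allg <- sort(unique(conc))
    i_hat <- which(abs(allg - fit$breakpoint_concentration) < 1e-12)
    i_true <- which(abs(allg - sq$cstar) < 1e-12)
    expect_lte(abs(i_hat - i_true), 1)
  }
  # noise-free generation: expected == observed for fully detected sequins
  cfg0 <- small_cfg(seed = 68, sequin_noise = FALSE)
  sq0 <- simulate_sequins(cfg0)
  detected <- sq0$mix$mixA_conc >= sq0$cstar & sq0$mix$mixB_conc >= sq0$cstar
  mean_a <- rowMeans(sq0$counts[, sq0$samples$mix == "A"])
  mean_b <- rowMeans(sq0$counts[, sq0$samples$mix == "B"])
  obs <- log2(mean_b / mean_a)
  exp_ <- expected_logfc(sq0$mix)
  rep_ <- sensitivity_report(exp_[detected], obs[detected])
  expect_gt(rep_$r_squared, 0.999)
})

test_that("CAGE peak placement is recovered by the intersection", {
  cfg <- small_cfg(seed = 69, cage_hit_fraction = 0.5)
  ref <- make_reference(cfg)
  inj <- inject_novel_features(ref, cfg)
  cage <- make_cage_peaks(inj$novel, inj$truth, cfg)
  tss_ids <- inj$truth$transcripts$transcript_id[
    inj$truth$transcripts$category == "tss"]
  win <- do.call(rbind, lapply(tss_ids, function(id) {
    t <- inj$novel$transcripts[[id]]
    v <- tss_window(t, "symmetric", 500)
    data.frame(transcript_id = id, chrom = t$chrom,
               start = v[["start"]], end = v[["end"]])
  }))
  out <- intersect_cage(win, cage$peaks)
  supported <- out$per_id$transcript_id[out$per_id$n_peaks > 0]
  expect_setequal(supported, cage$supported_ids)
  # hit_fraction 0 supports nothing
  cfg0 <- small_cfg(seed = 69, cage_hit_fraction = 0)
  cage0 <- make_cage_peaks(inj$novel, inj$truth, cfg0)
  out0 <- intersect_cage(win, cage0$peaks)
  expect_equal(out0$summary$n_supported_transcripts, 0L)
})
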