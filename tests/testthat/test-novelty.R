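test_that("self-classification of reference transcripts is empty", {
  cfg <- small_cfg(seed = 21, make_genome = FALSE)
  ref <- make_reference(cfg)$annotation
  for (t in ref$transcripts[seq_len(20)]) {
    r <- classify_transcript(t, ref)
    expect_equal(nrow(r$cassette_exons), 0L)
    expect_length(r$novel_donor_sites, 0L)
    expect_length(r$novel_acceptor_sites, 0L)
    expect_equal(r$both_novel_exons, 0L)
    expect_equal(nrow(r$novel_junctions_known_sites), 0L)
    expect_false(r$novel_tss)
    expect_false(r$novel_tts)
  }
})

test_that("worked novelty examples: cassette, shifted acceptor, no-context", {
  ref <- ref3()
  # internal exon inside the intron, no boundary in the site sets
  cass <- mk_tx("c", c(100, 200, 430, 490, 500, 600), source = "novel")
  r <- classify_transcript(cass, ref)
  expect_equal(unname(r$cassette_exons), matrix(c(430, 490), ncol = 2))
  expect_length(r$novel_donor_sites, 0L)
  expect_length(r$novel_acceptor_sites, 0L)
  expect_false(r$novel_tss)

  # acceptor of middle exon shifted +12 on + strand (3' site)
  acc <- mk_tx("a", c(100, 200, 312, 400, 500, 600), source = "novel")
  r2 <- classify_transcript(acc, ref)
  expect_equal(r2$novel_acceptor_sites, 312)
  expect_length(r2$novel_donor_sites, 0L)
  expect_equal(nrow(r2$cassette_exons), 0L)

  # chromosome absent from the reference: all novel, flagged, no error
  far <- mk_tx("f", c(10, 50, 100, 150), chrom = "chrX", source = "novel")
  r3 <- classify_transcript(far, ref)
  expect_true(r3$no_reference_context)
  expect_true(r3$novel_tss)
})

test_that("antisense duplicate detection is exact", {
  ref <- ref3(strand = "+")
  exact <- annotation(list(
    mk_tx("as1", c(100, 200, 300, 400, 500, 600), strand = "-",
          gene = "gA", source = "novel")))
  expect_equal(detect_antisense_duplicates(exact, ref), "as1")
  same_strand <- annotation(list(
    mk_tx("s1", c(100, 200, 300, 400, 500, 600), strand = "+",
          gene = "gA", source = "novel")))
  expect_length(detect_antisense_duplicates(same_strand, ref), 0L)
  off_by_one <- annotation(list(
    mk_tx("o1", c(100, 201, 300, 400, 500, 600), strand = "-",
          gene = "gA", source = "novel")))
  expect_length(detect_antisense_duplicates(off_by_one, ref), 0L)
})

test_that("end-site novelty respects the configured tolerance", {
  ref <- ref3()
  t_same <- mk_tx("t", c(100, 200, 500, 600), source = "novel")
  expect_false(classify_end_sites(t_same, ref, 0)[["novel_tss"]])
  t_far <- mk_tx("t", c(700, 800), source = "novel")   # 600 bp from TSS 100
  expect_true(classify_end_sites(t_far, ref, 0)[["novel_tss"]])
  t_near <- mk_tx("t", c(130, 200, 500, 600), source = "novel")  # 30 bp off
  expect_true(classify_end_sites(t_near, ref, 0)[["novel_tss"]])
  expect_false(classify_end_sites(t_near, ref, 50)[["novel_tss"]])
})

test_that("aggregate_catalog equals a brute-force recount", {
  expect_equal(aggregate_catalog(list())$n_transcripts, 0L)
  ref <- ref3()
  txs <- list(
    mk_tx("c1", c(100, 200, 430, 490, 500, 600), source = "novel"),
    mk_tx("c2", c(100, 200, 410, 470, 500, 600), source = "novel"),
    mk_tx("a1", c(100, 200, 312, 400, 500, 600), source = "novel"))
  reports <- lapply(txs, classify_transcript, reference = ref)
  cat_ <- aggregate_catalog(reports)
  expect_equal(cat_$n_cassette_exons,
               sum(vapply(reports, function(r) nrow(r$cassette_exons), 0L)))
  expect_equal(cat_$n_cassette_exons, 2L)
  expect_equal(cat_$n_novel_acceptor, 1L)
  expect_equal(cat_$n_unique_novel_acceptor, 1L)
})

test_that("classification matches the naive oracle on randomized instances", {
  cfg <- small_cfg(seed = 22, make_genome = FALSE)
  ref <- make_reference(cfg)$annotation
  multi <- Filter(function(t) nrow(t$exons) >= 4, ref$transcripts)
  set.seed(101)
  for (rep_ in seq_len(200)) {
    host <- multi[[sample.int(length(multi), 1)]]
    ex <- host$exons
    op <- sample(c("cassette", "shift_start", "shift_end", "both", "skip",
                   "tss"), 1)
    n <- nrow(ex)
    i <- sample(2:(n - 1), 1)
    if (op == "cassette") {
      gap_s <- ex[i - 1, 2]; gap_e <- ex[i, 1]
      if (gap_e - gap_s < 140) next
      s <- gap_s + sample(30:60, 1); ex <- rbind(ex, c(s, s + 50))
      ex <- ex[order(ex[, 1]), ]
    } else if (op == "shift_start") ex[i, 1] <- ex[i, 1] - sample(3:15, 1)
    else if (op == "shift_end") ex[i, 2] <- ex[i, 2] + sample(3:15, 1)
    else if (op == "both") {
      ex[i, 1] <- ex[i, 1] - sample(3:15, 1)
      ex[i, 2] <- ex[i, 2] + sample(3:15, 1)
    } else if (op == "skip") ex <- ex[-i, ]
    else if (op == "tss") {
      if (host$strand == "+") ex[1, 1] <- max(0, ex[1, 1] - sample(200:600, 1))
      else ex[n, 2] <- ex[n, 2] + sample(200:600, 1)
    }
    t <- transcript_model("q", host$gene_id, host$chrom, host$strand, ex,
                          source = "novel")
    got <- classify_transcript(t, ref)
    want <- oracle_novelty(t, ref)
    expect_equal(nrow(got$cassette_exons), want$cassette, info = op)
    expect_equal(length(got$novel_donor_sites), want$donor, info = op)
    expect_equal(length(got$novel_acceptor_sites), want$acceptor, info = op)
    expect_equal(got$both_novel_exons, want$both, info = op)
    expect_equal(nrow(got$novel_junctions_known_sites), want$jknown,
                 info = op)
    expect_equal(unname(got$novel_tss), want$novel_tss, info = op)
    expect_equal(unname(got$novel_tts), want$novel_tts, info = op)
  }
})

test_that("category disjointness: cassette exons stay out of site tallies", {
  ref <- ref3()
  # cassette exon plus a shifted donor elsewhere in the same transcript
  t <- mk_tx("x", c(100, 212, 430, 490, 500, 600), source = "novel")
  r <- classify_transcript(t, ref)
  expect_equal(nrow(r$cassette_exons), 1L)
  expect_equal(r$novel_donor_sites, 212)     # first exon's shifted donor
  expect_length(r$novel_acceptor_sites, 0L)
  expect_equal(r$both_novel_exons, 0L)
})
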