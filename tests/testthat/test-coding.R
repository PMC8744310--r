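test_that("longest ORF scanning across frames", {
  orf <- longest_orf("ATGAAATAA")
  expect_equal(orf[c("start", "end", "length")],
               list(start = 0, end = 9, length = 9))
  expect_true(orf$complete)
  expect_null(longest_orf("CCCCCC"))
  # frame 1 carries the longer ORF (built explicitly)
  seq <- paste0("ATG", strrep("AAA", 9), "TAA",      # frame 0: 33 nt
                "C",                                  # shift to frame 1
                "ATG", strrep("GGG", 19), "TAA")      # frame 1: 63 nt
  orf2 <- longest_orf(seq)
  expect_equal(orf2$length, 63)
  expect_equal(orf2$frame, (33 + 1) %% 3)
  # incomplete ORF: no stop before the 3' end
  orf3 <- longest_orf(paste0("CC", "ATG", strrep("GCA", 10)))
  expect_false(orf3$complete)
  expect_equal(orf3$length %% 3, 0)
})

test_that("Fickett score matches the independent table oracle", {
  set.seed(7)
  seqs <- c(
    strrep("ACGT", 30),
    vapply(1:40, function(i)
      paste(sample(c("A", "C", "G", "T"), sample(50:400, 1), replace = TRUE),
            collapse = ""), ""))
  for (s in seqs)
    expect_equal(fickett_score(s), oracle_fickett(s))
  # bounded by the extremes attainable from the tables
  lo <- sum(c(0.22, 0.23, 0.08, 0.09) * c(0.26, 0.18, 0.31, 0.33)) +
    sum(c(0.21, 0.31, 0.29, 0.24) * c(0.11, 0.12, 0.15, 0.14))
  hi <- sum(c(0.94, 0.81, 0.90, 0.97) * c(0.26, 0.18, 0.31, 0.33)) +
    sum(c(0.81, 0.82, 0.73, 0.75) * c(0.11, 0.12, 0.15, 0.14))
  sc <- vapply(seqs, fickett_score, 0)
  expect_true(all(sc >= lo - 1e-12 & sc <= hi + 1e-12))
  # composition terms are order-invariant: reversal keeps them equal for a
  # sequence whose positional parameters are symmetric (homopolymer)
  expect_equal(fickett_score(strrep("A", 60)),
               fickett_score(paste(rev(strsplit(strrep("A", 60), "")[[1]]),
                                   collapse = "")))
})

test_that("hexamer table and score behave as defined", {
  set.seed(8)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  train <- vapply(rep(200, 25), rnd, "")
  tab0 <- build_hexamer_table(train, train)
  expect_true(all(abs(tab0) < 1e-12))
  expect_equal(hexamer_score(rnd(90), tab0), 0)
  expect_error(hexamer_score("ACGTA", tab0), "sequence_too_short")
  # separable training data: held-out coding sequences score higher
  tr <- make_training_sequences(60, seed = 3)
  tab <- build_hexamer_table(tr$coding[1:40], tr$noncoding[1:40])
  held_c <- vapply(tr$coding[41:60], hexamer_score, 0, table = tab)
  held_n <- vapply(tr$noncoding[41:60], hexamer_score, 0, table = tab)
  expect_gt(mean(held_c), mean(held_n))
})

test_that("coding model trains, separates and respects the threshold", {
  tr <- make_training_sequences(40, seed = 5)
  model <- train_coding_model(tr$coding, tr$noncoding)
  expect_equal(model$threshold, 0.364)
  pc <- vapply(tr$coding, coding_probability, 0, model = model)
  pn <- vapply(tr$noncoding, coding_probability, 0, model = model)
  expect_true(all(pc >= 0 & pc <= 1) && all(pn >= 0 & pn <= 1))
  # separable classes: training accuracy 1
  expect_true(all(pc >= model$threshold))
  expect_true(all(pn < model$threshold))
  # probability is monotone in ORF length with other features near-fixed
  short_orf <- paste0(strrep("CT", 30), "ATG", strrep("GCA", 15), "TAA",
                      strrep("CT", 200))
  long_orf <- paste0(strrep("CT", 30), "ATG", strrep("GCA", 150), "TAA",
                     strrep("CT", 200))
  expect_gte(coding_probability(long_orf, model),
             coding_probability(short_orf, model))
  expect_error(train_coding_model(tr$coding[1:5], tr$noncoding), "20")
})

test_that("frame conservation agrees with a translation oracle", {
  # gene on a codon-safe chromosome; CDS spans two exons
  n_codons <- 400
  chrom <- gca_chrom(n_codons)
  # exons [30, 330) and [600, 900): CDS from 60 to 840
  chrom <- plant(chrom, 61, "ATG")          # CDS start at 0-based 60
  ref_t <- mk_tx("r1", c(30, 330, 600, 900), cds = c(60, 840))
  ref <- annotation(list(ref_t))
  genome <- list(chr1 = chrom)

  run_case <- function(len) {
    s <- 400
    nov <- mk_tx("n1", c(30, 330, s, s + len, 600, 900), source = "novel")
    rep_ <- classify_transcript(nov, ref)
    fc <- frame_conservation(nov, rep_, ref)
    # oracle: translate both CDS-anchored sequences and compare the suffix
    seq_r <- transcript_sequence(ref_t, genome)
    seq_n <- transcript_sequence(nov, genome)
    aa_r <- oracle_translate(substr(seq_r, 31, nchar(seq_r)))
    aa_n <- oracle_translate(substr(seq_n, 31, nchar(seq_n)))
    tail_r <- substr(aa_r, nchar(aa_r) - 20, nchar(aa_r))
    tail_n <- substr(aa_n, nchar(aa_n) - 20, nchar(aa_n))
    list(fc = fc, suffix_same = identical(tail_r, tail_n))
  }
  c57 <- run_case(57)
  expect_true(c57$fc)
  expect_true(c57$suffix_same)
  c58 <- run_case(58)
  expect_false(c58$fc)
  expect_false(c58$suffix_same)
  # 58 bp cassette wholly in the 5' UTR (outside the CDS span) conserves
  ref_u <- annotation(list(mk_tx("rU", c(30, 100, 400, 900),
                                 cds = c(500, 800))))
  utr <- mk_tx("nU", c(30, 100, 200, 258, 400, 900), source = "novel")
  rep_u <- classify_transcript(utr, ref_u)
  expect_true(frame_conservation(utr, rep_u, ref_u))
})

test_that("coding decision tree applies reasons in order", {
  ncr <- annotation(list(mk_tx("r1", c(100, 200, 500, 600), gene = "gN")),
                    gene_biotype = c(gN = "noncoding"))
  nov <- mk_tx("n1", c(100, 200, 300, 360, 500, 600), gene = "gN",
               source = "novel")
  call1 <- classify_coding_status(nov, classify_transcript(nov, ncr), ncr)
  expect_equal(call1$status, "noncoding")
  expect_equal(call1$reason, "noncoding_parent")

  chrom <- plant(gca_chrom(400), 61, "ATG")
  ref <- annotation(list(mk_tx("r1", c(30, 330, 600, 900),
                               cds = c(60, 840))))
  fcx <- mk_tx("n2", c(30, 330, 400, 457, 600, 900), source = "novel")
  call2 <- classify_coding_status(fcx, classify_transcript(fcx, ref), ref)
  expect_equal(call2$reason, "frame_conserving")
  expect_equal(call2$status, "coding")
  fsx <- mk_tx("n3", c(30, 330, 400, 458, 600, 900), source = "novel")
  call3 <- classify_coding_status(fsx, classify_transcript(fsx, ref), ref)
  expect_equal(call3$reason, "frameshift")

  # TSS-only novelty defers to the model; threshold is inclusive
  tr <- make_training_sequences(40, seed = 5)
  model <- train_coding_model(tr$coding, tr$noncoding)
  tssx <- mk_tx("n4", c(10, 330, 600, 900), source = "novel")
  genome <- list(chr1 = plant(gca_chrom(400), 61, "ATG"))
  call4 <- classify_coding_status(tssx, classify_transcript(tssx, ref), ref,
                                  model = model, genome = genome)
  expect_true(call4$reason %in% c("cpat_coding", "cpat_noncoding"))
  expect_false(is.na(call4$probability))
  expect_equal(call4$status,
               if (call4$probability >= model$threshold) "coding"
               else "noncoding")
  # model required when the tree reaches it
  expect_error(classify_coding_status(tssx, classify_transcript(tssx, ref),
                                      ref), "model")
})
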