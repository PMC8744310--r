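ev_types <- function(evs) sort(vapply(evs, `[[`, "", "type"))

test_that("pairwise event taxonomy on worked examples", {
  a <- mk_tx("a", c(100, 200, 300, 400, 500, 600))
  b <- mk_tx("b", c(100, 200, 500, 600))
  expect_equal(ev_types(pairwise_events(a, b)), "ES")

  # intron retention: [100,400) vs [100,200)+[300,400)
  a2 <- mk_tx("a2", c(100, 400, 500, 600))
  b2 <- mk_tx("b2", c(100, 200, 300, 400, 500, 600))
  expect_equal(ev_types(pairwise_events(a2, b2)), "IR")

  # different non-overlapping first exons, shared downstream chain
  a3 <- mk_tx("a3", c(100, 150, 500, 600, 700, 800))
  b3 <- mk_tx("b3", c(300, 360, 500, 600, 700, 800))
  expect_equal(ev_types(pairwise_events(a3, b3)), "ATSS")

  # A5: shifted donor with overlapping upstream exons (+ strand)
  a4 <- mk_tx("a4", c(100, 200, 500, 600))
  b4 <- mk_tx("b4", c(100, 230, 500, 600))
  expect_equal(ev_types(pairwise_events(a4, b4)), "A5")

  # A3: shifted acceptor, overlapping downstream exons
  a5 <- mk_tx("a5", c(100, 200, 500, 600))
  b5 <- mk_tx("b5", c(100, 200, 530, 600))
  expect_equal(ev_types(pairwise_events(a5, b5)), "A3")

  # on the minus strand the same genomic shift is the opposite side
  a6 <- mk_tx("a6", c(100, 200, 500, 600), strand = "-")
  b6 <- mk_tx("b6", c(100, 230, 500, 600), strand = "-")
  expect_equal(ev_types(pairwise_events(a6, b6)), "A3")

  # MEE: exclusive non-overlapping internal exons, shared flanks
  a7 <- mk_tx("a7", c(100, 200, 300, 350, 500, 600))
  b7 <- mk_tx("b7", c(100, 200, 400, 450, 500, 600))
  expect_equal(ev_types(pairwise_events(a7, b7)), "MEE")

  # MES: two consecutive skipped exons bridged by one junction
  a8 <- mk_tx("a8", c(100, 200, 250, 280, 320, 360, 500, 600))
  b8 <- mk_tx("b8", c(100, 200, 500, 600))
  expect_equal(ev_types(pairwise_events(a8, b8)), "MES")

  expect_error(pairwise_events(a, mk_tx("z", c(1, 10), gene = "other")),
               "one gene")
})

test_that("events are invariant under genomic translation", {
  shift_tx <- function(t, k) {
    transcript_model(t$transcript_id, t$gene_id, t$chrom, t$strand,
                     t$exons + k, source = t$source)
  }
  a <- mk_tx("a", c(100, 200, 300, 400, 500, 600))
  b <- mk_tx("b", c(100, 230, 500, 600))
  for (k in c(1000, 54321))
    expect_equal(ev_types(pairwise_events(a, b)),
                 ev_types(pairwise_events(shift_tx(a, k), shift_tx(b, k))))
})

test_that("planted single-operation pairs are recovered exactly", {
  set.seed(33)
  base_positions <- function() {
    w <- sample(60:150, 5, replace = TRUE)
    g <- sample(200:600, 4, replace = TRUE)
    starts <- 1000 + cumsum(c(0, w[-5] + g))
    cbind(starts, starts + w)
  }
  for (rep_ in seq_len(200)) {
    ex <- base_positions()
    strand <- sample(c("+", "-"), 1)
    op <- sample(c("ES", "IR", "A5", "A3", "ATSS", "ATTS", "MEE"), 1)
    exb <- ex
    if (op == "ES") exb <- ex[-3, ]
    if (op == "IR") {
      i <- sample(2:4, 1)
      exb <- rbind(ex[seq_len(i - 1), ], c(ex[i, 1], ex[i + 1, 2]),
                   if (i + 2 <= 5) ex[(i + 2):5, ])
      tmp <- ex; ex <- exb; exb <- tmp   # a retains the intron
    }
    if (op == "A5") {
      d <- sample(10:40, 1)
      if (strand == "+") exb[3, 2] <- ex[3, 2] - d else exb[3, 1] <- ex[3, 1] + d
    }
    if (op == "A3") {
      d <- sample(10:40, 1)
      if (strand == "+") exb[3, 1] <- ex[3, 1] + d else exb[3, 2] <- ex[3, 2] - d
    }
    if (op == "ATSS") {
      if (strand == "+") exb[1, ] <- ex[1, ] - sample(300:500, 1)
      else exb[5, ] <- ex[5, ] + sample(300:500, 1)
    }
    if (op == "ATTS") {
      if (strand == "+") exb[5, ] <- ex[5, ] + sample(300:500, 1)
      else exb[1, ] <- ex[1, ] - sample(300:500, 1)
    }
    if (op == "MEE") {
      gap_lo <- ex[3, 2] + 20; gap_hi <- ex[4, 1] - 20
      if (gap_hi - gap_lo < 40) next
      exb[3, ] <- c(gap_lo, gap_lo + 30)
    }
    a <- transcript_model("a", "g", "chr1", strand, ex, source = "reference")
    b <- transcript_model("b", "g", "chr1", strand, exb,
                          source = "reference")
    expect_equal(ev_types(pairwise_events(a, b)), op, info = op)
  }
})

test_that("isoform fractions normalise per expressed gene-sample", {
  counts <- rbind(t1 = c(30, 0), t2 = c(70, 0), t3 = c(10, 5))
  colnames(counts) <- c("s1", "s2")
  tx2gene <- c(t1 = "g1", t2 = "g1", t3 = "g2")
  ifm <- isoform_fractions(counts, tx2gene)
  expect_equal(unname(ifm[c("t1", "t2"), "s1"]), c(0.3, 0.7))
  expect_true(all(is.na(ifm[c("t1", "t2"), "s2"])))
  expect_equal(unname(ifm["t3", ]), c(1, 1))
  expect_error(isoform_fractions(counts, tx2gene[1:2]), "without gene")
})

test_that("perfect switch attains the exhaustive-permutation minimum 2/252", {
  ifm0 <- rbind(t1 = c(rep(0.8, 5), rep(0.2, 5)),
                t2 = c(rep(0.2, 5), rep(0.8, 5)))
  colnames(ifm0) <- paste0("s", 1:10)
  attr(ifm0, "tx2gene") <- c(t1 = "g1", t2 = "g1")
  design <- rep(c("x", "y"), each = 5)
  res <- dtu_switch_test(ifm0, design)
  expect_equal(res$genes$p_value, 2 / 252)
  expect_equal(res$genes$switch_score, 1.2)
  expect_equal(sum(res$isoforms$dIF), 0)
  # identical fractions: score 0, p 1
  flat <- rbind(t1 = rep(0.5, 10), t2 = rep(0.5, 10))
  colnames(flat) <- paste0("s", 1:10)
  attr(flat, "tx2gene") <- c(t1 = "g1", t2 = "g1")
  res0 <- dtu_switch_test(flat, design)
  expect_equal(res0$genes$switch_score, 0)
  expect_equal(res0$genes$p_value, 1)
  expect_error(dtu_switch_test(ifm0, c("x", rep("y", 9))), ">= 2")
})

test_that("signed dIF sums to zero per gene on simulated data", {
  cfg <- small_cfg(seed = 41, make_genome = FALSE)
  ref <- make_reference(cfg)
  cnt <- simulate_counts(ref$annotation, cfg)
  keep <- rowSums(cnt$counts) > 0
  ifm <- isoform_fractions(cnt$counts[keep, ], cnt$tx2gene)
  res <- dtu_switch_test(ifm, factor(cnt$samples$condition), seed = 2)
  sums <- tapply(res$isoforms$dIF, res$isoforms$gene_id, sum)
  expect_true(all(abs(sums) < 1e-9))
})

test_that("event usage difference arithmetic and empty cases", {
  ann <- annotation(list(
    mk_tx("t1", c(100, 200, 300, 400, 500, 600), gene = "g1"),
    mk_tx("t2", c(100, 200, 500, 600), gene = "g1"),
    mk_tx("solo", c(1000, 1200), gene = "g2")))
  ifm <- rbind(t1 = c(rep(0.8, 5), rep(0.2, 5)),
               t2 = c(rep(0.2, 5), rep(0.8, 5)),
               solo = rep(1, 10))
  colnames(ifm) <- paste0("s", 1:10)
  attr(ifm, "tx2gene") <- c(t1 = "g1", t2 = "g1", solo = "g2")
  design <- factor(rep(c("x", "y"), each = 5))
  out <- gene_event_summary(ann, ifm, design)
  es <- out$events[out$events$type == "ES", ]
  expect_equal(nrow(es), 1L)
  expect_equal(es$inclusion, "t1")
  expect_equal(es$usage_diff, 0.6)
  expect_false("g2" %in% out$events$gene_id)
  # single-isoform-only annotation gives an empty table
  solo_ann <- annotation(list(mk_tx("solo", c(1000, 1200), gene = "g2")))
  out2 <- gene_event_summary(solo_ann, ifm["solo", , drop = FALSE], design)
  expect_equal(nrow(out2$events), 0L)
})

test_that("functional consequences flag status, ORF and annotations", {
  switch <- list(isoforms = data.frame(
    gene_id = "g1", transcript_id = c("up", "down"), dIF = c(0.4, -0.4)))
  calls <- data.frame(transcript_id = c("up", "down"),
                      status = c("coding", "noncoding"),
                      reason = "cpat_coding", probability = NA)
  out <- functional_consequences(switch, calls)
  expect_match(out$consequences, "coding_gain")
  ann_tab <- data.frame(transcript_id = c("up", "down"),
                        orf_length = c(600, 300))
  out2 <- functional_consequences(switch, calls, ann_tab)
  expect_match(out2$consequences, "orf_length_change")
  same <- data.frame(transcript_id = c("up", "down"),
                     status = "coding", reason = "x", probability = NA)
  out3 <- functional_consequences(switch, same,
                                  data.frame(transcript_id = c("up", "down"),
                                             orf_length = c(300, 300)))
  expect_equal(out3$consequences, "")
})
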