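# End-to-end pipeline driver: antisense removal -> novelty classification ->
# coverage validation -> expression filter -> merged validated annotation ->
# coding assessment -> CAGE TSS validation -> DE (gene + transcript) -> DTU ->
# AS-event summary -> spike-in sensitivity. Declarative JSON config; stages
# skip (and record the skip) when their inputs are absent.

#' Assemble a pipeline configuration
#'
#' @param reference_gtf,candidate_gtf Required annotation paths.
#' @param genome_fasta,coverage_bedgraph,junction_tsv,counts_tsv,samples_tsv
#'   Optional evidence inputs; stages needing an absent input are skipped.
#' @param cage_bed,sequin_mix_tsv,sequin_counts_tsv More optional inputs.
#' @param out_dir Output directory for reports and the manifest.
#' @param params A `validation_params`.
#' @param lfc,fdr DE thresholds.
#' @param cp_threshold Coding-probability threshold.
#' @param cage_window,cage_mode CAGE window size and mode.
#' @param tss_tolerance TSS/TTS novelty tolerance (bp).
#' @param seed Seed for every stochastic step (model training, permutations).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_gtf, candidate_gtf,
                            genome_fasta = NULL, coverage_bedgraph = NULL,
                            junction_tsv = NULL, counts_tsv = NULL,
                            samples_tsv = NULL, cage_bed = NULL,
                            sequin_mix_tsv = NULL, sequin_counts_tsv = NULL,
                            out_dir = tempfile("isoval_out"),
                            params = validation_params(),
                            lfc = 1.5, fdr = 0.05, cp_threshold = 0.364,
                            cage_window = 500, cage_mode = "symmetric",
                            tss_tolerance = 0, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    config$params <- do.call(validation_params,
                             as.list(config$params %||% list()))
    config <- do.call(pipeline_config,
                      config[names(config) %in%
                               names(formals(pipeline_config))])
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(...) message("[isoval] ", ...)

#' Run the annotation-validation and differential-analysis pipeline
#'
#' Executes every stage whose inputs are configured, writes per-stage TSV
#' reports, the validated merged GTF and a JSON manifest (stage record counts,
#' percentages, file checksums) into `out_dir`, and returns the manifest.
#' Identical configs and seeds give identical manifests and checksums.
#'
#' @param config A `pipeline_config`, or path to a JSON serialisation of one.
#' @return Manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  manifest <- list(seed = cfg$seed, stages = list(), files = list())
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, note) {
    manifest$stages[[name]] <<- note
    log_stage(name, ": ", paste(names(note), unlist(note), sep = "=",
                                collapse = " "),
              sprintf(" (%.1fs)", proc.time()[["elapsed"]] - t0))
  }
  outfile <- function(name) file.path(cfg$out_dir, name)
  save_tsv <- function(d, name) {
    data.table::fwrite(d, outfile(name), sep = "\t")
    manifest$files[[name]] <<- unname(tools::md5sum(outfile(name)))
  }

  ref <- read_gtf(cfg$reference_gtf, source = "reference")
  cand <- read_gtf(cfg$candidate_gtf, source = "novel")
  n_candidates <- length(cand$transcripts)
  stage("load", list(reference = length(ref$transcripts),
                     candidates = n_candidates))

  as_ids <- detect_antisense_duplicates(cand, ref)
  keep <- setdiff(names(cand$transcripts), as_ids)
  cand <- annotation(cand$transcripts[keep])
  stage("antisense_removal", list(removed = length(as_ids)))

  reports <- lapply(cand$transcripts, classify_transcript, reference = ref,
                    tolerance_bp = cfg$tss_tolerance)
  save_tsv(novelty_table(reports), "novelty_report.tsv")
  catalog <- aggregate_catalog(reports)
  save_tsv(data.frame(metric = names(catalog),
                      value = unlist(catalog)), "novelty_catalog.tsv")
  stage("novelty_classification", list(classified = length(reports)))

  n_cov_failed <- 0L
  if (!is.null(cfg$coverage_bedgraph)) {
    cov <- read_bedgraph(cfg$coverage_bedgraph)
    filt <- filter_by_exon_coverage(cand, reports, cov, p)
    n_cov_failed <- length(filt$removed_ids)
    cand <- filt$annotation
    reports <- reports[names(cand$transcripts)]
    stage("coverage_validation", list(removed = n_cov_failed,
                                      retained = length(cand$transcripts)))
  } else stage("coverage_validation", list(skipped = TRUE))

  if (!is.null(cfg$junction_tsv)) {
    sup <- read_junction_table(cfg$junction_tsv)
    jx_rows <- list()
    for (t in cand$transcripts) {
      jx <- transcript_junctions(t)
      if (nrow(jx)) jx_rows[[t$transcript_id]] <- jx
    }
    jx <- unique(do.call(rbind, jx_rows))
    if (!is.null(jx) && nrow(jx)) {
      jx$validated <- vapply(seq_len(nrow(jx)), function(i)
        junction_validated(jx$chrom[i], jx$strand[i], jx$intron_start[i],
                           jx$intron_end[i], sup, p), NA)
      save_tsv(jx, "junction_validation.tsv")
      stage("junction_validation",
            list(junctions = nrow(jx), validated = sum(jx$validated)))
    } else stage("junction_validation", list(junctions = 0L))
  } else stage("junction_validation", list(skipped = TRUE))

  counts <- samples <- NULL
  if (!is.null(cfg$counts_tsv)) counts <- read_counts(cfg$counts_tsv)
  if (!is.null(cfg$samples_tsv))
    samples <- data.table::fread(cfg$samples_tsv, data.table = FALSE)
  n_expr_failed <- 0L
  if (!is.null(counts)) {
    novel_ids <- names(cand$transcripts)
    present <- intersect(novel_ids, rownames(counts))
    retained <- expression_filter(counts[present, , drop = FALSE], p)
    failed <- setdiff(novel_ids, retained)
    n_expr_failed <- length(failed)
    cand <- annotation(cand$transcripts[setdiff(novel_ids, failed)])
    reports <- reports[names(cand$transcripts)]
    stage("expression_filter", list(removed = n_expr_failed,
                                    retained = length(cand$transcripts)))
  } else stage("expression_filter", list(skipped = TRUE))

  n_validated <- length(cand$transcripts)
  merged <- merge_annotations(ref, cand)
  write_gtf(merged, outfile("validated_annotation.gtf"))
  manifest$files[["validated_annotation.gtf"]] <-
    unname(tools::md5sum(outfile("validated_annotation.gtf")))
  stage("merge", list(transcripts = length(merged$transcripts)))

  genome <- if (!is.null(cfg$genome_fasta))
    read_genome_fasta(cfg$genome_fasta) else NULL
  model <- NULL
  if (!is.null(genome)) {
    train <- make_training_sequences(40, seed = cfg$seed)
    model <- train_coding_model(train$coding, train$noncoding,
                                threshold = cfg$cp_threshold)
  }
  calls <- lapply(cand$transcripts, function(t)
    tryCatch(classify_coding_status(t, reports[[t$transcript_id]], ref,
                                    model = model, genome = genome),
             error = function(e)
               coding_call(t$transcript_id, "unresolved", "model_unavailable")))
  call_tab <- coding_calls_table(calls)
  save_tsv(call_tab, "coding_calls.tsv")
  n_coding <- sum(call_tab$status == "coding")
  n_noncoding <- sum(call_tab$status == "noncoding")
  stage("coding_assessment",
        list(coding = n_coding, noncoding = n_noncoding,
             unresolved = sum(call_tab$status == "unresolved")))

  if (!is.null(cfg$cage_bed)) {
    peaks <- read_cage_bed(cfg$cage_bed)
    tss_tx <- Filter(function(t) isTRUE(reports[[t$transcript_id]]$novel_tss),
                     cand$transcripts)
    win <- do.call(rbind, lapply(tss_tx, function(t) {
      w <- tss_window(t, mode = cfg$cage_mode, w = cfg$cage_window)
      data.frame(transcript_id = t$transcript_id, chrom = t$chrom,
                 start = w[["start"]], end = w[["end"]], strand = t$strand)
    }))
    if (is.null(win))
      win <- data.frame(transcript_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character())
    cage <- intersect_cage(win, peaks)
    save_tsv(cage$per_id, "cage_support.tsv")
    stage("cage_validation", cage$summary)
  } else stage("cage_validation", list(skipped = TRUE))

  de_summary <- function(counts, design) {
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    res <- de_test(counts, design, tmm_factors(counts))
    hits <- threshold_filter(res, lfc = cfg$lfc, fdr = cfg$fdr)
    list(res = res, hits = hits)
  }
  if (!is.null(counts) && !is.null(samples)) {
    design <- factor(samples$condition[match(colnames(counts),
                                             samples$sample)])
    tx2gene <- vapply(merged$transcripts, `[[`, "", "gene_id")
    known <- intersect(rownames(counts), names(tx2gene))
    tx_counts <- counts[known, , drop = FALSE]
    de_tx <- de_summary(tx_counts, design)
    save_tsv(de_tx$res, "de_transcript.tsv")
    save_tsv(de_tx$hits, "de_transcript_hits.tsv")
    gene_counts <- aggregate_gene_counts(tx_counts, tx2gene)
    de_g <- de_summary(gene_counts, design)
    save_tsv(de_g$res, "de_gene.tsv")
    save_tsv(de_g$hits, "de_gene_hits.tsv")
    stage("differential_expression",
          list(transcripts_tested = nrow(de_tx$res),
               transcript_hits = nrow(de_tx$hits),
               genes_tested = nrow(de_g$res),
               gene_hits = nrow(de_g$hits)))

    expressed <- tx_counts[rowSums(tx_counts) > 0, , drop = FALSE]
    ifm <- isoform_fractions(expressed, tx2gene)
    dtu <- dtu_switch_test(ifm, design, seed = cfg$seed)
    save_tsv(dtu$genes, "dtu_genes.tsv")
    save_tsv(dtu$isoforms, "dtu_isoforms.tsv")
    cons <- functional_consequences(dtu, call_tab)
    save_tsv(cons, "dtu_consequences.tsv")
    stage("differential_usage",
          list(genes_tested = nrow(dtu$genes),
               switches_q05 = sum(dtu$genes$q_value < 0.05)))

    ev <- gene_event_summary(merged, ifm, design, seed = cfg$seed)
    save_tsv(ev$events, "as_events.tsv")
    save_tsv(ev$by_type, "as_event_summary.tsv")
    stage("as_events", list(events = nrow(ev$events)))
  } else {
    stage("differential_expression", list(skipped = TRUE))
    stage("differential_usage", list(skipped = TRUE))
    stage("as_events", list(skipped = TRUE))
  }

  if (!is.null(cfg$sequin_mix_tsv) && !is.null(cfg$sequin_counts_tsv) &&
      !is.null(samples)) {
    mix <- read_mix_table(cfg$sequin_mix_tsv)
    sq_counts <- read_counts(cfg$sequin_counts_tsv)
    sq_mix <- samples$mix[match(colnames(sq_counts), samples$sample)]
    lens <- stats::setNames(mix$length, mix$sequin_id)
    tpm <- tpm_from_counts(sq_counts, lens)
    design <- factor(sq_mix, levels = c("B", "A"))
    res <- de_test(sq_counts[rowSums(sq_counts) > 0, , drop = FALSE], design)
    observed <- stats::setNames(res$logFC, res$feature)
    expected <- expected_logfc(mix, formula = "standard")
    sens <- sensitivity_report(expected, observed)
    loq <- lapply(c(A = "A", B = "B"), function(mx) {
      cols <- which(sq_mix == mx)
      conc <- if (mx == "A") mix$mixA_conc else mix$mixB_conc
      obs <- as.vector(tpm[mix$sequin_id, cols])
      estimate_loq(rep(conc, times = length(cols)), obs)
    })
    save_tsv(data.frame(sequin_id = names(expected),
                        expected_logfc = unname(expected),
                        observed_logfc = unname(observed[names(expected)])),
             "sequin_logfc.tsv")
    save_tsv(data.frame(mix = names(loq),
                        loq = vapply(loq, `[[`, 0,
                                     "breakpoint_concentration"),
                        sse = vapply(loq, `[[`, 0, "sse")),
             "sequin_loq.tsv")
    stage("spikein",
          list(r_squared = round(sens$r_squared, 4),
               loq_mixA = loq$A$breakpoint_concentration,
               loq_mixB = loq$B$breakpoint_concentration))
  } else stage("spikein", list(skipped = TRUE))

  manifest$summary <- list(
    n_candidates = n_candidates,
    n_antisense_removed = length(as_ids),
    n_coverage_failed = n_cov_failed,
    n_expression_filtered = n_expr_failed,
    n_validated = n_validated,
    pct_validated = 100 * n_validated / max(1, n_candidates),
    n_coding = n_coding,
    n_noncoding = n_noncoding,
    pct_coding = 100 * n_coding / max(1, n_validated),
    pct_noncoding = 100 * n_noncoding / max(1, n_validated))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a complete synthetic input bundle
#'
#' Generates reference + candidate annotations, genome, coverage, junction
#' support, counts, samples, CAGE peaks, spike-in tables and ground-truth
#' labels, and writes them in the formats the pipeline reads. The returned
#' `pipeline_config` runs on the bundle without edits.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Directory to write into.
#' @return List: `config` (a `pipeline_config`), `truth` (TruthSet plus
#'   stage truths), `paths`.
#' @export
simulate_bundle <- function(cfg = sim_config(), out_dir = tempfile("bundle")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(name) file.path(out_dir, name)
  ref <- make_reference(cfg)
  inj <- inject_novel_features(ref, cfg)
  cov <- simulate_coverage(inj$novel, inj$truth, cfg)
  merged <- merge_annotations(ref$annotation, inj$novel)
  cnt <- simulate_counts(merged, cfg)
  sq <- simulate_sequins(cfg)
  cage <- make_cage_peaks(inj$novel, inj$truth, cfg)

  write_gtf(ref$annotation, pth("reference.gtf"))
  write_gtf(inj$novel, pth("candidate.gtf"))
  if (!is.null(ref$genome)) write_genome_fasta(ref$genome, pth("genome.fa"))
  write_bedgraph(cov$coverage, pth("coverage.bedgraph"))
  jx <- cov$junction_truth[c("chrom", "intron_start", "intron_end",
                             "strand", "read_count")]
  data.table::fwrite(jx, pth("junctions.tsv"), sep = "\t")
  write_counts(cnt$counts, pth("counts.tsv"), id_col = "transcript_id")
  data.table::fwrite(cnt$samples, pth("samples.tsv"), sep = "\t")
  pk <- cage$peaks
  data.table::fwrite(pk[c("chrom", "start", "end")], pth("cage.bed"),
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(as.data.frame(sq$mix), pth("sequin_mix.tsv"),
                     sep = "\t")
  write_counts(sq$counts, pth("sequin_counts.tsv"), id_col = "sequin_id")
  data.table::fwrite(inj$truth$transcripts, pth("truth_transcripts.tsv"),
                     sep = "\t")
  data.table::fwrite(cnt$truth_de, pth("truth_de.tsv"), sep = "\t")
  data.table::fwrite(cnt$truth_dtu, pth("truth_dtu.tsv"), sep = "\t")

  config <- pipeline_config(
    reference_gtf = pth("reference.gtf"),
    candidate_gtf = pth("candidate.gtf"),
    genome_fasta = if (!is.null(ref$genome)) pth("genome.fa") else NULL,
    coverage_bedgraph = pth("coverage.bedgraph"),
    junction_tsv = pth("junctions.tsv"),
    counts_tsv = pth("counts.tsv"),
    samples_tsv = pth("samples.tsv"),
    cage_bed = pth("cage.bed"),
    sequin_mix_tsv = pth("sequin_mix.tsv"),
    sequin_counts_tsv = pth("sequin_counts.tsv"),
    out_dir = file.path(out_dir, "out"),
    seed = cfg$seed)
  cfg_json <- config[!vapply(config, is.null, NA)]
  cfg_json$params <- unclass(cfg_json$params)
  jsonlite::write_json(unclass(cfg_json), pth("pipeline_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(config = config,
       truth = c(inj["truth"], list(cage_supported = cage$supported_ids,
                                    de = cnt$truth_de, dtu = cnt$truth_dtu,
                                    cstar = sq$cstar,
                                    junctions = cov$junction_truth)),
       paths = list(dir = out_dir))
}
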