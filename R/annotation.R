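# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# GTF I/O converts to/from 1-based inclusive at the boundary.

#' Construct a transcript model
#'
#' A transcript is a strand-aware chain of non-overlapping exons on one
#' chromosome, with an optional CDS genomic span. This is the unit that is
#' classified for novelty, validated against short-read evidence, and
#' quantified.
#'
#' @param transcript_id,gene_id Feature identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix of 0-based half-open exon intervals,
#'   in genomic order.
#' @param cds Optional length-2 numeric vector, the genomic span of the coding
#'   region (0-based half-open), contained in the exon footprint.
#' @param source `"reference"` or `"novel"`.
#' @param attributes Named character vector of extra GTF attributes.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, source = "reference",
                             attributes = character()) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"),
            source %in% c("reference", "novel"))
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript ", transcript_id, ": empty or inverted exon interval")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript ", transcript_id, ": overlapping exons")
  if (!is.null(cds)) {
    cds <- as.numeric(cds)
    stopifnot(length(cds) == 2L, cds[1L] < cds[2L])
    if (cds[1L] < exons[1L, 1L] || cds[2L] > exons[nrow(exons), 2L])
      stop("transcript ", transcript_id, ": CDS outside exon footprint")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = as.character(chrom), strand = strand,
                 exons = exons, cds = cds, source = source,
                 attributes = attributes),
            class = "transcript_model")
}

#' Total exonic length of a transcript
#' @param t A `transcript_model`.
#' @return Length in bases.
#' @export
transcript_length <- function(t) sum(t$exons[, 2L] - t$exons[, 1L])

#' Splice junctions of a transcript
#'
#' Junctions are represented by their intron coordinates, 0-based half-open:
#' `intron_start` is the first intronic base, `intron_end` one past the last.
#'
#' @param t A `transcript_model`.
#' @return A data.frame with columns `chrom`, `strand`, `intron_start`,
#'   `intron_end`, one row per junction in genomic order (zero rows for
#'   single-exon transcripts).
#' @export
transcript_junctions <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L)
    return(data.frame(chrom = character(), strand = character(),
                      intron_start = numeric(), intron_end = numeric()))
  data.frame(chrom = t$chrom, strand = t$strand,
             intron_start = t$exons[-n, 2L],
             intron_end = t$exons[-1L, 1L])
}

# Strand-aware TSS/TTS: 0-based position of the 5'-most / 3'-most base.
tx_tss <- function(t) {
  if (t$strand == "+") t$exons[1L, 1L] else t$exons[nrow(t$exons), 2L] - 1
}
tx_tts <- function(t) {
  if (t$strand == "+") t$exons[nrow(t$exons), 2L] - 1 else t$exons[1L, 1L]
}

jx_key <- function(start, end) paste(start, end, sep = ":")

#' Assemble an annotation from transcript models
#'
#' Builds the gene table and the per-(chromosome, strand) indexes of donor
#' sites, acceptor sites, junctions, TSS/TTS positions and exon intervals that
#' all novelty comparisons are made against. Donor/acceptor are strand-aware:
#' on `+`, donor = intron start and acceptor = intron end; on `-`, reversed.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param gene_biotype Optional named character vector `gene_id -> biotype`
#'   (`"coding"` or `"noncoding"`). Where absent, the biotype is taken from a
#'   `gene_type`/`gene_biotype` transcript attribute when present, else
#'   inferred: coding iff any transcript of the gene has a CDS.
#' @return An object of class `annotation` with elements `transcripts` (named
#'   list), `genes` (named list of `list(transcript_ids, biotype)`) and
#'   `index`.
#' @export
annotation <- function(transcripts, gene_biotype = NULL) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicated transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  genes <- list()
  for (t in transcripts) {
    g <- genes[[t$gene_id]]
    if (is.null(g)) g <- list(transcript_ids = character(), biotype = NA_character_)
    g$transcript_ids <- c(g$transcript_ids, t$transcript_id)
    genes[[t$gene_id]] <- g
  }
  for (gid in names(genes)) {
    bt <- NA_character_
    if (!is.null(gene_biotype) && gid %in% names(gene_biotype))
      bt <- unname(gene_biotype[[gid]])
    if (is.na(bt)) {
      txs <- transcripts[genes[[gid]]$transcript_ids]
      attr_bt <- unlist(lapply(txs, function(t) {
        a <- t$attributes[names(t$attributes) %in% c("gene_type", "gene_biotype")]
        unname(a)
      }))
      if (length(attr_bt)) {
        bt <- if (any(attr_bt == "protein_coding" | attr_bt == "coding"))
          "coding" else "noncoding"
      } else {
        bt <- if (any(vapply(txs, function(t) !is.null(t$cds), NA)))
          "coding" else "noncoding"
      }
    }
    genes[[gid]]$biotype <- bt
  }
  ann <- structure(list(transcripts = transcripts, genes = genes, index = NULL),
                   class = "annotation")
  ann$index <- build_index(ann)
  ann
}

#' @export
print.annotation <- function(x, ...) {
  cat("annotation:", length(x$transcripts), "transcripts,",
      length(x$genes), "genes\n")
  src <- table(vapply(x$transcripts, `[[`, "", "source"))
  cat("  sources:", paste(names(src), as.integer(src), collapse = ", "), "\n")
  invisible(x)
}

#' Build per-(chrom, strand) feature indexes
#'
#' @param ann An `annotation`.
#' @return Named list keyed `"chrom|strand"`; each element holds sorted unique
#'   `donors`, `acceptors`, `tss`, `tts` positions, junction keys `junctions`,
#'   and an exon interval matrix `exons`.
#' @export
build_index <- function(ann) {
  acc <- new.env(parent = emptyenv())
  for (t in ann$transcripts) {
    key <- paste(t$chrom, t$strand, sep = "|")
    e <- get0(key, envir = acc)
    if (is.null(e))
      e <- list(donors = list(), acceptors = list(), junctions = list(),
                tss = list(), tts = list(), exons = list())
    jx <- transcript_junctions(t)
    if (nrow(jx)) {
      if (t$strand == "+") {
        e$donors[[length(e$donors) + 1L]] <- jx$intron_start
        e$acceptors[[length(e$acceptors) + 1L]] <- jx$intron_end
      } else {
        e$donors[[length(e$donors) + 1L]] <- jx$intron_end
        e$acceptors[[length(e$acceptors) + 1L]] <- jx$intron_start
      }
      e$junctions[[length(e$junctions) + 1L]] <-
        jx_key(jx$intron_start, jx$intron_end)
    }
    e$tss[[length(e$tss) + 1L]] <- unname(tx_tss(t))
    e$tts[[length(e$tts) + 1L]] <- unname(tx_tts(t))
    e$exons[[length(e$exons) + 1L]] <- t$exons
    assign(key, e, envir = acc)
  }
  idx <- list()
  for (key in ls(acc)) {
    e <- get(key, envir = acc)
    ex <- unique(do.call(rbind, e$exons))
    idx[[key]] <- list(
      donors = sort(unique(unlist(e$donors))),
      acceptors = sort(unique(unlist(e$acceptors))),
      junctions = sort(unique(unlist(e$junctions))),
      tss = sort(unique(unlist(e$tss))),
      tts = sort(unique(unlist(e$tts))),
      exons = ex[order(ex[, 1L], ex[, 2L]), , drop = FALSE])
  }
  idx
}

#' Read a GTF file into an annotation
#'
#' Accepts the GENCODE attribute dialect (`gene_id "X"; transcript_id "Y";`),
#' gzip-transparently. Exon coordinates are converted from GTF 1-based
#' inclusive to the internal 0-based half-open convention; CDS features, when
#' present, populate the transcript's CDS span.
#'
#' @param path Path to a GTF (optionally gzipped).
#' @param source Force the source tag of all transcripts (`"reference"` or
#'   `"novel"`); by default transcripts whose GTF source column is `novel` or
#'   `TALON` are tagged novel, everything else reference.
#' @return An `annotation`.
#' @export
read_gtf <- function(path, source = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(con <- gzfile(path)); close(con)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L))
    stop("malformed GTF line ", which(body)[which(nf < 9L)[1L]],
         " in ", path, ": fewer than 9 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (!all(c("type", "transcript_id", "gene_id") %in% names(mc)))
    stop("GTF lacks type/transcript_id/gene_id: ", path)
  keep <- mc$type %in% c("exon", "CDS")
  gr <- gr[keep]; mc <- S4Vectors::mcols(gr)
  if (!length(gr)) return(annotation(list()))
  std <- c("source", "type", "score", "phase")
  extra_cols <- setdiff(names(mc), c(std, "gene_id", "transcript_id"))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(mc$type),
                   gtf_source = as.character(mc$source),
                   transcript_id = mc$transcript_id,
                   gene_id = mc$gene_id,
                   stringsAsFactors = FALSE)
  row_split <- split(seq_len(nrow(df)), df$transcript_id)
  txs <- lapply(names(row_split), function(tid) {
    rows <- df[row_split[[tid]], ]
    ex <- rows[rows$type == "exon", ]
    if (!nrow(ex)) return(NULL)
    if (length(unique(ex$strand)) != 1L || any(ex$strand == "*"))
      stop("transcript ", tid, ": exons on mixed or undefined strands")
    cds_rows <- rows[rows$type == "CDS", ]
    cds <- if (nrow(cds_rows)) c(min(cds_rows$start), max(cds_rows$end)) else NULL
    src <- if (!is.null(source)) source
           else if (any(ex$gtf_source %in% c("novel", "TALON"))) "novel"
           else "reference"
    first <- row_split[[tid]][rows$type == "exon"][1L]
    attrs <- character()
    for (col in extra_cols) {
      v <- mc[[col]][first]
      if (length(v) == 1L && !is.na(v)) attrs[[col]] <- as.character(v)
    }
    transcript_model(tid, ex$gene_id[1L], ex$chrom[1L], ex$strand[1L],
                     cbind(ex$start, ex$end), cds = cds,
                     source = src, attributes = attrs)
  })
  names(txs) <- names(row_split)
  annotation(Filter(Negate(is.null), txs))
}

#' Write an annotation to GTF
#'
#' Emits exon features (and per-exon CDS features where a CDS span is present),
#' 1-based inclusive, GENCODE attribute dialect, with deterministic ordering by
#' (chrom, transcript start, transcript_id): two runs on the same annotation
#' are byte-identical.
#'
#' @param ann An `annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  txs <- ann$transcripts
  if (length(txs)) {
    ord <- order(vapply(txs, `[[`, "", "chrom"),
                 vapply(txs, function(t) t$exons[1L, 1L], 0),
                 vapply(txs, `[[`, "", "transcript_id"))
    txs <- txs[ord]
  }
  chunks <- vector("list", length(txs) + 1L)
  chunks[[1L]] <- "##format: gtf"
  ci <- 1L
  for (t in txs) {
    base_attr <- sprintf('gene_id "%s"; transcript_id "%s";',
                         t$gene_id, t$transcript_id)
    extra <- t$attributes
    if (length(extra)) {
      extra <- extra[order(names(extra))]
      base_attr <- paste(base_attr,
                         paste(sprintf('%s "%s";', names(extra), extra),
                               collapse = " "))
    }
    fmt <- function(type, s, e, frame = ".")
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              t$chrom, t$source, type, as.integer(s + 1), as.integer(e),
              t$strand, frame, base_attr)
    tl <- vapply(seq_len(nrow(t$exons)), function(i)
      fmt("exon", t$exons[i, 1L], t$exons[i, 2L]), "")
    if (!is.null(t$cds)) {
      seg <- intersect_intervals(t$exons, t$cds[1L], t$cds[2L])
      if (t$strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
      done <- 0
      for (i in seq_len(nrow(seg))) {
        frame <- (3 - done %% 3) %% 3
        tl <- c(tl, fmt("CDS", seg[i, 1L], seg[i, 2L], frame))
        done <- done + seg[i, 2L] - seg[i, 1L]
      }
    }
    ci <- ci + 1L
    chunks[[ci]] <- tl
  }
  writeLines(unlist(chunks), path)
  invisible(path)
}

# Exonic sub-intervals of [s, e): intersection of each exon with the span.
intersect_intervals <- function(exons, s, e) {
  lo <- pmax(exons[, 1L], s)
  hi <- pmin(exons[, 2L], e)
  keep <- lo < hi
  cbind(start = lo[keep], end = hi[keep])
}

#' Merge a reference and a novel annotation
#'
#' Novel transcripts of existing genes attach to those genes; gene biotypes
#' from the reference win. Transcript id sets must be disjoint.
#'
#' @param reference,novel `annotation` objects.
#' @return The merged `annotation`.
#' @export
merge_annotations <- function(reference, novel) {
  clash <- intersect(names(reference$transcripts), names(novel$transcripts))
  if (length(clash))
    stop("transcript_id collision(s): ", paste(clash, collapse = ", "))
  bt <- c(vapply(reference$genes, `[[`, "", "biotype"),
          vapply(novel$genes, `[[`, "", "biotype"))
  bt <- bt[!duplicated(names(bt))]            # reference biotype wins
  annotation(c(reference$transcripts, novel$transcripts), gene_biotype = bt)
}

#' Structural equality of two annotations
#'
#' Compares transcript sets (ids, coordinates, CDS, strand, source, attributes)
#' and gene biotypes; index is derived so not compared directly.
#'
#' @param a,b `annotation` objects.
#' @return Logical.
#' @export
annotation_equal <- function(a, b) {
  if (!setequal(names(a$transcripts), names(b$transcripts))) return(FALSE)
  for (id in names(a$transcripts)) {
    x <- a$transcripts[[id]]; y <- b$transcripts[[id]]
    same <- identical(x$gene_id, y$gene_id) &&
      identical(x$chrom, y$chrom) && identical(x$strand, y$strand) &&
      isTRUE(all.equal(unname(x$exons), unname(y$exons))) &&
      identical(is.null(x$cds), is.null(y$cds)) &&
      (is.null(x$cds) || isTRUE(all.equal(unname(x$cds), unname(y$cds)))) &&
      identical(x$source, y$source)
    sort_attrs <- function(a) {
      if (!length(a)) return(stats::setNames(character(), character()))
      a <- a[order(names(a))]
      stats::setNames(as.character(a), names(a))
    }
    if (!same || !identical(sort_attrs(x$attributes),
                            sort_attrs(y$attributes))) return(FALSE)
  }
  if (!setequal(names(a$genes), names(b$genes))) return(FALSE)
  for (g in names(a$genes))
    if (!identical(a$genes[[g]]$biotype, b$genes[[g]]$biotype)) return(FALSE)
  TRUE
}
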