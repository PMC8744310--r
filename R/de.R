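# Simplified differential-expression engine: TMM-style normalization factors,
# gene aggregation, a negative-binomial exact-style two-group test with
# moment-estimated common dispersion, BH correction, threshold filtering, and
# binomial count thinning.

#' Benjamini-Hochberg step-up q-values
#' @param p Numeric vector of p-values.
#' @return q-values (monotone in p rank, each >= its p).
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (!n) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

#' TMM-style normalization factors
#'
#' Doubly-trimmed weighted mean of gene-wise log2 count ratios against a
#' reference sample (the sample whose upper-quartile count is closest to the
#' mean upper quartile). The returned factor combines library size and
#' composition (a sample with twice the counts of another, gene for gene,
#' gets twice the factor); factors are scaled to geometric mean 1 and are
#' meant to divide the raw counts.
#'
#' @param counts Feature x sample matrix of non-negative counts, >= 2 samples,
#'   each with positive library size.
#' @param logratio_trim Two-sided trim fraction on M-values (default 0.30).
#' @param sum_trim Two-sided trim fraction on A-values (default 0.05).
#' @return Numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, sum_trim = 0.05) {
  stopifnot(ncol(counts) >= 2L)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero-count sample")
  uq <- apply(counts, 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  xr <- counts[, ref]
  f <- vapply(seq_len(ncol(counts)), function(s) {
    x <- counts[, s]
    keep <- x > 0 & xr > 0
    if (!any(keep)) return(1)
    M <- log2(x[keep] / xr[keep])
    A <- 0.5 * log2(x[keep] * xr[keep])
    w <- 1 / x[keep] + 1 / xr[keep]
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(sel)) sel <- rep(TRUE, n)
    2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  }, 0)
  f / exp(mean(log(f)))
}

#' Aggregate transcript counts to gene level
#'
#' @param counts Transcript x sample matrix with rownames.
#' @param tx2gene Named character vector `transcript_id -> gene_id` covering
#'   all rows.
#' @return Gene x sample matrix; column sums are preserved.
#' @export
aggregate_gene_counts <- function(counts, tx2gene) {
  miss <- setdiff(rownames(counts), names(tx2gene))
  if (length(miss))
    stop("unmapped transcripts: ", paste(miss, collapse = ", "))
  rowsum(counts, tx2gene[rownames(counts)])
}

# conditional NB exact-style two-sided p-value for group sums ya vs yb
nb_exact_p <- function(ya, yb, na, nb, phi) {
  t_ <- ya + yb
  if (t_ == 0) return(1)
  mu <- t_ / (na + nb)
  size_a <- na / phi; size_b <- nb / phi
  if (t_ > 5e4) {
    # large counts: conditional distribution of ya given the total is
    # effectively normal; the enumeration below would be needlessly huge
    va <- na * mu + (na * mu)^2 / size_a
    vb <- nb * mu + (nb * mu)^2 / size_b
    sd_c <- sqrt(va * vb / (va + vb))
    m_c <- t_ * na / (na + nb)
    return(min(1, 2 * stats::pnorm(-abs(ya - m_c) / sd_c)))
  }
  # probability mass over all splits a + b = t_ (truncate far tails)
  sd_a <- sqrt(na * mu + (na * mu)^2 / size_a)
  lo <- max(0, floor(na * mu - 30 * sd_a))
  hi <- min(t_, ceiling(na * mu + 30 * sd_a))
  a <- lo:hi
  logf <- stats::dnbinom(a, size = size_a, mu = na * mu, log = TRUE) +
    stats::dnbinom(t_ - a, size = size_b, mu = nb * mu, log = TRUE)
  f <- exp(logf - max(logf))
  obs <- stats::dnbinom(ya, size = size_a, mu = na * mu, log = TRUE) +
    stats::dnbinom(yb, size = size_b, mu = nb * mu, log = TRUE)
  fobs <- exp(obs - max(logf))
  min(1, sum(f[f <= fobs * (1 + 1e-12)]) / sum(f))
}

#' Two-group negative-binomial differential expression test
#'
#' Counts are divided by the supplied normalization factors; the common
#' dispersion is estimated by the method of moments across features (pooled
#' within-group variances, floor 1e-4); each feature then gets an exact-style
#' conditional NB test on its normalized group sums, and BH q-values. logFC is
#' the log2 ratio of normalized condition means with pseudo-count 0.5
#' (condition 1 = first factor level, vs condition 2).
#'
#' @param counts Feature x sample matrix of non-negative integer counts,
#'   all-zero features removed.
#' @param design Two-level condition factor, one label per column.
#' @param norm_factors Per-sample factors (default [tmm_factors()]).
#' @param dispersion Optional fixed common dispersion; required when a
#'   condition has a single sample.
#' @return data.frame: feature, logFC, mean_expr, p_value, q_value.
#' @export
de_test <- function(counts, design, norm_factors = NULL, dispersion = NULL) {
  design <- as.factor(design)
  stopifnot(nlevels(design) == 2L, length(design) == ncol(counts))
  i1 <- which(design == levels(design)[1L])
  i2 <- which(design == levels(design)[2L])
  if ((length(i1) < 2L || length(i2) < 2L) && is.null(dispersion))
    stop("a condition has < 2 samples; supply a dispersion")
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  z <- sweep(counts, 2L, norm_factors, "/")
  m1 <- rowMeans(z[, i1, drop = FALSE])
  m2 <- rowMeans(z[, i2, drop = FALSE])
  logfc <- log2((m1 + 0.5) / (m2 + 0.5))
  if (is.null(dispersion)) {
    v1 <- apply(z[, i1, drop = FALSE], 1L, stats::var)
    v2 <- apply(z[, i2, drop = FALSE], 1L, stats::var)
    n1 <- length(i1); n2 <- length(i2)
    vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    mpool <- rowMeans(z)
    ok <- mpool > 0
    phi_g <- (vpool[ok] - mpool[ok]) / mpool[ok]^2
    dispersion <- max(1e-4, mean(phi_g, na.rm = TRUE))
  }
  dispersion <- max(1e-4, dispersion)
  ya <- round(rowSums(z[, i1, drop = FALSE]))
  yb <- round(rowSums(z[, i2, drop = FALSE]))
  p <- vapply(seq_len(nrow(counts)), function(g)
    nb_exact_p(ya[g], yb[g], length(i1), length(i2), dispersion), 0)
  data.frame(feature = rownames(counts), logFC = logfc,
             mean_expr = rowMeans(z), p_value = p,
             q_value = bh_adjust(p), row.names = NULL)
}

#' Threshold filter on DE results
#'
#' Keeps features with `|logFC| >= lfc` (inclusive) and `q < fdr`, reporting
#' direction (`"up"` for positive logFC in condition 1, `"down"` otherwise).
#'
#' @param res Output of [de_test()].
#' @param lfc log2 fold-change magnitude threshold (default 1.5).
#' @param fdr FDR threshold (default 0.05, strict `<`).
#' @return Subset of `res` with a `direction` column.
#' @export
threshold_filter <- function(res, lfc = 1.5, fdr = 0.05) {
  keep <- abs(res$logFC) >= lfc & res$q_value < fdr
  out <- res[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Binomial downsampling of a count matrix
#'
#' Thins every cell with `rbinom(count, fraction)`; deterministic per seed.
#'
#' @param counts Integer matrix.
#' @param fraction Retention probability in (0, 1].
#' @param seed RNG seed.
#' @return Thinned matrix, same shape and dimnames.
#' @export
downsample_counts <- function(counts, fraction, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(counts)
  out <- with_seed(seed, {
    v <- stats::rbinom(length(counts), size = as.integer(counts),
                       prob = fraction)
    matrix(v, nrow = nrow(counts), dimnames = dimnames(counts))
  })
  out
}

#' Read a counts TSV (feature id column + one column per sample)
#' @param path TSV path; first column feature ids, header row sample ids.
#' @return Integer matrix with rownames.
#' @export
read_counts <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a counts matrix as TSV
#' @param counts Matrix with rownames.
#' @param path Output path.
#' @param id_col Name of the feature id column (default "feature_id").
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, id_col = "feature_id") {
  d <- data.frame(rownames(counts), counts, check.names = FALSE,
                  row.names = NULL)
  names(d)[1L] <- id_col
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}
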