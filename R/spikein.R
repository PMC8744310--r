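# Sequin spike-in sensitivity analysis: TPM, expected logFC between the two
# mixes, broken-stick limit-of-quantification estimation, and expected-vs-
# observed regression.

#' Transcripts per million from counts and effective lengths
#'
#' @param counts Feature x sample matrix.
#' @param effective_lengths Named (or positionally matching) vector of
#'   positive lengths.
#' @return TPM matrix; each column with any signal sums to 1e6.
#' @export
tpm_from_counts <- function(counts, effective_lengths) {
  if (!is.null(names(effective_lengths)))
    effective_lengths <- effective_lengths[rownames(counts)]
  if (any(is.na(effective_lengths) | effective_lengths <= 0))
    stop("zero, negative or missing effective length")
  rate <- counts / effective_lengths
  denom <- colSums(rate)
  denom[denom == 0] <- NA_real_
  out <- sweep(rate, 2L, denom, "/") * 1e6
  out[is.na(out)] <- 0
  out
}

#' Read a spike-in mix table
#' @param path TSV with columns sequin_id, mixA_conc, mixB_conc, length.
#' @return data.frame of class `sequin_mix`.
#' @export
read_mix_table <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  sequin_mix(d)
}

#' Construct a spike-in mix table
#' @param d data.frame with sequin_id, mixA_conc, mixB_conc (attomol/ul) and
#'   length (nt).
#' @return Validated data.frame of class `sequin_mix`.
#' @export
sequin_mix <- function(d) {
  stopifnot(all(c("sequin_id", "mixA_conc", "mixB_conc", "length")
                %in% names(d)),
            all(d$mixA_conc > 0), all(d$mixB_conc > 0), all(d$length > 0))
  class(d) <- c("sequin_mix", "data.frame")
  d
}

#' Expected spike-in log fold change between mixes
#'
#' Default `standard` formula: `log2(MixB/MixA)`. The `literal` variant
#' `log2(MixB/MixA - 1) + 1` (as sometimes printed) is undefined for
#' `MixB <= MixA` and returns an error for such sequins; the two coincide at
#' a ratio of exactly 2.
#'
#' @param mix A `sequin_mix`.
#' @param formula `"standard"` or `"literal"`.
#' @return Named numeric vector of expected logFC per sequin.
#' @export
expected_logfc <- function(mix, formula = c("standard", "literal")) {
  formula <- match.arg(formula)
  ratio <- mix$mixB_conc / mix$mixA_conc
  out <- if (formula == "standard") {
    log2(ratio)
  } else {
    if (any(ratio <= 1))
      stop("literal formula undefined for sequins with MixB/MixA <= 1: ",
           paste(mix$sequin_id[ratio <= 1], collapse = ", "))
    log2(ratio - 1) + 1
  }
  stats::setNames(out, mix$sequin_id)
}

#' Limit of quantification by broken-stick regression
#'
#' Fits, on (log2 concentration, log2(abundance + pseudo)), a two-segment
#' model with the breakpoint on the grid of observed concentrations: points
#' below the breakpoint get a flat or free-slope least-squares line
#' (whichever fits better), points at or above it a free-slope line. The
#' breakpoint minimizing the total sum of squared errors is the LOQ. If a
#' single line fits within 1e-9 of the best two-segment fit, the LOQ is the
#' minimum observed concentration.
#'
#' @param concentrations Positive concentrations (attomol/ul), one per
#'   observation.
#' @param abundances Non-negative abundances (e.g. TPM), same length.
#' @param min_points Minimum number of distinct concentrations (default 4).
#' @param pseudo Pseudo-abundance added before log2 (default 0.01).
#' @return List of class `loq_result`: `breakpoint_concentration`,
#'   `below_slope`, `below_intercept`, `above_slope`, `above_intercept`,
#'   `sse`, `single_line_sse`.
#' @export
estimate_loq <- function(concentrations, abundances, min_points = 4,
                         pseudo = 0.01) {
  stopifnot(length(concentrations) == length(abundances),
            all(concentrations > 0), all(abundances >= 0))
  grid <- sort(unique(concentrations))
  if (length(grid) < min_points)
    stop("need >= ", min_points, " distinct concentrations")
  x <- log2(concentrations)
  y <- log2(abundances + pseudo)
  fit_line <- function(xs, ys) {
    if (length(xs) < 2L || stats::var(xs) == 0) {
      b <- 0; a <- mean(ys)
    } else {
      b <- stats::cov(xs, ys) / stats::var(xs)
      a <- mean(ys) - b * mean(xs)
    }
    list(a = a, b = b, sse = sum((ys - a - b * xs)^2))
  }
  fit_flat <- function(ys) list(a = mean(ys), b = 0,
                                sse = sum((ys - mean(ys))^2))
  single <- fit_line(x, y)
  best <- NULL
  for (cb in grid) {
    xb <- log2(cb)
    li <- x < xb
    ri <- x >= xb
    if (sum(li) < 2L || sum(ri) < 2L) next
    left_flat <- fit_flat(y[li])
    left_free <- fit_line(x[li], y[li])
    left <- if (left_flat$sse <= left_free$sse) left_flat else left_free
    right <- fit_line(x[ri], y[ri])
    tot <- left$sse + right$sse
    if (is.null(best) || tot < best$sse - 1e-12)
      best <- list(breakpoint_concentration = cb,
                   below_slope = left$b, below_intercept = left$a,
                   above_slope = right$b, above_intercept = right$a,
                   sse = tot)
  }
  if (is.null(best) || single$sse <= best$sse + 1e-9)
    best <- list(breakpoint_concentration = min(grid),
                 below_slope = single$b, below_intercept = single$a,
                 above_slope = single$b, above_intercept = single$a,
                 sse = single$sse)
  best$single_line_sse <- single$sse
  class(best) <- "loq_result"
  best
}

#' Expected-vs-observed sensitivity regression
#'
#' Ordinary least squares of observed on expected logFC; pairs with
#' non-finite expected values are excluded and counted.
#'
#' @param expected,observed Named numeric vectors (matched by name when both
#'   are named, else positionally); >= 3 finite pairs required.
#' @return List of class `sensitivity_report`: `r_squared`, `slope`,
#'   `intercept`, `n_pairs`, `n_excluded`.
#' @export
sensitivity_report <- function(expected, observed) {
  if (!is.null(names(expected)) && !is.null(names(observed))) {
    common <- intersect(names(expected), names(observed))
    expected <- expected[common]; observed <- observed[common]
  }
  stopifnot(length(expected) == length(observed))
  ok <- is.finite(expected) & is.finite(observed)
  n_excl <- sum(!ok)
  e <- expected[ok]; o <- observed[ok]
  if (length(e) < 3L) stop("need >= 3 finite expected/observed pairs")
  b <- stats::cov(e, o) / stats::var(e)
  a <- mean(o) - b * mean(e)
  ss_res <- sum((o - a - b * e)^2)
  ss_tot <- sum((o - mean(o))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(r_squared = r2, slope = b, intercept = a,
                 n_pairs = length(e), n_excluded = n_excl),
            class = "sensitivity_report")
}
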