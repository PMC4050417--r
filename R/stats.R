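#' Exact paired Wilcoxon signed-rank test
#'
#' Paired two-tailed Wilcoxon signed-rank test. Differences of zero are
#' dropped before ranking (Wilcoxon's original treatment); absolute
#' differences are ranked with mid-ranks for ties. The statistic W is the
#' smaller of the positive- and negative-rank sums. For up to
#' \code{exact_limit} non-zero pairs the two-tailed p-value is exact:
#' p = 2 P(T <= W) under the null, with the null distribution of the rank
#' sum obtained by dynamic programming over all 2^n sign assignments
#' (mid-ranks included), capped at 1. Beyond the limit a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit largest number of non-zero pairs for which the exact
#'   enumeration is used (default 25).
#' @return An object of class \code{paired_test_result}: list with
#'   \code{n_pairs}, \code{n_nonzero}, \code{W}, \code{p}, \code{method}
#'   (\code{"exact"} or \code{"approximate"}), \code{degenerate} (TRUE when
#'   all differences are zero, in which case p = 1).
#' @examples
#' wilcoxon_exact(c(2, 3, 5, 9), c(1, 1, 1, 1))$p
#' @export
wilcoxon_exact <- function(x, y, exact_limit = 25L) {
  if (length(x) != length(y) || !length(x))
    stop("x and y must be paired vectors of equal positive length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  d <- x - y
  nz <- d != 0
  n <- sum(nz)
  if (n == 0L) {
    return(structure(list(n_pairs = length(x), n_nonzero = 0L, W = 0,
                          p = 1, method = "exact", degenerate = TRUE),
                     class = "paired_test_result"))
  }
  d <- d[nz]
  r <- rank(abs(d))                       # mid-ranks for ties
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  if (n <= exact_limit) {
    # doubled ranks are integers even with mid-ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)         # counts[s+1] = #assignments with sum s
    counts[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(total + 1L - rr)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * W))
    p <- 2 * sum(counts[seq_len(w2 + 1L)]) / 2^n
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu + 0.5) / sqrt(sigma2)    # continuity correction toward the tail
    p <- 2 * stats::pnorm(z)
    method <- "approximate"
  }
  structure(list(n_pairs = length(x), n_nonzero = n, W = W,
                 p = min(p, 1), method = method, degenerate = FALSE),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W = %g, n = %d (%d non-zero), two-tailed p = %.4g\n",
              x$method, x$W, x$n_pairs, x$n_nonzero, x$p))
  invisible(x)
}

#' Summarize a per-lesion volume table
#'
#' Per-column mean, sample SD, min and max for the planning volumes, plus the
#' ratio-of-means (x100, i.e. percent) for PTV/PTVg and BITV/BTV and the
#' per-row percentage ratios. Ratio-of-means — not mean of per-row ratios —
#' is what a cohort mean row reports.
#'
#' @param records data frame with columns \code{ptv_cc}, \code{ptvg_cc},
#'   \code{bitv_cc}, \code{btv_cc} (further columns are passed through to
#'   the column summary).
#' @return List with \code{columns} (data frame: column, mean, sd, min, max),
#'   \code{ratio_of_means} (named vector, percent: \code{ptv_ptvg},
#'   \code{bitv_btv}) and \code{per_row} (the input with \code{ptv_ptvg_pct}
#'   and \code{bitv_btv_pct} columns added).
#' @export
summarize_volumes <- function(records) {
  need <- c("ptv_cc", "ptvg_cc", "bitv_cc", "btv_cc")
  if (!is.data.frame(records) || !nrow(records))
    stop("records must be a non-empty data frame")
  if (!all(need %in% names(records)))
    stop("records must contain columns ", paste(need, collapse = ", "))
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("patient", "lesion"))
  columns <- data.frame(
    column = num_cols,
    mean = vapply(num_cols, function(cn) mean(records[[cn]]), numeric(1)),
    sd = vapply(num_cols, function(cn)
      if (nrow(records) > 1) stats::sd(records[[cn]]) else NA_real_, numeric(1)),
    min = vapply(num_cols, function(cn) min(records[[cn]]), numeric(1)),
    max = vapply(num_cols, function(cn) max(records[[cn]]), numeric(1)),
    row.names = NULL)
  ratio_of_means <- c(
    ptv_ptvg = 100 * mean(records$ptv_cc) / mean(records$ptvg_cc),
    bitv_btv = 100 * mean(records$bitv_cc) / mean(records$btv_cc))
  per_row <- records
  per_row$ptv_ptvg_pct <- 100 * records$ptv_cc / records$ptvg_cc
  per_row$bitv_btv_pct <- 100 * records$bitv_cc / records$btv_cc
  list(columns = columns, ratio_of_means = ratio_of_means, per_row = per_row)
}

#' Median and range
#'
#' @param values numeric vector of length >= 1.
#' @return Named numeric vector \code{median}, \code{min}, \code{max}
#'   (median is the mean of the central pair for even n).
#' @export
median_range <- function(values) {
  if (!length(values) || any(!is.finite(values)))
    stop("values must be a non-empty finite numeric vector")
  c(median = stats::median(values), min = min(values), max = max(values))
}

#' Count lesions whose gated PTV failed to shrink
#'
#' Number of rows with PTVg >= PTV — the exceptions to the expected gated
#' planning-volume reduction (typically lesions adjacent to the lungs, where
#' motion-blurred non-gated uptake is clipped by the manual CTV).
#'
#' @param records data frame with \code{ptv_cc} and \code{ptvg_cc} columns.
#' @return Integer count.
#' @export
count_exceptions <- function(records) {
  if (!is.data.frame(records) || !nrow(records))
    stop("records must be a non-empty data frame")
  sum(records$ptvg_cc >= records$ptv_cc)
}

#' Reference cohort fixtures
#'
#' Per-patient SUV thresholds and per-lesion planning volumes from a
#' published 8-patient / 14-lesion liver SBRT pilot cohort, shipped as CSV
#' fixtures for regression testing of the cohort statistics. Values are the
#' printed clinical values; volume rows are therefore not required to
#' satisfy the margin-superset invariants of pipeline-produced records.
#'
#' @param which \code{"thresholds"} (patient, gated_suv, nongated_suv) or
#'   \code{"volumes"} (patient, lesion, ptv_cc, ptvg_cc, bitv_cc, btv_cc,
#'   ctv_cc, liver_cc).
#' @return A data frame.
#' @export
load_reference_cohort <- function(which = c("volumes", "thresholds")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("cohort_", which, ".csv"), package = "petitv")
  if (!nzchar(f))
    stop("cohort fixture not found; is the package installed?")
  utils::read.csv(f, stringsAsFactors = FALSE)
}
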