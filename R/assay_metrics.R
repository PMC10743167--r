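#' LDH cytotoxicity percentage
#'
#' Linear rescaling of a test well's OD490 between the low (spontaneous
#' release) and high (full lysis) controls:
#' `100 * (od_test - od_low) / (od_high - od_low)`.
#' The result is affine-invariant: a constant offset applied to all three
#' readings cancels. Values outside \[0, 100\] (biological over/undershoot)
#' are returned as-is with a warning.
#'
#' @param od_test absorbance(s) at 490 nm of the test sample(s).
#' @param od_low low-control absorbance.
#' @param od_high high-control absorbance; must exceed `od_low`.
#' @return cytotoxicity in percent, same length as `od_test`.
#' @export
cytotoxicity <- function(od_test, od_low, od_high) {
  assert_scalar_number(od_low, "od_low")
  assert_scalar_number(od_high, "od_high")
  if (!is.numeric(od_test) || !length(od_test) || any(!is.finite(od_test)))
    stop_evhub("`od_test` must be finite numeric")
  if (od_high <= od_low)
    stop_evhub("invalid assay: od_high must exceed od_low (cytotoxicity undefined)")
  pct <- 100 * (od_test - od_low) / (od_high - od_low)
  if (any(pct < 0 | pct > 100))
    warning("cytotoxicity outside [0, 100]%; returned unclipped")
  pct
}

#' Phagocytic activity from bead uptake
#'
#' Percentage of cells that incorporated fluorescent microbeads.
#'
#' @param n_bead_positive bead-positive cell count(s).
#' @param n_total total cell count(s), > 0.
#' @return activity in percent.
#' @export
phagocytic_activity <- function(n_bead_positive, n_total) {
  if (any(n_total <= 0)) stop_evhub("`n_total` must be > 0")
  if (any(n_bead_positive < 0) || any(n_bead_positive > n_total))
    stop_evhub("`n_bead_positive` must lie in [0, n_total]")
  100 * n_bead_positive / n_total
}

#' Extrapolate invaded cell numbers from sampled membrane areas
#'
#' Cell counts from small sampled rectangles are summed and scaled by the
#' fraction of the membrane area they cover; the fraction is an
#' experiment-specific required input.
#'
#' @param area_counts non-negative cell counts of the sampled areas
#'   (conventionally 20 rectangles).
#' @param fraction_sampled fraction of the whole membrane covered by the
#'   sampled areas, in (0, 1].
#' @return estimated total cell count (nearest integer).
#' @export
invasion_estimate <- function(area_counts, fraction_sampled) {
  if (!is.numeric(area_counts) || !length(area_counts) || any(area_counts < 0))
    stop_evhub("`area_counts` must be non-negative numeric")
  assert_scalar_number(fraction_sampled, "fraction_sampled")
  if (fraction_sampled <= 0 || fraction_sampled > 1)
    stop_evhub("`fraction_sampled` must be in (0, 1]")
  round(sum(area_counts) / fraction_sampled)
}

# Grubbs critical value: ((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2)) with t the
# one-tailed Student quantile at `q`, df = n-2
grubbs_critical <- function(n, q) {
  t <- qt(1 - q, df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Smirnoff-Grubbs outlier test
#'
#' Tests the single most extreme observation against the Grubbs critical
#' value. The default two-sided test uses the statistic
#' `G = max|x - mean| / SD` with the one-tailed Student quantile at
#' `alpha / (2n)` (df = n - 2), which keeps the null flag rate at the
#' nominal `alpha` while catching outliers in either direction — the
#' behaviour box-plot outlier marking needs. `tail = "one"` tests only the
#' maximum (upper) observation at `alpha / n`. At most one observation is
#' flagged per pass; `iterative = TRUE` repeats the test on the remaining
#' values until no outlier is found.
#'
#' @param x numeric series, length >= 3.
#' @param alpha significance level.
#' @param tail `"two"` (default, either direction) or `"one"` (upper only).
#' @param iterative repeat after removing each flagged value?
#' @return integer vector of flagged indices into `x` (empty when none),
#'   with attributes `statistic` and `critical` from the first pass.
#' @export
grubbs_outlier <- function(x, alpha = 0.05, tail = c("two", "one"),
                           iterative = FALSE) {
  tail <- match.arg(tail)
  if (!is.numeric(x) || length(x) < 3L)
    stop_evhub("`x` must be numeric with n >= 3")
  assert_scalar_number(alpha, "alpha", positive = TRUE)
  flagged <- integer(0)
  remaining <- seq_along(x)
  first <- TRUE
  g1 <- c1 <- NA_real_
  repeat {
    xs <- x[remaining]
    n <- length(xs)
    if (n < 3L) break
    s <- sd(xs)
    if (s == 0) {
      if (first) message("zero standard deviation; no outlier test performed")
      break
    }
    dev <- if (tail == "two") abs(xs - mean(xs)) else xs - mean(xs)
    g <- max(dev) / s
    crit <- grubbs_critical(n, if (tail == "two") alpha / (2 * n) else alpha / n)
    if (first) { g1 <- g; c1 <- crit; first <- FALSE }
    if (g <= crit) break
    idx <- remaining[which.max(dev)]
    flagged <- c(flagged, idx)
    if (!iterative) break
    remaining <- setdiff(remaining, idx)
  }
  structure(flagged, statistic = g1, critical = c1)
}

#' Two-tailed two-sample t-test p-value
#'
#' Classical Student (pooled-variance) test by default; `equal_variance =
#' FALSE` gives the Welch variant. When both groups are degenerate
#' (zero variance) the p-value is 1 for equal means and 0 otherwise, by
#' convention.
#'
#' @param a,b numeric series, each with n >= 2.
#' @param equal_variance pool the variances (Student) or not (Welch)?
#' @return the two-tailed p-value.
#' @export
two_tailed_t <- function(a, b, equal_variance = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop_evhub("each series needs at least 2 observations")
  if (sd(a) == 0 && sd(b) == 0) {
    message("both groups degenerate; p-value by convention")
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  t.test(a, b, var.equal = equal_variance, alternative = "two.sided")$p.value
}
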