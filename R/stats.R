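## Statistical comparison of per-split scores: paired two-tailed t-tests,
## 95% confidence intervals for a mean, and pooled-SD Cohen's d.

#' Paired two-tailed t-test on per-split scores
#'
#' Two-tailed probability from the t statistic of the paired differences
#' with n-1 degrees of freedom. Degenerate cases are defined explicitly:
#' all-zero differences give p = 1 (no evidence of any difference), and
#' nonzero constant differences give p = 0 (the zero-variance limit).
#'
#' @param a,b Equal-length numeric vectors paired by split.
#' @return The p-value.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 paired values")
  d <- a - b
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(0)
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Pooled-SD Cohen's d
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled standard deviation
#' over both groups (n1 + n2 - 2 denominator). Identical groups give 0.
#'
#' @param a,b Numeric score vectors.
#' @export
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  md <- mean(a) - mean(b)
  if (md == 0) return(0)
  pooled <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                   (n1 + n2 - 2))
  if (pooled == 0) return(sign(md) * Inf)
  md / pooled
}

#' 95% confidence interval for a mean
#'
#' `mean +/- t_{0.975, n-1} * sd / sqrt(n)`.
#'
#' @param values Numeric vector (length >= 2).
#' @return Named vector `c(low, high)`.
#' @export
ci95 <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  c(low = mean(values) - half, high = mean(values) + half)
}
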