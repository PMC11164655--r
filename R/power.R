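# Closed-form power for the paired / one-sample t-test.

#' Power of a two-sided paired t-test
#'
#' Exact power from the noncentral t distribution: with `df = n - 1` and
#' noncentrality `d * sqrt(n)`, power is the probability that |T'| exceeds
#' the two-sided critical value. The (numerically negligible) lower-tail
#' rejection probability is included.
#'
#' @param n Number of participants (pairs), at least 2.
#' @param d Cohen's d for paired differences (mean difference / SD of
#'   differences); sign is irrelevant.
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in \[0, 1\].
#' @examples
#' power_paired_t(20, 0.66)  # the design's 80% power statement
#' @export
power_paired_t <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2, n == round(n), alpha > 0, alpha < 1, is.numeric(d))
  df <- n - 1
  ncp <- d * sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}
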