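#' Power of a paired (two-dependent-means) t-test
#'
#' Exact power via the noncentral t distribution: with `n` pairs, effect size
#' `d` (standardized mean difference of the paired differences) and two-tailed
#' level `alpha`, the test statistic under the alternative is noncentral t
#' with `n - 1` degrees of freedom and noncentrality `d * sqrt(n)`.
#'
#' @param n number of participants (pairs), `n >= 2`.
#' @param d effect size (Cohen's d for dependent means), `d > 0`.
#' @param alpha two-tailed significance level.
#' @return Achieved power in (0, 1).
#' @examples
#' paired_t_power(57, d = 0.5, alpha = 0.0167)  # ~0.90
#' @export
paired_t_power <- function(n, d, alpha = 0.05) {
  if (n < 2) stop("n must be >= 2")
  if (d <= 0) stop("d must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
}

#' Smallest sample size reaching a target power
#'
#' Increment-and-check search for the smallest `n >= 2` whose paired-t power
#' meets the target.
#'
#' @param d effect size.
#' @param alpha two-tailed significance level.
#' @param target_power required power in (0, 1).
#' @return List with `n` and `achieved_power`.
#' @examples
#' required_n(d = 0.5, alpha = 0.0167, target_power = 0.90)$n  # 57
#' @export
required_n <- function(d, alpha = 0.05, target_power = 0.90) {
  if (target_power <= 0 || target_power >= 1) stop("target_power must be in (0, 1)")
  n <- 2L
  while (paired_t_power(n, d, alpha) < target_power) n <- n + 1L
  list(n = n, achieved_power = paired_t_power(n, d, alpha))
}
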