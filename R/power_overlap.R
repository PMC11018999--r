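# Power for binary-outcome MR and sample-overlap bias diagnostics.

#' Statistical power of a binary-outcome MR analysis
#'
#' Closed-form power for a two-sided Wald test of the causal log-odds
#' ratio. The hypothesized odds ratio is first attenuated to the
#' risk-difference scale, b = K * (OR / (1 + K*(OR - 1)) - 1) with case
#' fraction K; the estimator variance is (K*(1-K) - b^2) / (N * R2), and
#' power = Phi(-z + |b|/sd) + Phi(-z - |b|/sd) at two-sided level alpha.
#'
#' @param n Total outcome sample size.
#' @param k_case Case fraction K in (0, 1).
#' @param r2 Variance in the exposure explained by the instruments, \[0, 1).
#' @param or_hyp Hypothesized odds ratio per exposure SD.
#' @param alpha Two-sided significance level; default 0.05.
#' @return Power in \[0, 1\].
#' @export
mr_power_binary <- function(n, k_case, r2, or_hyp, alpha = 0.05) {
  stopifnot(k_case > 0, k_case < 1, r2 >= 0, r2 < 1, or_hyp > 0,
            alpha > 0, alpha < 1)
  b <- k_case * (or_hyp / (1 + k_case * (or_hyp - 1)) - 1)
  v <- (k_case * (1 - k_case) - b^2) / (n * r2)
  if (v <= 0) stop("non-positive variance: check N, R2, K, OR", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(b) / sqrt(v)
  stats::pnorm(-z + ncp) + stats::pnorm(-z - ncp)
}

#' Bias and type-I-error inflation from exposure/outcome sample overlap
#'
#' In two-sample MR with partially overlapping samples, weak-instrument
#' bias pulls the estimate toward the confounded observational association
#' in proportion to the overlap. The bias is approximated as
#' `overlap_fraction * confounded_effect / f_bar` (mean instrument F), and
#' the inflated type-I error is the rejection probability of the nominal
#' two-sided level-alpha test when the estimator is centred at that bias:
#' P(|Z| > z_{1-alpha/2}) with Z ~ Normal(bias / se_mr, 1).
#'
#' @param overlap_fraction Overlapping-sample fraction in \[0, 1\].
#' @param confounded_effect Assumed confounded observational association on
#'   the analysis scale.
#' @param f_bar Mean instrument F statistic (> 0).
#' @param se_mr SE of the MR estimate.
#' @param alpha Nominal two-sided level; default 0.05.
#' @return List with `bias` and `type1_error`.
#' @export
overlap_bias <- function(overlap_fraction, confounded_effect, f_bar, se_mr,
                         alpha = 0.05) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1, f_bar > 0,
            se_mr > 0)
  bias <- overlap_fraction * confounded_effect / f_bar
  z <- stats::qnorm(1 - alpha / 2)
  mu <- bias / se_mr
  type1 <- stats::pnorm(-z - mu) + stats::pnorm(-z + mu)
  list(bias = bias, type1_error = type1)
}
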