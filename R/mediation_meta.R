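# Two-step mediation MR and inverse-variance meta-analysis across studies.

#' Delta-method inference for an indirect (mediated) effect
#'
#' Combines step-1 (exposure -> mediator, univariable MR) and step-2
#' (mediator -> outcome adjusted for the exposure, multivariable MR)
#' estimates: indirect = beta1 * beta2 with delta-method SE
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`; the proportion mediated is
#' indirect / total * 100 with the delta-method CI treating the total as a
#' third independent estimate.
#'
#' @param beta1,se1 Exposure -> mediator effect and SE.
#' @param beta2,se2 Mediator -> outcome direct effect (given the exposure)
#'   and SE.
#' @param total,se_total Total exposure -> outcome effect and SE.
#' @param mediator,outcome Optional labels.
#' @return An object of class `mr_mediation` with `indirect`,
#'   `se_indirect`, `p_indirect`, `proportion_pct` and its CI.
#' @export
mediation_effect <- function(beta1, se1, beta2, se2, total, se_total,
                             mediator = NULL, outcome = NULL) {
  indirect <- beta1 * beta2
  se_ind <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  p_ind <- 2 * stats::pnorm(-abs(indirect / se_ind))
  if (abs(total) < .Machine$double.eps^0.5) {
    prop <- NA_real_; se_prop <- NA_real_
  } else {
    prop <- indirect / total
    # delta method on beta1*beta2/total with independent components
    se_prop <- abs(prop) * sqrt((se1 / beta1)^2 + (se2 / beta2)^2 +
                                (se_total / total)^2)
  }
  structure(list(beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 indirect = indirect, se_indirect = se_ind,
                 p_indirect = p_ind, total = total, se_total = se_total,
                 proportion_pct = 100 * prop,
                 prop_ci_low = 100 * (prop - stats::qnorm(0.975) * se_prop),
                 prop_ci_high = 100 * (prop + stats::qnorm(0.975) * se_prop),
                 mediator = mediator, outcome = outcome),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat("Two-step mediation MR",
      if (!is.null(x$mediator)) paste0("via ", x$mediator),
      if (!is.null(x$outcome)) paste0("on ", x$outcome), "\n")
  cat(sprintf("  beta1 = %.4f (SE %.4f); beta2 = %.4f (SE %.4f)\n",
              x$beta1, x$se1, x$beta2, x$se2))
  cat(sprintf("  indirect = %.4f (SE %.4f, p = %.3g); total = %.4f\n",
              x$indirect, x$se_indirect, x$p_indirect, x$total))
  if (is.finite(x$proportion_pct))
    cat(sprintf("  proportion mediated = %.1f%% [%.1f%%, %.1f%%]\n",
                x$proportion_pct, x$prop_ci_low, x$prop_ci_high))
  else cat("  proportion mediated undefined (total effect ~ 0)\n")
  invisible(x)
}

#' Two-step mediation MR from summary statistics
#'
#' Step 1 estimates the exposure -> mediator effect by univariable
#' random-effects IVW on the exposure's instruments. Step 2 estimates the
#' mediator -> outcome effect adjusted for the exposure by multivariable
#' IVW on the joint instrument set. The total effect is the univariable
#' IVW of exposure on outcome from the same data. Inference on the
#' indirect effect and proportion mediated is by the delta method; an
#' optional parametric bootstrap CI for the proportion is available.
#'
#' @param exposure,mediator,outcome GWAS record data.frames.
#' @param ld LD lookup; default independence.
#' @param p_instrument Instrument threshold; default 5e-8.
#' @param n_boot If > 0, also compute a parametric-bootstrap percentile CI
#'   for the proportion (resampling the three betas from normal laws).
#' @param seed Optional seed for the bootstrap.
#' @param labels Optional c(mediator, outcome) labels.
#' @return An `mr_mediation` object (with `prop_ci_boot` when requested).
#' @export
two_step_mediation <- function(exposure, mediator, outcome,
                               ld = ld_independent(), p_instrument = 5e-8,
                               n_boot = 0, seed = NULL, labels = NULL) {
  inst <- ld_clump(filter_significant(exposure, p_instrument), ld)
  # step 1: exposure -> mediator, UVMR
  h1 <- retained(harmonize(inst, mediator, drop_palindromes = FALSE))
  s1 <- ivw_mre(h1)
  # step 2: mediator -> outcome given exposure, MVMR on the joint set
  u <- mvmr_instrument_union(list(exposure = exposure, mediator = mediator),
                             list(exposure = inst$snp_id,
                                  mediator = ld_clump(
                                    filter_significant(mediator, p_instrument),
                                    ld)$snp_id),
                             outcome, ld = ld, drop_palindromes = FALSE)
  s2 <- mvmr_ivw(u$bx, u$by, u$sy)
  # total effect: exposure -> outcome, UVMR on the exposure instruments
  ht <- retained(harmonize(inst, outcome, drop_palindromes = FALSE))
  tot <- ivw_mre(ht)
  res <- mediation_effect(s1$beta, s1$se, s2$beta[["mediator"]],
                          s2$se[["mediator"]], tot$beta, tot$se,
                          mediator = labels[1], outcome = labels[2])
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    props <- 100 * (stats::rnorm(n_boot, res$beta1, res$se1) *
                    stats::rnorm(n_boot, res$beta2, res$se2)) /
                   stats::rnorm(n_boot, res$total, res$se_total)
    res$prop_ci_boot <- stats::quantile(props, c(0.025, 0.975), names = FALSE)
  }
  res$step1 <- s1; res$step2 <- s2; res$total_fit <- tot
  res
}

#' Inverse-variance meta-analysis of MR estimates
#'
#' Fixed-effect pooling of study estimates with Cochran's between-study Q
#' and I-squared; the random-effects model adds the DerSimonian-Laird
#' tau-squared to each study variance before pooling.
#'
#' @param beta,se Study estimates and SEs (log-odds scale), length >= 2.
#'   Alternatively `beta` may be a list of `mr_estimate`s.
#' @param model `"fixed"` (default) or `"random"`.
#' @param labels Optional study labels.
#' @return An object of class `mr_meta`: pooled `beta`, `se`, CI, `pvalue`,
#'   `q`, `p_heterogeneity`, `i2` (percent), `tau2`.
#' @export
meta_ivw <- function(beta, se = NULL, model = c("fixed", "random"),
                     labels = NULL) {
  model <- match.arg(model)
  if (is.list(beta) && is.null(se)) {
    se <- vapply(beta, function(e) e$se, numeric(1))
    beta <- vapply(beta, function(e) e$beta, numeric(1))
  }
  k <- length(beta)
  if (k < 2) stop("meta-analysis needs at least 2 studies", call. = FALSE)
  w <- 1 / se^2
  pooled_f <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - pooled_f)^2)
  i2 <- max(0, (q - (k - 1)) / q) * 100
  if (!is.finite(i2)) i2 <- 0
  tau2 <- 0
  if (model == "random") {
    c_denom <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / c_denom)
    w <- 1 / (se^2 + tau2)
  }
  pooled <- sum(w * beta) / sum(w)
  pse <- sqrt(1 / sum(w))
  structure(list(beta = pooled, se = pse,
                 ci_low = pooled - stats::qnorm(0.975) * pse,
                 ci_high = pooled + stats::qnorm(0.975) * pse,
                 pvalue = 2 * stats::pnorm(-abs(pooled / pse)),
                 q = q,
                 p_heterogeneity = stats::pchisq(q, k - 1, lower.tail = FALSE),
                 i2 = i2, tau2 = tau2, model = model, k = k,
                 study_beta = beta, study_se = se, labels = labels),
            class = "mr_meta")
}

#' @export
print.mr_meta <- function(x, ...) {
  cat(sprintf("Meta-analysis (%s effects, %d studies)\n", x$model, x$k))
  cat(sprintf("  pooled beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$beta, x$se, exp(x$beta), exp(x$ci_low), exp(x$ci_high), x$pvalue))
  cat(sprintf("  Q = %.3f, p_het = %.3g, I2 = %.0f%%\n", x$q,
              x$p_heterogeneity, x$i2))
  invisible(x)
}

#' Reverse-direction univariable MR
#'
#' Runs the full instrument-selection and univariable-MR chain with the
#' roles swapped: instruments are selected from the original outcome
#' trait's GWAS and the original exposure becomes the outcome. When the
#' outcome trait has no genome-wide-significant instruments the function
#' returns an empty-result status instead of failing.
#'
#' @param outcome_records GWAS records of the trait now used as exposure.
#' @param exposure_records GWAS records of the trait now used as outcome.
#' @param outcome_meta,exposure_meta [study_meta()] objects for the two
#'   traits in their new roles.
#' @param ... Passed to [select_instruments()].
#' @return A list of class `mr_reverse`: either `status = "ok"` with an
#'   `mr_fit` (direction = "reverse"), or `status = "no_instruments"`.
#' @export
reverse_mr <- function(outcome_records, exposure_records, outcome_meta,
                       exposure_meta, ...) {
  sel <- try(select_instruments(outcome_records, exposure_records,
                                outcome_meta, exposure_meta, ...),
             silent = TRUE)
  n_ok <- if (inherits(sel, "try-error")) 0 else sum(is.na(sel$excluded_reason))
  if (n_ok < 2)
    return(structure(list(status = "no_instruments", direction = "reverse",
                          n_snp = n_ok), class = "mr_reverse"))
  fit <- mr_fit(sel, methods = "ivw_mre")
  structure(list(status = "ok", direction = "reverse", fit = fit,
                 n_snp = n_ok), class = "mr_reverse")
}

#' @export
print.mr_reverse <- function(x, ...) {
  cat("Reverse-direction MR:", x$status, "\n")
  if (x$status == "ok") print(x$fit)
  invisible(x)
}
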