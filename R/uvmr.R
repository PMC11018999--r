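# Univariable two-sample MR estimators. All work on the summary-data
# arrays of a harmonized set: exposure effects bx with SE sx, outcome
# effects by with SE sy, one entry per retained instrument.

mr_estimate <- function(method, beta, se, n_snp, outcome = NULL, q = NULL,
                        q_pvalue = NULL, dispersion = NULL, ...) {
  z <- beta / se
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - stats::qnorm(0.975) * se,
                 ci_high = beta + stats::qnorm(0.975) * se,
                 pvalue = 2 * stats::pnorm(-abs(z)),
                 n_snp = n_snp, outcome = outcome, q = q,
                 q_pvalue = q_pvalue, dispersion = dispersion, ...),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$se, exp(x$beta), exp(x$ci_low), exp(x$ci_high),
              x$pvalue, x$n_snp))
  if (!is.null(x$q))
    cat(sprintf("  Cochran's Q = %.3f (df %d, p = %.3g)\n", x$q,
                if (is.null(x$q_df)) x$n_snp - 1L else x$q_df, x$q_pvalue))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f (SE %.4f, p = %.3g)\n",
                x$egger_intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

hset_arrays <- function(h) {
  keep <- retained(h)
  list(bx = keep$beta_exp, sx = keep$se_exp, by = keep$beta_out,
       sy = keep$se_out, snp_id = keep$snp_id)
}

#' Per-SNP Wald ratio
#'
#' The building block of all summary-data MR estimators: the outcome effect
#' divided by the exposure effect, with first-order SE `sy / |bx|`.
#'
#' @param bx,sx Exposure effect and SE.
#' @param by,sy Outcome effect and SE.
#' @return List with `ratio` and `se`, vectorized.
#' @export
wald_ratio <- function(bx, sx, by, sy) {
  if (any(bx == 0)) stop("Wald ratio undefined for zero exposure effect", call. = FALSE)
  list(ratio = by / bx, se = sy / abs(bx))
}

#' Inverse-variance-weighted estimate with multiplicative random effects
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights 1/sy^2. Cochran's Q measures heterogeneity of the per-SNP
#' estimates; the SE is inflated by the over-dispersion factor
#' `max(1, Q/(J-1))` so the multiplicative random-effects SE is never
#' smaller than the fixed-effect one. P-values use the standard normal.
#'
#' @param h An `mr_harmonized` set (or a list with `bx`, `sx`, `by`, `sy`).
#' @param outcome Optional outcome label carried into the estimate.
#' @return An `mr_estimate` with fields `q`, `q_pvalue`, `dispersion`.
#' @export
ivw_mre <- function(h, outcome = NULL) {
  a <- if (inherits(h, "mr_harmonized")) hset_arrays(h) else h
  J <- length(a$bx)
  if (J < 2) stop("IVW needs at least 2 instruments", call. = FALSE)
  w <- 1 / a$sy^2
  sxx <- sum(w * a$bx^2)
  beta <- sum(w * a$bx * a$by) / sxx
  q <- sum(w * (a$by - beta * a$bx)^2)
  phi <- max(1, q / (J - 1))
  se <- sqrt(phi / sxx)
  mr_estimate("ivw_mre", beta, se, J, outcome = outcome, q = q,
              q_pvalue = stats::pchisq(q, J - 1, lower.tail = FALSE),
              q_df = J - 1L, dispersion = phi)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' an intercept, after orienting all instruments to non-negative exposure
#' effect (Egger is not orientation-invariant, so the convention is fixed).
#' The slope is the causal estimate even when all instruments are
#' pleiotropic, provided pleiotropy is independent of instrument strength;
#' a non-zero intercept is the directional-pleiotropy test. SEs are scaled
#' by `max(1, sqrt(Q_egger/(J-2)))`.
#'
#' @inheritParams ivw_mre
#' @return An `mr_estimate` with `egger_intercept`, `intercept_se`,
#'   `intercept_p` and residual heterogeneity `q` (df J-2).
#' @export
egger <- function(h, outcome = NULL) {
  a <- if (inherits(h, "mr_harmonized")) hset_arrays(h) else h
  J <- length(a$bx)
  if (J < 3) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  flip <- sign(a$bx)
  flip[flip == 0] <- 1
  bx <- a$bx * flip
  by <- a$by * flip
  w <- 1 / a$sy^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  cf <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% cf
  q <- sum(w * resid^2)
  phi <- max(1, q / (J - 2))
  V <- phi * solve(xtwx)
  se <- sqrt(diag(V))
  int_z <- cf[1] / se[1]
  mr_estimate("egger", cf[2], se[2], J, outcome = outcome, q = q,
              q_pvalue = stats::pchisq(q, J - 2, lower.tail = FALSE),
              q_df = J - 2L, dispersion = phi,
              egger_intercept = cf[1], intercept_se = se[1],
              intercept_p = 2 * stats::pnorm(-abs(int_z)))
}

# Core weighted-median computation: interpolate the ordered ratios at
# cumulative weight midpoint 0.5.
weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Orders per-SNP Wald ratios and takes the inverse-variance-weighted
#' median (linear interpolation of the ordered ratios at cumulative weight
#' midpoint one half). Consistent when instruments carrying more than half
#' of the weight are valid. The SE comes from a parametric bootstrap
#' redrawing the exposure and outcome effects from their normal sampling
#' laws.
#'
#' @inheritParams ivw_mre
#' @param n_boot Bootstrap draws for the SE; default 1000.
#' @param seed Optional integer seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = NULL, outcome = NULL) {
  a <- if (inherits(h, "mr_harmonized")) hset_arrays(h) else h
  J <- length(a$bx)
  if (J < 3) stop("weighted median needs at least 3 instruments", call. = FALSE)
  ratio <- a$by / a$bx
  weight <- (a$bx / a$sy)^2
  est <- weighted_median_point(ratio, weight)
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(J, a$bx, a$sx)
    by <- stats::rnorm(J, a$by, a$sy)
    weighted_median_point(by / bx, (bx / a$sy)^2)
  }, numeric(1))
  mr_estimate("weighted_median", est, stats::sd(boot), J, outcome = outcome)
}

# Leave-one-out IVW slopes for every SNP, computed from running totals.
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO outlier detection and correction
#'
#' Residual sum of squares test for horizontal-pleiotropy outliers. The
#' observed RSS uses leave-one-out IVW slopes (each SNP's residual measured
#' against the model fitted without it) and is compared against `n_sim`
#' parametric simulations of the summary data under the fitted model
#' (global test). Each SNP's observed squared residual is compared against
#' its own simulated distribution, Bonferroni-corrected across SNPs
#' (outlier test). When outliers are found, the distortion test compares
#' the change in the IVW estimate after removing them against removals of
#' random subsets of the same size, and the corrected estimate is the IVW
#' fit on the remaining instruments.
#'
#' @inheritParams ivw_mre
#' @param n_sim Parametric simulations; default 1000.
#' @param outlier_alpha Significance level for outlier calling (applied
#'   Bonferroni-corrected); default 0.05.
#' @param seed Optional integer seed.
#' @return A list of class `mr_presso` with `global_rss`, `global_p`,
#'   `outlier_p` (per SNP), `outliers` (SNP indices), `distortion_p`,
#'   `raw` and `corrected` `mr_estimate`s.
#' @export
presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = NULL,
                   outcome = NULL) {
  a <- if (inherits(h, "mr_harmonized")) hset_arrays(h) else h
  J <- length(a$bx)
  if (J < 4) stop("MR-PRESSO needs at least 4 instruments", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w <- 1 / a$sy^2
  b_loo <- loo_slopes(a$bx, a$by, w)
  obs_res2 <- w * (a$by - b_loo * a$bx)^2
  obs_rss <- sum(obs_res2)

  # simulate summary data under the per-SNP leave-one-out fits
  sim_rss <- numeric(n_sim)
  exceed <- numeric(J)
  for (s in seq_len(n_sim)) {
    bx_s <- stats::rnorm(J, a$bx, a$sx)
    by_s <- stats::rnorm(J, b_loo * a$bx, a$sy)
    b_loo_s <- loo_slopes(bx_s, by_s, w)
    res2_s <- w * (by_s - b_loo_s * bx_s)^2
    sim_rss[s] <- sum(res2_s)
    exceed <- exceed + (res2_s >= obs_res2)
  }
  global_p <- mean(sim_rss >= obs_rss)
  outlier_p <- (exceed + 1) / (n_sim + 1)
  outliers <- which(outlier_p * J < outlier_alpha)

  raw <- ivw_mre(a, outcome = outcome)
  corrected <- raw
  corrected$method <- "ivw_post_presso"
  distortion_p <- NA_real_
  if (length(outliers) && (J - length(outliers)) >= 2) {
    keep <- setdiff(seq_len(J), outliers)
    sub <- lapply(a[c("bx", "sx", "by", "sy")], `[`, keep)
    corrected <- ivw_mre(sub, outcome = outcome)
    corrected$method <- "ivw_post_presso"
    obs_shift <- abs(raw$beta - corrected$beta)
    shift <- vapply(seq_len(n_sim), function(s) {
      drop <- sample.int(J, length(outliers))
      kp <- setdiff(seq_len(J), drop)
      sub_s <- lapply(a[c("bx", "sx", "by", "sy")], `[`, kp)
      abs(raw$beta - ivw_mre(sub_s)$beta)
    }, numeric(1))
    distortion_p <- mean(shift >= obs_shift)
  }
  structure(list(global_rss = obs_rss, global_p = global_p,
                 outlier_p = outlier_p, outliers = outliers,
                 outlier_snps = a$snp_id[outliers],
                 distortion_p = distortion_p,
                 raw = raw, corrected = corrected, n_sim = n_sim),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.3f, global p = %.3g (%d simulations)\n",
              x$global_rss, x$global_p, x$n_sim))
  if (length(x$outliers)) {
    cat("  outliers:", paste(if (!is.null(x$outlier_snps)) x$outlier_snps
                             else x$outliers, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_p))
    print(x$corrected)
  } else cat("  no outliers detected\n")
  invisible(x)
}

#' Bonferroni-corrected significance threshold across outcomes
#'
#' @param alpha Family-wise level; default 0.05.
#' @param n_outcomes Number of outcomes tested.
#' @return `alpha / n_outcomes`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_outcomes) {
  stopifnot(n_outcomes >= 1)
  alpha / n_outcomes
}

#' Classify a p-value against the Bonferroni and nominal thresholds
#'
#' @param p P-value(s).
#' @param alpha Family-wise level; default 0.05.
#' @param n_outcomes Number of outcomes tested.
#' @return `"significant"` below the corrected threshold, `"suggestive"`
#'   for corrected-threshold <= p < alpha, else `"ns"`.
#' @export
significance_label <- function(p, alpha = 0.05, n_outcomes) {
  thr <- bonferroni_threshold(alpha, n_outcomes)
  ifelse(p < thr, "significant", ifelse(p < alpha, "suggestive", "ns"))
}

#' Fit univariable MR estimators to a harmonized set
#'
#' The main univariable fitting surface: runs the requested estimators and
#' returns them as one classed object with `print`, `summary`, `coef` and
#' `confint` methods.
#'
#' @param h An `mr_harmonized` set.
#' @param methods Character vector among `"ivw_mre"`, `"egger"`,
#'   `"weighted_median"`, `"presso"`.
#' @param outcome Optional outcome label.
#' @param n_boot Weighted-median bootstrap draws.
#' @param n_sim MR-PRESSO simulations.
#' @param seed Optional integer seed for the stochastic methods.
#' @return An object of class `mr_fit`.
#' @export
mr_fit <- function(h, methods = c("ivw_mre", "egger", "weighted_median"),
                   outcome = NULL, n_boot = 1000, n_sim = 1000, seed = NULL) {
  methods <- match.arg(methods, c("ivw_mre", "egger", "weighted_median", "presso"),
                       several.ok = TRUE)
  ests <- list()
  presso_res <- NULL
  for (m in methods) {
    if (m == "ivw_mre") ests$ivw_mre <- ivw_mre(h, outcome = outcome)
    if (m == "egger") ests$egger <- egger(h, outcome = outcome)
    if (m == "weighted_median")
      ests$weighted_median <- weighted_median(h, n_boot = n_boot, seed = seed,
                                              outcome = outcome)
    if (m == "presso") {
      presso_res <- presso(h, n_sim = n_sim, seed = seed, outcome = outcome)
      ests$ivw_post_presso <- presso_res$corrected
    }
  }
  structure(list(estimates = ests, presso = presso_res, outcome = outcome,
                 n_snp = if (inherits(h, "mr_harmonized"))
                   sum(is.na(h$excluded_reason)) else length(h$bx)),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Univariable MR fit", if (!is.null(x$outcome)) paste0("(", x$outcome, ")"),
      "-", x$n_snp, "instruments\n")
  for (e in x$estimates) print(e)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  df <- estimates_table(object)
  class(df) <- c("summary.mr_fit", "data.frame")
  df
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- t(vapply(object$estimates,
                function(e) c(e$beta - z * e$se, e$beta + z * e$se), numeric(2)))
  colnames(m) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), " %")
  m
}
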