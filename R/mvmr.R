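# Multivariable MR: each exposure's direct effect on the outcome
# conditional on the co-exposures, from summary data.

#' Multivariable IVW with multiplicative random effects
#'
#' Weighted multiple regression of outcome effects on the matrix of
#' exposure effects without an intercept, weights 1/sy^2. SEs are scaled by
#' `max(1, sqrt(Q/(J-m)))` so heterogeneity never shrinks them below the
#' fixed-effect values.
#'
#' @param bx J x m matrix of exposure effects (one column per exposure).
#' @param by,sy Outcome effects and SEs, length J.
#' @param exposures Optional exposure labels (defaults to column names).
#' @param outcome Optional outcome label.
#' @return An object of class `mvmr_fit`: per-exposure `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, plus `q`, `q_pvalue`, `n_snp`.
#' @export
mvmr_ivw <- function(bx, by, sy, exposures = colnames(bx), outcome = NULL) {
  bx <- as.matrix(bx)
  J <- nrow(bx); m <- ncol(bx)
  if (m < 1) stop("need at least one exposure", call. = FALSE)
  if (J <= m) stop("need more instruments than exposures", call. = FALSE)
  if (is.null(exposures)) exposures <- paste0("exposure", seq_len(m))
  keep <- colSums(bx != 0) > 0
  qrx <- qr(bx[, keep, drop = FALSE])
  if (qrx$rank < sum(keep))
    stop("collinear exposure effects: ",
         paste(exposures[keep], collapse = ", "), call. = FALSE)
  w <- 1 / sy^2
  xtwx <- crossprod(bx, w * bx)
  # all-zero columns are reported with a zero effect rather than failing
  est <- rep(0, m)
  V <- matrix(0, m, m)
  xt <- xtwx[keep, keep, drop = FALSE]
  est[keep] <- solve(xt, crossprod(bx[, keep, drop = FALSE], w * by))
  resid <- by - bx %*% est
  q <- sum(w * resid^2)
  phi <- max(1, q / (J - sum(keep)))
  V[keep, keep] <- phi * solve(xt)
  se <- sqrt(diag(V))
  se[!keep] <- NA_real_
  z <- est / se
  structure(list(exposures = exposures, beta = stats::setNames(est, exposures),
                 se = stats::setNames(se, exposures),
                 ci_low = est - stats::qnorm(0.975) * se,
                 ci_high = est + stats::qnorm(0.975) * se,
                 pvalue = 2 * stats::pnorm(-abs(z)),
                 q = q, q_pvalue = stats::pchisq(q, J - sum(keep), lower.tail = FALSE),
                 dispersion = phi, n_snp = J, outcome = outcome),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat("Multivariable MR (random-effects IVW)",
      if (!is.null(x$outcome)) paste0("on ", x$outcome), "-",
      x$n_snp, "instruments\n")
  df <- data.frame(exposure = x$exposures, beta = x$beta, se = x$se,
                   ci_low = x$ci_low, ci_high = x$ci_high, p = x$pvalue)
  print(df, digits = 4, row.names = FALSE)
  cat(sprintf("Q = %.3f (p = %.3g)\n", x$q, x$q_pvalue))
  invisible(x)
}

#' @export
coef.mvmr_fit <- function(object, ...) object$beta

#' @export
confint.mvmr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(object$beta - z * object$se, object$beta + z * object$se)
  rownames(m) <- object$exposures
  colnames(m) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), " %")
  m
}

#' Build the multivariable instrument set
#'
#' Takes the union of the instruments selected for each exposure,
#' re-clumps the union jointly (so instruments for different exposures in
#' LD with each other are pruned), requires every SNP to be present in
#' every exposure GWAS and in the outcome GWAS, and harmonizes everything
#' to the first exposure's effect-allele orientation.
#'
#' @param exposure_list Named list of GWAS record data.frames, one per
#'   exposure (full summary statistics, not only selected instruments).
#' @param instrument_ids Named list (same names) of character vectors of
#'   selected instrument SNP ids per exposure.
#' @param outcome GWAS record data.frame for the outcome.
#' @param ld,r2_max,window_kb Joint re-clumping parameters as in
#'   [ld_clump()].
#' @param drop_palindromes Exclude palindromic SNPs; default TRUE.
#' @return A list with `bx` (J x m matrix), `sx`, `by`, `sy`, `snp_id`,
#'   `exposures` and `dropped` (SNPs missing from some study).
#' @export
mvmr_instrument_union <- function(exposure_list, instrument_ids, outcome,
                                  ld = ld_independent(), r2_max = 0.001,
                                  window_kb = 10000, drop_palindromes = TRUE) {
  stopifnot(length(exposure_list) >= 2,
            identical(names(exposure_list), names(instrument_ids)))
  ids <- unique(unlist(instrument_ids))
  if (!length(ids)) stop("empty instrument union", call. = FALSE)
  first <- exposure_list[[1]]
  # joint re-clump on the union, ranked by the best p across exposures
  union_rows <- do.call(rbind, lapply(names(exposure_list), function(nm) {
    recs <- exposure_list[[nm]]
    recs[recs$snp_id %in% ids, intersect(c("snp_id", "chrom", "pos", "pvalue"),
                                         names(recs)), drop = FALSE]
  }))
  union_rows <- union_rows[order(union_rows$pvalue), , drop = FALSE]
  union_rows <- union_rows[!duplicated(union_rows$snp_id), , drop = FALSE]
  clumped <- ld_clump(union_rows, ld, r2_max, window_kb)
  ids <- clumped$snp_id

  present <- Reduce(intersect, c(lapply(exposure_list, function(r) r$snp_id),
                                 list(outcome$snp_id)))
  dropped <- setdiff(ids, present)
  ids <- intersect(ids, present)
  if (!length(ids)) stop("no union instruments present in every study", call. = FALSE)

  h1 <- harmonize(first[first$snp_id %in% ids, , drop = FALSE], outcome,
                  drop_palindromes = drop_palindromes)
  h1 <- retained(h1)
  ids <- h1$snp_id
  m <- length(exposure_list)
  bx <- matrix(NA_real_, length(ids), m,
               dimnames = list(ids, names(exposure_list)))
  sx <- bx
  bx[, 1] <- h1$beta_exp; sx[, 1] <- h1$se_exp
  for (j in seq_len(m)[-1]) {
    hj <- harmonize(first[first$snp_id %in% ids, , drop = FALSE],
                    exposure_list[[j]], drop_palindromes = FALSE)
    idx <- match(ids, hj$snp_id)
    bx[, j] <- hj$beta_out[idx]
    sx[, j] <- hj$se_out[idx]
  }
  ok <- stats::complete.cases(bx)
  list(bx = bx[ok, , drop = FALSE], sx = sx[ok, , drop = FALSE],
       by = h1$beta_out[ok], sy = h1$se_out[ok], snp_id = ids[ok],
       exposures = names(exposure_list),
       dropped = c(dropped, ids[!ok]))
}

#' Multivariable MR from full summary-statistic tables
#'
#' Convenience wrapper: selects instruments per exposure at the given
#' threshold, builds the joint instrument set with
#' [mvmr_instrument_union()], and fits [mvmr_ivw()].
#'
#' @inheritParams mvmr_instrument_union
#' @param p_instrument Per-exposure selection threshold; default 5e-8.
#' @param outcome_label Optional label.
#' @return An `mvmr_fit`.
#' @export
mvmr_fit <- function(exposure_list, outcome, ld = ld_independent(),
                     p_instrument = 5e-8, r2_max = 0.001, window_kb = 10000,
                     drop_palindromes = TRUE, outcome_label = NULL) {
  instrument_ids <- lapply(exposure_list, function(recs)
    ld_clump(filter_significant(recs, p_instrument), ld, r2_max, window_kb)$snp_id)
  u <- mvmr_instrument_union(exposure_list, instrument_ids, outcome,
                             ld = ld, r2_max = r2_max, window_kb = window_kb,
                             drop_palindromes = drop_palindromes)
  fit <- mvmr_ivw(u$bx, u$by, u$sy, exposures = u$exposures,
                  outcome = outcome_label)
  fit$instruments <- u$snp_id
  fit$dropped <- u$dropped
  fit
}
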