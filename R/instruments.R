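#' Keep genome-wide-significant SNPs
#'
#' @param records GWAS record data.frame with a `pvalue` column.
#' @param p_threshold Strict upper bound on p; default 5e-8.
#' @return The rows with `pvalue < p_threshold`, order preserved.
#' @export
filter_significant <- function(records, p_threshold = 5e-8) {
  records[records$pvalue < p_threshold, , drop = FALSE]
}

#' Build an LD lookup from a pairwise r-squared table
#'
#' @param pairs Data frame (or path to a 3-column TSV) with columns
#'   `snp_a`, `snp_b`, `r2`. Pairs absent from the table have r-squared 0.
#' @return A function `(id_a, id_b) -> r2`, vectorized over its arguments.
#' @export
ld_lookup <- function(pairs) {
  if (is.character(pairs))
    pairs <- utils::read.delim(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(pairs))
    for (i in seq_len(nrow(pairs)))
      assign(key(pairs$snp_a[i], pairs$snp_b[i]), pairs$r2[i], envir = env)
  function(a, b) {
    k <- key(a, b)
    vapply(k, function(kk) {
      v <- mget(kk, envir = env, ifnotfound = 0)[[1]]
      as.numeric(v)
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' All-pass LD lookup asserting independence
#' @return A lookup function that returns 0 for every pair.
#' @export
ld_independent <- function() function(a, b) rep(0, length(a))

#' Greedy LD clumping
#'
#' Ranks SNPs by ascending p-value (ties broken lexicographically on
#' `snp_id`), keeps the top SNP, removes all not-yet-kept SNPs on the same
#' chromosome within `window_kb` that have pairwise r-squared at or above
#' `r2_max` with it, and repeats until the table is exhausted.
#'
#' @param records GWAS records with `snp_id`, `pvalue` and, when
#'   `window_kb` is finite and positive, `chrom`/`pos`.
#' @param ld An LD lookup function as from [ld_lookup()]; default assumes
#'   independence.
#' @param r2_max Removal threshold; default 0.001.
#' @param window_kb Window in kilobases; default 10000.
#' @return The retained rows, in the original row order.
#' @export
ld_clump <- function(records, ld = ld_independent(), r2_max = 0.001,
                     window_kb = 10000) {
  if (!nrow(records)) return(records)
  need_pos <- window_kb > 0 && is.finite(window_kb)
  if (need_pos && (!all(c("chrom", "pos") %in% names(records)) ||
                   any(!is.finite(records$pos))))
    stop("ld_clump needs chrom/pos when window_kb is positive", call. = FALSE)
  ord <- order(records$pvalue, records$snp_id)
  alive <- rep(TRUE, nrow(records))
  kept <- logical(nrow(records))
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (!length(cand)) break
    if (need_pos) {
      cand <- cand[records$chrom[cand] == records$chrom[i] &
                   abs(records$pos[cand] - records$pos[i]) <= window_kb * 1000]
    }
    if (!length(cand)) next
    r2 <- ld(records$snp_id[i], records$snp_id[cand])
    alive[cand[r2 >= r2_max]] <- FALSE
  }
  records[kept, , drop = FALSE]
}

#' Exclude instruments associated with the outcome
#'
#' Instruments strongly associated with the outcome in their own right
#' (default p < 5e-5) are likely to violate the exclusion restriction and
#' are marked excluded with reason `"outcome_associated"`.
#'
#' @param h An `mr_harmonized` set.
#' @param p_threshold Strict outcome-p bound; default 5e-5.
#' @return The set with the exclusion reasons updated.
#' @export
exclude_outcome_associated <- function(h, p_threshold = 5e-5) {
  hit <- is.na(h$excluded_reason) & h$p_out < p_threshold
  h$excluded_reason[hit] <- "outcome_associated"
  h
}

#' Variance in a quantitative trait explained by one SNP
#'
#' r2 = 2 * EAF * (1 - EAF) * beta^2, with beta in SD units.
#'
#' @param eaf Effect-allele frequency in \[0, 1\].
#' @param beta Per-allele effect in SD units.
#' @return Variance explained, vectorized.
#' @export
variance_explained <- function(eaf, beta) {
  stopifnot(all(eaf >= 0 & eaf <= 1, na.rm = TRUE))
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument-strength F statistic
#'
#' F = ((N - k - 1) / k) * R2 / (1 - R2). With k = 1 and a single SNP's r2
#' this is the per-SNP weak-instrument screen (F < 10 flags weakness); with
#' the full instrument count k and the summed R2 it is the overall
#' diagnostic.
#'
#' @param n Sample size (must exceed k + 1).
#' @param k Number of instruments.
#' @param r2 Variance explained, in \[0, 1).
#' @return The F statistic.
#' @export
f_statistic <- function(n, k, r2) {
  if (any(r2 >= 1)) stop("r2 must be < 1", call. = FALSE)
  stopifnot(all(n > k + 1))
  ((n - k - 1) / k) * r2 / (1 - r2)
}

# Per-SNP variance explained appropriate to the trait type: allele-frequency
# form for quantitative traits, z-based approximation r2 = z^2/(z^2 + n_eff)
# with n_eff = 4 / (1/n_cases + 1/n_controls) for binary ones.
trait_r2 <- function(beta, se, eaf, n, trait_type, n_cases = NULL, n_controls = NULL) {
  if (trait_type == "binary") {
    z <- beta / se
    n_eff <- 4 / (1 / n_cases + 1 / n_controls)
    z^2 / (z^2 + n_eff)
  } else {
    variance_explained(eaf, beta)
  }
}

#' Steiger directionality filter
#'
#' Excludes instruments that explain more variance in the outcome than in
#' the exposure — evidence that the SNP primarily affects the outcome and
#' reverses the assumed causal direction. A per-SNP directionality z-score
#' (Fisher-z difference of the implied correlations) is recorded.
#'
#' @param h An `mr_harmonized` set.
#' @param exposure_meta,outcome_meta [study_meta()] objects supplying trait
#'   types and sample sizes.
#' @return The set with `steiger_z` added and failing rows marked
#'   `"steiger_fail"`.
#' @export
steiger_filter <- function(h, exposure_meta, outcome_meta) {
  if (any(!is.finite(h$n_exp)) || any(!is.finite(h$n_out)))
    stop("steiger_filter needs per-row sample sizes on both sides", call. = FALSE)
  r2_exp <- trait_r2(h$beta_exp, h$se_exp, h$eaf, h$n_exp,
                     exposure_meta$trait_type,
                     exposure_meta$n_cases, exposure_meta$n_controls)
  nc <- if ("n_cases_out" %in% names(h)) h$n_cases_out else outcome_meta$n_cases
  nk <- if ("n_controls_out" %in% names(h)) h$n_controls_out else outcome_meta$n_controls
  r2_out <- trait_r2(h$beta_out, h$se_out, h$eaf_out, h$n_out,
                     outcome_meta$trait_type, nc, nk)
  z_exp <- atanh(pmin(sqrt(pmax(r2_exp, 0)), 1 - 1e-12))
  z_out <- atanh(pmin(sqrt(pmax(r2_out, 0)), 1 - 1e-12))
  h$steiger_z <- (z_exp - z_out) / sqrt(1 / (h$n_exp - 3) + 1 / (h$n_out - 3))
  fail <- is.na(h$excluded_reason) & r2_out > r2_exp
  h$excluded_reason[fail] <- "steiger_fail"
  h
}

#' Per-SNP weak-instrument screen
#'
#' Computes each retained SNP's F (k = 1 on its own variance explained in
#' the exposure) and excludes SNPs with F below the threshold.
#'
#' @param h An `mr_harmonized` set.
#' @param f_min Exclusion threshold; default 10.
#' @return The set with `f_snp` added and weak rows marked
#'   `"weak_instrument"`.
#' @export
weak_instrument_filter <- function(h, f_min = 10) {
  r2 <- variance_explained(h$eaf, h$beta_exp)
  h$f_snp <- f_statistic(h$n_exp, 1, r2)
  weak <- is.na(h$excluded_reason) & h$f_snp < f_min
  h$excluded_reason[weak] <- "weak_instrument"
  h
}

#' Select and grade instruments for one exposure-outcome pair
#'
#' Runs the full selection chain in a fixed, logged order: genome-wide
#' significance on the exposure, greedy LD clumping, harmonization with
#' palindrome exclusion, outcome-association exclusion, Steiger
#' directionality filtering, then the per-SNP F screen. Each stage only
#' removes rows; per-stage SNP counts are recorded.
#'
#' @param exposure,outcome GWAS record data.frames.
#' @param exposure_meta,outcome_meta [study_meta()] objects.
#' @param ld LD lookup function; default assumes independence.
#' @param p_instrument Significance threshold (default 5e-8).
#' @param r2_max,window_kb Clumping parameters (defaults 0.001, 10000 kb).
#' @param p_outcome Outcome-association threshold (default 5e-5).
#' @param f_min Per-SNP F threshold (default 10).
#' @param drop_palindromes Exclude palindromic SNPs (default TRUE).
#' @param steiger Apply the Steiger filter (default TRUE).
#' @return An `mr_harmonized` set with attributes `attrition` (named stage
#'   counts) and `diagnostics` (see [instrument_diagnostics()]).
#' @export
select_instruments <- function(exposure, outcome, exposure_meta, outcome_meta,
                               ld = ld_independent(), p_instrument = 5e-8,
                               r2_max = 0.001, window_kb = 10000,
                               p_outcome = 5e-5, f_min = 10,
                               drop_palindromes = TRUE, steiger = TRUE) {
  counts <- c(input = nrow(exposure))
  sig <- filter_significant(exposure, p_instrument)
  counts["significant"] <- nrow(sig)
  clumped <- ld_clump(sig, ld, r2_max, window_kb)
  counts["clumped"] <- nrow(clumped)
  h <- harmonize(clumped, outcome, drop_palindromes = drop_palindromes)
  counts["harmonized"] <- sum(is.na(h$excluded_reason))
  h <- exclude_outcome_associated(h, p_outcome)
  counts["outcome_filtered"] <- sum(is.na(h$excluded_reason))
  if (steiger) h <- steiger_filter(h, exposure_meta, outcome_meta)
  counts["steiger"] <- sum(is.na(h$excluded_reason))
  h <- weak_instrument_filter(h, f_min)
  counts["strong"] <- sum(is.na(h$excluded_reason))
  attr(h, "attrition") <- counts
  attr(h, "diagnostics") <- instrument_diagnostics(h)
  h
}

#' Instrument-strength diagnostics for a harmonized set
#'
#' Summarises retained instruments: count, summed variance explained,
#' overall F from the k-instrument formula, the mean of per-SNP F values,
#' and Steiger bookkeeping.
#'
#' @param h An `mr_harmonized` set (with `f_snp` when available).
#' @return A list of class `instrument_diagnostics` with `k`, `r2_sum`,
#'   `f_overall`, `f_mean`, `f_per_snp`, `steiger_kept`, `steiger_dropped`.
#' @export
instrument_diagnostics <- function(h) {
  keep <- retained(h)
  k <- nrow(keep)
  r2 <- variance_explained(keep$eaf, keep$beta_exp)
  r2_sum <- sum(r2)
  n <- if (k) stats::median(keep$n_exp) else NA_real_
  f_per <- if (k) f_statistic(keep$n_exp, 1, r2) else numeric(0)
  structure(list(
    k = k,
    r2_sum = r2_sum,
    f_overall = if (k && r2_sum < 1) f_statistic(n, k, r2_sum) else NA_real_,
    f_mean = if (k) mean(f_per) else NA_real_,
    f_per_snp = f_per,
    steiger_kept = k,
    steiger_dropped = sum(!is.na(h$excluded_reason) & h$excluded_reason == "steiger_fail")
  ), class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf("Instruments: k = %d, R2 sum = %.4g, overall F = %.4g, mean per-SNP F = %.4g\n",
              x$k, x$r2_sum, x$f_overall, x$f_mean))
  if (x$steiger_dropped)
    cat("  Steiger-dropped SNPs:", x$steiger_dropped, "\n")
  invisible(x)
}
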