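# Seeded generator of GWAS summary statistics with known causal truth.
# Simulation is at the summary level: per-SNP true effects are drawn, then
# estimation noise is added with the SE implied by the sample size and
# allele frequency, so every pipeline stage can be exercised against a
# recorded ground truth without individual-level genotypes.

#' Define a synthetic two-sample MR scenario
#'
#' Collects the generating parameters of a synthetic scenario. Defaults
#' emulate a urate-style quantitative exposure GWAS (n = 437,354, effects
#' in SD units, ~300 instruments jointly explaining ~6% of variance) and a
#' FinnGen-scale binary stroke outcome (n = 311,635, case fraction 0.1278,
#' effects on the log-odds scale).
#'
#' @param beta_causal True causal effect, log-odds per exposure SD.
#' @param n_snp Number of instrument SNPs.
#' @param gamma_sd Scale of true instrument effects; magnitudes are drawn
#'   half-normal(gamma_sd), oriented to the exposure-increasing allele.
#' @param pleio_mean,pleio_sd Pleiotropy law for invalid instruments
#'   (direct SNP -> outcome effects): mean 0 is balanced, non-zero mean is
#'   directional.
#' @param frac_invalid Fraction of instruments carrying pleiotropy.
#' @param delta,tau,direct Mediation block: exposure -> mediator effect
#'   `delta`, mediator -> outcome effect `tau`, residual direct exposure ->
#'   outcome effect `direct`. All NA disables the mediator; when set, the
#'   total causal effect is `direct + delta * tau`.
#' @param n_snp_mediator Extra instruments specific to the mediator.
#' @param n_exposure,n_outcome,n_mediator Sample sizes.
#' @param case_fraction Outcome case fraction K (binary outcome).
#' @param overlap_fraction Fraction of shared samples between exposure and
#'   outcome GWAS; induces correlation `overlap_fraction *
#'   overlap_confounding` between their estimation errors.
#' @param overlap_confounding Confounding factor scaling the overlap
#'   correlation; default 1.
#' @param palindrome_fraction Fraction of SNPs given palindromic (A/T or
#'   G/C) alleles; default 0.
#' @param scramble_orientation Report a random half of outcome rows on the
#'   opposite allele orientation so harmonization has real work to do.
#' @param eaf_range Uniform range for effect-allele frequencies.
#' @param seed Integer seed; every generator run is fully determined by it.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(beta_causal = 0, n_snp = 300, gamma_sd = 0.025,
                      pleio_mean = 0, pleio_sd = 0, frac_invalid = 0,
                      delta = NA, tau = NA, direct = NA,
                      n_snp_mediator = 100,
                      n_exposure = 437354, n_outcome = 311635,
                      n_mediator = 450000, case_fraction = 0.1278,
                      overlap_fraction = 0, overlap_confounding = 1,
                      palindrome_fraction = 0, scramble_orientation = TRUE,
                      eaf_range = c(0.05, 0.95), seed = 1L) {
  stopifnot(frac_invalid >= 0, frac_invalid <= 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            n_exposure > 0, n_outcome > 0, n_snp >= 1)
  has_mediator <- !is.na(delta)
  beta_total <- if (has_mediator) direct + delta * tau else beta_causal
  structure(list(beta_causal = beta_causal, n_snp = n_snp,
                 gamma_sd = gamma_sd, pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, frac_invalid = frac_invalid,
                 delta = delta, tau = tau, direct = direct,
                 has_mediator = has_mediator, beta_total = beta_total,
                 proportion_mediated = if (has_mediator && beta_total != 0)
                   delta * tau / beta_total else NA_real_,
                 n_snp_mediator = n_snp_mediator,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 n_mediator = n_mediator, case_fraction = case_fraction,
                 overlap_fraction = overlap_fraction,
                 overlap_confounding = overlap_confounding,
                 palindrome_fraction = palindrome_fraction,
                 scramble_orientation = scramble_orientation,
                 eaf_range = eaf_range, seed = as.integer(seed)),
            class = "sim_truth")
}

# Non-palindromic allele pairs (effect, other); palindromic pairs listed
# separately for deliberate injection.
NONPAL_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                         "G","A", "G","T", "T","C", "T","G"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A","T", "T","A", "C","G", "G","C"),
                    ncol = 2, byrow = TRUE)

sim_panel <- function(n, eaf_range, palindrome_fraction) {
  pal <- stats::runif(n) < palindrome_fraction
  pick <- function(m, k) m[sample.int(nrow(m), k, replace = TRUE), , drop = FALSE]
  al <- matrix(NA_character_, n, 2)
  if (any(!pal)) al[!pal, ] <- pick(NONPAL_PAIRS, sum(!pal))
  if (any(pal)) al[pal, ] <- pick(PAL_PAIRS, sum(pal))
  data.frame(snp_id = sprintf("rs%07d", sample.int(9999999, n)),
             chrom = as.character(sample.int(22, n, replace = TRUE)),
             pos = sample.int(2.5e8, n, replace = TRUE),
             effect_allele = al[, 1], other_allele = al[, 2],
             eaf = stats::runif(n, eaf_range[1], eaf_range[2]),
             stringsAsFactors = FALSE)
}

# SE of a per-allele effect estimate from sample size and allele frequency:
# quantitative traits 1/sqrt(n * 2p(1-p)); binary (log-odds) additionally
# scaled by the case-fraction variance, 1/sqrt(n * K(1-K) * 2p(1-p)).
sim_se <- function(n, eaf, case_fraction = NULL) {
  het <- 2 * eaf * (1 - eaf)
  if (is.null(case_fraction)) 1 / sqrt(n * het)
  else 1 / sqrt(n * case_fraction * (1 - case_fraction) * het)
}

pval_from <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

# Exactly round(frac * J) instruments are invalid, at random positions, so
# a scenario's invalid composition is its stated fraction, not a binomial
# draw around it.
draw_invalid <- function(J, frac) {
  k <- round(frac * J)
  inv <- rep(FALSE, J)
  if (k > 0) inv[sample.int(J, k)] <- TRUE
  inv
}

sim_records <- function(panel, beta_hat, se, n, n_cases = NULL,
                        flip = NULL) {
  df <- panel
  if (!is.null(flip) && any(flip)) {
    # report flipped rows on the opposite allele orientation
    ea <- df$effect_allele
    df$effect_allele[flip] <- df$other_allele[flip]
    df$other_allele[flip] <- ea[flip]
    df$eaf[flip] <- 1 - df$eaf[flip]
    beta_hat[flip] <- -beta_hat[flip]
  }
  df$beta <- beta_hat
  df$se <- se
  df$pvalue <- pval_from(beta_hat, se)
  df$n <- n
  if (!is.null(n_cases)) {
    df$n_cases <- n_cases
    df$n_controls <- n - n_cases
  }
  df
}

#' Simulate an exposure/outcome GWAS pair with known causal truth
#'
#' Draws true instrument effects, adds estimation noise scaled by sample
#' size and allele frequency (with optional correlated noise for
#' overlapping samples), applies the scenario's pleiotropy law to the
#' invalid fraction, and emits two GWAS record tables plus a truth log.
#'
#' @param truth A [sim_truth()] scenario.
#' @return List with `exposure` and `outcome` record data.frames, and
#'   `truth` — the scenario augmented with the drawn per-SNP `gamma_true`,
#'   `alpha_pleio`, `invalid` flags and the SNP panel.
#' @export
simulate_two_sample <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed)
  J <- truth$n_snp
  panel <- sim_panel(J, truth$eaf_range, truth$palindrome_fraction)
  gamma <- abs(stats::rnorm(J, 0, truth$gamma_sd))
  invalid <- draw_invalid(J, truth$frac_invalid)
  alpha <- ifelse(invalid,
                  stats::rnorm(J, truth$pleio_mean, truth$pleio_sd), 0)
  Gamma <- truth$beta_causal * gamma + alpha

  se_x <- sim_se(truth$n_exposure, panel$eaf)
  se_y <- sim_se(truth$n_outcome, panel$eaf, truth$case_fraction)
  rho <- truth$overlap_fraction * truth$overlap_confounding
  e_shared <- stats::rnorm(J)
  e_x <- rho * e_shared + sqrt(1 - rho^2) * stats::rnorm(J)
  e_y <- rho * e_shared + sqrt(1 - rho^2) * stats::rnorm(J)

  flip <- if (truth$scramble_orientation) stats::runif(J) < 0.5 else rep(FALSE, J)
  exposure <- sim_records(panel, gamma + se_x * e_x, se_x, truth$n_exposure)
  n_cases <- round(truth$n_outcome * truth$case_fraction)
  outcome <- sim_records(panel, Gamma + se_y * e_y, se_y, truth$n_outcome,
                         n_cases = n_cases, flip = flip)
  truth$gamma_true <- gamma
  truth$alpha_pleio <- alpha
  truth$invalid <- invalid
  truth$panel <- panel
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate a replication outcome GWAS on an existing scenario
#'
#' Generates a second consortium's outcome GWAS for the SNP panel and true
#' instrument effects already drawn by [simulate_two_sample()], so
#' multi-study designs (replication, meta-analysis) share one genetic
#' architecture while estimation noise, sample size and case mix differ.
#'
#' @param sim Result of [simulate_two_sample()].
#' @param n_outcome,case_fraction Sample size and case fraction of the new
#'   study.
#' @param seed Integer seed for the new study's noise.
#' @param beta_causal Optional different true causal effect; defaults to
#'   the scenario's.
#' @return A GWAS record data.frame for the new outcome study.
#' @export
simulate_outcome <- function(sim, n_outcome, case_fraction, seed,
                             beta_causal = NULL) {
  truth <- sim$truth
  stopifnot(inherits(truth, "sim_truth"), !is.null(truth$panel))
  set.seed(seed)
  if (is.null(beta_causal)) beta_causal <- truth$beta_causal
  J <- truth$n_snp
  Gamma <- beta_causal * truth$gamma_true + truth$alpha_pleio
  se_y <- sim_se(n_outcome, truth$panel$eaf, case_fraction)
  flip <- if (truth$scramble_orientation) stats::runif(J) < 0.5 else rep(FALSE, J)
  sim_records(truth$panel, Gamma + se_y * stats::rnorm(J), se_y, n_outcome,
              n_cases = round(n_outcome * case_fraction), flip = flip)
}

#' Simulate harmonized summary arrays directly
#'
#' Fast path for simulation studies on the estimators: returns the
#' exposure/outcome effect arrays as if already harmonized (no allele
#' bookkeeping), under the same statistical model as
#' [simulate_two_sample()].
#'
#' @param truth A [sim_truth()] scenario.
#' @return List with `bx`, `sx`, `by`, `sy`, `snp_id` and the per-SNP
#'   truth (`gamma_true`, `alpha_pleio`, `invalid`).
#' @export
simulate_arrays <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed)
  J <- truth$n_snp
  eaf <- stats::runif(J, truth$eaf_range[1], truth$eaf_range[2])
  gamma <- abs(stats::rnorm(J, 0, truth$gamma_sd))
  invalid <- draw_invalid(J, truth$frac_invalid)
  alpha <- ifelse(invalid,
                  stats::rnorm(J, truth$pleio_mean, truth$pleio_sd), 0)
  se_x <- sim_se(truth$n_exposure, eaf)
  se_y <- sim_se(truth$n_outcome, eaf, truth$case_fraction)
  rho <- truth$overlap_fraction * truth$overlap_confounding
  e_shared <- stats::rnorm(J)
  e_x <- rho * e_shared + sqrt(1 - rho^2) * stats::rnorm(J)
  e_y <- rho * e_shared + sqrt(1 - rho^2) * stats::rnorm(J)
  list(bx = gamma + se_x * e_x, sx = se_x,
       by = truth$beta_causal * gamma + alpha + se_y * e_y, sy = se_y,
       snp_id = sprintf("snp%04d", seq_len(J)), eaf = eaf,
       gamma_true = gamma, alpha_pleio = alpha, invalid = invalid)
}

#' Simulate exposure, mediator and outcome GWAS with a mediated pathway
#'
#' The mediator's true effects are `delta * gamma` on the exposure's
#' instruments plus its own independent instruments; the outcome's true
#' effects are `direct * gamma + tau * (mediator effect)`. The true
#' proportion mediated, `delta*tau / (direct + delta*tau)`, is recorded in
#' the truth log.
#'
#' @param truth A [sim_truth()] scenario with the mediator block set.
#' @return List with `exposure`, `mediator`, `outcome` record data.frames
#'   and the augmented `truth` log.
#' @export
simulate_mediation <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"), truth$has_mediator)
  set.seed(truth$seed)
  J <- truth$n_snp
  K <- truth$n_snp_mediator
  panel <- sim_panel(J + K, truth$eaf_range, truth$palindrome_fraction)

  gamma <- c(abs(stats::rnorm(J, 0, truth$gamma_sd)), rep(0, K))
  med_own <- c(rep(0, J), abs(stats::rnorm(K, 0, truth$gamma_sd)))
  med_true <- truth$delta * gamma + med_own
  out_true <- truth$direct * gamma + truth$tau * med_true
  invalid <- draw_invalid(J + K, truth$frac_invalid)
  alpha <- ifelse(invalid,
                  stats::rnorm(J + K, truth$pleio_mean, truth$pleio_sd), 0)
  out_true <- out_true + alpha

  se_x <- sim_se(truth$n_exposure, panel$eaf)
  se_m <- sim_se(truth$n_mediator, panel$eaf)
  se_y <- sim_se(truth$n_outcome, panel$eaf, truth$case_fraction)

  n_all <- J + K
  flip <- if (truth$scramble_orientation) stats::runif(n_all) < 0.5 else rep(FALSE, n_all)
  exposure <- sim_records(panel, gamma + se_x * stats::rnorm(n_all), se_x,
                          truth$n_exposure)
  mediator <- sim_records(panel, med_true + se_m * stats::rnorm(n_all), se_m,
                          truth$n_mediator)
  n_cases <- round(truth$n_outcome * truth$case_fraction)
  outcome <- sim_records(panel, out_true + se_y * stats::rnorm(n_all), se_y,
                         truth$n_outcome, n_cases = n_cases, flip = flip)
  truth$gamma_true <- gamma
  truth$mediator_true <- med_true
  truth$outcome_true <- out_true
  truth$panel <- panel
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Simulate an LD block of correlated effect estimates
#'
#' Generates `size` SNPs on one chromosome within a narrow window whose
#' effect estimates share an equicorrelated component with pairwise
#' correlation `sqrt(r2)` (so the squared correlation matches the stated
#' genotype r-squared), together with the matching 3-column LD table.
#'
#' @param size Number of SNPs in the block (>= 2).
#' @param r2 Pairwise genotype r-squared in \[0, 1).
#' @param n Sample size for the SEs; default 437354.
#' @param beta_scale Scale of the shared signal; default 0.03.
#' @param seed Integer seed.
#' @return List with `records` (GWAS record data.frame) and `ld` (data
#'   frame with `snp_a`, `snp_b`, `r2`).
#' @export
simulate_ld_block <- function(size, r2, n = 437354, beta_scale = 0.03,
                              seed = 1L) {
  stopifnot(size >= 2, r2 >= 0, r2 < 1)
  set.seed(seed)
  panel <- sim_panel(size, c(0.05, 0.95), 0)
  panel$chrom <- "1"
  panel$pos <- sort(sample.int(5e5, size)) + 1e6
  panel$eaf <- rep(0.5, size) # equal SEs keep the block exactly equicorrelated
  rho <- sqrt(r2)
  se <- sim_se(n, panel$eaf)
  equicorr <- function(k) {
    g <- stats::rnorm(1)
    sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(k)
  }
  true_eff <- beta_scale * equicorr(size)   # correlated true effects
  beta_hat <- true_eff + se * equicorr(size) # plus correlated estimation noise
  rec <- sim_records(panel, beta_hat, se, n)
  pairs <- t(utils::combn(size, 2))
  ld <- data.frame(snp_a = panel$snp_id[pairs[, 1]],
                   snp_b = panel$snp_id[pairs[, 2]],
                   r2 = r2, stringsAsFactors = FALSE)
  list(records = rec, ld = ld)
}

#' Write a simulated scenario to GWAS TSV files plus a truth log
#'
#' @param sim Result of [simulate_two_sample()] or [simulate_mediation()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; writes `<role>.tsv` per record set and
#'   `truth.json` (requires jsonlite) or `truth.txt`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roles <- intersect(c("exposure", "mediator", "outcome"), names(sim))
  for (r in roles) {
    df <- sim[[r]]
    names(df) <- c(SNP = "snp_id", CHR = "chrom", POS = "pos", EA = "effect_allele",
                   OA = "other_allele", EAF = "eaf", BETA = "beta", SE = "se",
                   P = "pvalue", N = "n", N_CASES = "n_cases",
                   N_CONTROLS = "n_controls")[match(names(df),
                     c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                       "eaf", "beta", "se", "pvalue", "n", "n_cases", "n_controls"))]
    utils::write.table(df, file.path(dir, paste0(r, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tl <- sim$truth[setdiff(names(sim$truth), "panel")]
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(tl, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.table(utils::capture.output(utils::str(tl)),
                       file.path(dir, "truth.txt"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
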