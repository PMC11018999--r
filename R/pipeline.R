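# Study orchestration: per-outcome univariable MR with the sensitivity
# stack, reverse MR, multivariable adjustment, mediation, and
# cross-consortium meta-analysis, with stage-level attrition logging.

#' Assemble a study configuration
#'
#' @param exposure List with `records` (data.frame or file path) and `meta`
#'   ([study_meta()]).
#' @param outcomes Named list of outcome specs, each a list with `records`
#'   and `meta`.
#' @param covariates Named list of additional trait specs (confounders and
#'   mediators), same shape.
#' @param mvmr_sets Named list of character vectors: covariate names to
#'   adjust for jointly, fitted per outcome (e.g. `list(bp = c("sbp",
#'   "dbp"))`). Empty list disables MVMR.
#' @param mediators Character vector of covariate names to test as
#'   mediators per outcome. Empty disables mediation.
#' @param meta_groups Named list of character vectors of outcome labels to
#'   pool per meta-analysis.
#' @param p_instrument,r2_max,window_kb,p_outcome,f_min Selection
#'   thresholds (defaults 5e-8, 0.001, 10000 kb, 5e-5, 10).
#' @param alpha Significance level; default 0.05.
#' @param n_outcomes Number of outcomes for the Bonferroni threshold;
#'   defaults to `length(outcomes)`.
#' @param methods Univariable estimators to run.
#' @param presso Run MR-PRESSO and report post-outlier-removal IVW.
#' @param reverse Run reverse-direction MR per outcome.
#' @param power_or Hypothesized OR for the power diagnostic; default 1.1.
#' @param ld LD lookup; default independence.
#' @param n_boot,n_sim Bootstrap/simulation sizes.
#' @param seed Integer master seed.
#' @param out_dir Output directory for the TSV tables.
#' @return A list of class `study_config`.
#' @export
study_config <- function(exposure, outcomes, covariates = list(),
                         mvmr_sets = list(), mediators = character(),
                         meta_groups = list(),
                         p_instrument = 5e-8, r2_max = 0.001,
                         window_kb = 10000, p_outcome = 5e-5, f_min = 10,
                         alpha = 0.05, n_outcomes = length(outcomes),
                         methods = c("ivw_mre", "egger", "weighted_median"),
                         presso = TRUE, reverse = TRUE, power_or = 1.1,
                         ld = ld_independent(), n_boot = 1000, n_sim = 1000,
                         seed = 1L, out_dir = tempfile("mr_study_")) {
  stopifnot(length(outcomes) >= 1, !is.null(names(outcomes)))
  stopifnot(p_instrument > 0, r2_max > 0, window_kb > 0, p_outcome > 0,
            f_min > 0, alpha > 0)
  for (nm in unlist(mvmr_sets)) if (!nm %in% names(covariates))
    stop("mvmr_sets references unknown covariate: ", nm, call. = FALSE)
  for (nm in mediators) if (!nm %in% names(covariates))
    stop("mediators references unknown covariate: ", nm, call. = FALSE)
  structure(as.list(environment()), class = "study_config")
}

resolve_records <- function(spec) {
  if (is.character(spec$records))
    read_summary_stats(spec$records, spec$meta, quiet = TRUE)
  else spec$records
}

#' Run the full MR study described by a configuration
#'
#' Per outcome: instrument selection with stage-by-stage attrition,
#' univariable estimation (IVW-MRE, MR-Egger, weighted median, and IVW
#' after MR-PRESSO outlier removal), a diagnostics row (nSNP, Cochran's Q
#' and p, Egger intercept and p, R-squared sum, overall and mean F, power),
#' and reverse-direction MR. Then multivariable adjustment per configured
#' covariate set, two-step mediation per configured mediator, and
#' meta-analysis of the IVW estimates per configured outcome group. A
#' failing stage is recorded and the remaining outcomes still run. Results
#' are returned and written as TSV tables to `config$out_dir`.
#'
#' @param config A [study_config()].
#' @return A list of class `study_result` with elements `uvmr`,
#'   `diagnostics`, `reverse`, `mvmr`, `mediation`, `meta` (data.frames),
#'   `fits` (per-outcome objects), `attrition` and `log`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  exposure <- resolve_records(config$exposure)
  out_recs <- lapply(config$outcomes, resolve_records)
  cov_recs <- lapply(config$covariates, resolve_records)
  logline <- character()
  say <- function(...) logline <<- c(logline, sprintf(...))
  say("seed=%d", config$seed)

  methods <- config$methods
  if (config$presso) methods <- union(methods, "presso")
  uvmr_rows <- list(); diag_rows <- list(); rev_rows <- list()
  fits <- list(); attrition <- list(); errors <- list()

  for (i in seq_along(out_recs)) {
    label <- names(out_recs)[i]
    res <- try({
      sel <- select_instruments(exposure, out_recs[[i]],
                                config$exposure$meta,
                                config$outcomes[[i]]$meta,
                                ld = config$ld,
                                p_instrument = config$p_instrument,
                                r2_max = config$r2_max,
                                window_kb = config$window_kb,
                                p_outcome = config$p_outcome,
                                f_min = config$f_min)
      attrition[[label]] <- attr(sel, "attrition")
      say("[%s] attrition: %s", label,
          paste(sprintf("%s=%d", names(attrition[[label]]),
                        attrition[[label]]), collapse = " "))
      fit <- mr_fit(sel, methods = methods, outcome = label,
                    n_boot = config$n_boot, n_sim = config$n_sim,
                    seed = config$seed + i)
      fits[[label]] <- fit
      uvmr_rows[[label]] <- estimates_table(fit)

      d <- attr(sel, "diagnostics")
      ivw <- fit$estimates$ivw_mre
      eg <- fit$estimates$egger
      om <- config$outcomes[[i]]$meta
      pw <- if (om$trait_type == "binary" && d$r2_sum > 0 && d$r2_sum < 1)
        100 * mr_power_binary(om$n, om$n_cases / om$n, d$r2_sum,
                              config$power_or, config$alpha)
      else NA_real_
      diag_rows[[label]] <- data.frame(
        outcome = label, n_snp = d$k,
        q = if (is.null(ivw)) NA_real_ else ivw$q,
        q_pvalue = if (is.null(ivw)) NA_real_ else ivw$q_pvalue,
        egger_intercept = if (is.null(eg)) NA_real_ else eg$egger_intercept,
        intercept_p = if (is.null(eg)) NA_real_ else eg$intercept_p,
        r2_sum = d$r2_sum, f_overall = d$f_overall, f_mean = d$f_mean,
        power_pct = pw, stringsAsFactors = FALSE)

      if (config$reverse) {
        rv <- reverse_mr(out_recs[[i]], exposure, config$outcomes[[i]]$meta,
                         config$exposure$meta, ld = config$ld,
                         p_instrument = config$p_instrument,
                         r2_max = config$r2_max, window_kb = config$window_kb,
                         p_outcome = config$p_outcome, f_min = config$f_min)
        rev_rows[[label]] <- if (rv$status == "ok") {
          cbind(data.frame(outcome = label, direction = "reverse",
                           status = "ok", stringsAsFactors = FALSE),
                estimates_table(rv$fit)[, -(1:2)])
        } else data.frame(outcome = label, direction = "reverse",
                          status = rv$status, stringsAsFactors = FALSE)
      }
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      errors[[label]] <- conditionMessage(attr(res, "condition"))
      say("[%s] FAILED: %s", label, errors[[label]])
    }
  }

  # multivariable adjustment per covariate set, per outcome
  mvmr_rows <- list()
  for (set_name in names(config$mvmr_sets)) {
    covs <- config$mvmr_sets[[set_name]]
    for (label in names(out_recs)) {
      res <- try({
        xl <- c(list(exposure = exposure), cov_recs[covs])
        fit <- mvmr_fit(xl, out_recs[[label]], ld = config$ld,
                        p_instrument = config$p_instrument,
                        r2_max = config$r2_max, window_kb = config$window_kb,
                        outcome_label = label)
        mvmr_rows[[paste(set_name, label)]] <- data.frame(
          set = set_name, outcome = label, exposure = fit$exposures,
          beta = fit$beta, se = fit$se, ci_low = fit$ci_low,
          ci_high = fit$ci_high, pvalue = fit$pvalue, n_snp = fit$n_snp,
          q = fit$q, q_pvalue = fit$q_pvalue, stringsAsFactors = FALSE)
        NULL
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        errors[[paste("mvmr", set_name, label)]] <-
          conditionMessage(attr(res, "condition"))
    }
  }

  # two-step mediation per mediator, per outcome
  med_rows <- list()
  for (md in config$mediators) {
    for (label in names(out_recs)) {
      res <- try({
        m <- two_step_mediation(exposure, cov_recs[[md]], out_recs[[label]],
                                ld = config$ld,
                                p_instrument = config$p_instrument,
                                labels = c(md, label))
        med_rows[[paste(md, label)]] <- data.frame(
          mediator = md, outcome = label, beta1 = m$beta1, se1 = m$se1,
          beta2 = m$beta2, se2 = m$se2, indirect = m$indirect,
          se_indirect = m$se_indirect, p_indirect = m$p_indirect,
          total = m$total, proportion_pct = m$proportion_pct,
          prop_ci_low = m$prop_ci_low, prop_ci_high = m$prop_ci_high,
          stringsAsFactors = FALSE)
        NULL
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        errors[[paste("mediation", md, label)]] <-
          conditionMessage(attr(res, "condition"))
    }
  }

  # meta-analysis of IVW estimates per outcome group
  meta_rows <- list()
  for (grp in names(config$meta_groups)) {
    members <- config$meta_groups[[grp]]
    ests <- lapply(fits[members], function(f) f$estimates$ivw_mre)
    ests <- ests[!vapply(ests, is.null, logical(1))]
    if (length(ests) >= 2) {
      mm <- meta_ivw(ests, model = "fixed", labels = names(ests))
      meta_rows[[grp]] <- data.frame(
        group = grp, k = mm$k, beta = mm$beta, se = mm$se,
        or = exp(mm$beta), ci_low = mm$ci_low, ci_high = mm$ci_high,
        pvalue = mm$pvalue, q = mm$q, p_heterogeneity = mm$p_heterogeneity,
        i2 = mm$i2, stringsAsFactors = FALSE)
    }
  }

  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL
  out <- structure(list(
    uvmr = bind(uvmr_rows), diagnostics = bind(diag_rows),
    reverse = bind(rev_rows), mvmr = bind(mvmr_rows),
    mediation = bind(med_rows), meta = bind(meta_rows),
    fits = fits, attrition = attrition, errors = errors,
    bonferroni = bonferroni_threshold(config$alpha, config$n_outcomes),
    log = logline, config = config), class = "study_result")

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tbl in c("uvmr", "diagnostics", "reverse", "mvmr", "mediation", "meta")) {
    df <- out[[tbl]]
    if (!is.null(df)) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
      utils::write.table(df, file.path(config$out_dir, paste0(tbl, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  writeLines(out$log, file.path(config$out_dir, "run_log.txt"))
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("MR study result:", length(x$fits), "outcome(s) analysed\n")
  cat("Bonferroni threshold:", format(x$bonferroni, digits = 3), "\n")
  if (!is.null(x$uvmr)) {
    cat("\nUnivariable estimates:\n")
    print(x$uvmr[, c("method", "outcome", "n_snp", "beta", "se", "or",
                     "pvalue")], digits = 3, row.names = FALSE)
  }
  if (!is.null(x$meta)) {
    cat("\nMeta-analysis:\n")
    print(x$meta, digits = 3, row.names = FALSE)
  }
  if (length(x$errors)) {
    cat("\nFailed stages:\n")
    for (nm in names(x$errors)) cat(" ", nm, "->", x$errors[[nm]], "\n")
  }
  invisible(x)
}
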