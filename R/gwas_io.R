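#' Default column dialect for GWAS summary-statistic files
#'
#' Maps canonical record fields to the header names used in the tab-delimited
#' input. Override entries to read other consortium dialects (FinnGen,
#' MEGASTROKE, ...) without rewriting the file.
#'
#' @return Named character vector, names are canonical fields, values are
#'   file column headers.
#' @export
default_column_map <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pvalue = "P", n = "N",
    n_cases = "N_CASES", n_controls = "N_CONTROLS")
}

#' Describe one GWAS study
#'
#' Bundles the metadata needed to interpret a summary-statistic file: trait
#' type (quantitative traits report effects in SD units, binary traits on the
#' log-odds scale), sample sizes, optional SD scaling of the exposure unit
#' (e.g. 80.3 umol/L per SD for serum urate), and the column dialect.
#'
#' @param study_label Short label used in outputs.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n Total sample size.
#' @param n_cases Number of cases; required for binary traits.
#' @param sd_unit Optional positive scale of one exposure SD in natural units.
#' @param column_map Named character vector mapping canonical fields to file
#'   headers; defaults to [default_column_map()].
#' @return An object of class `study_meta`.
#' @export
study_meta <- function(study_label, trait_type = c("quantitative", "binary"),
                       n, n_cases = NULL, sd_unit = NULL,
                       column_map = default_column_map()) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "binary" && is.null(n_cases))
    stop("binary traits must carry n_cases", call. = FALSE)
  if (!is.null(sd_unit) && sd_unit <= 0)
    stop("sd_unit must be positive", call. = FALSE)
  map <- default_column_map()
  map[names(column_map)] <- column_map
  structure(list(study_label = study_label, trait_type = trait_type,
                 n = as.integer(n),
                 n_cases = if (is.null(n_cases)) NULL else as.integer(n_cases),
                 n_controls = if (is.null(n_cases)) NULL else as.integer(n - n_cases),
                 sd_unit = sd_unit, column_map = map),
            class = "study_meta")
}

#' @export
print.study_meta <- function(x, ...) {
  cat("GWAS study:", x$study_label, sprintf("(%s)\n", x$trait_type))
  cat("  n =", x$n)
  if (!is.null(x$n_cases)) cat(" (", x$n_cases, "cases /", x$n_controls, "controls )")
  cat("\n")
  invisible(x)
}

VALID_ALLELES <- c("A", "C", "G", "T")

# Row-level validation of a parsed summary-statistic table. Returns a list
# with the clean data.frame and a character vector of drop reasons.
validate_gwas_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  bad(!(df$effect_allele %in% VALID_ALLELES) |
      !(df$other_allele %in% VALID_ALLELES), "non_biallelic_snp")
  bad(df$effect_allele == df$other_allele, "identical_alleles")
  bad(!is.finite(df$beta), "missing_beta")
  bad(!is.finite(df$se) | df$se <= 0, "nonpositive_se")
  bad(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1, "invalid_pvalue")
  if ("eaf" %in% names(df))
    bad(is.finite(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf_out_of_range")
  list(keep = df[is.na(reason), , drop = FALSE], reason = reason)
}

#' Read a GWAS summary-statistic file
#'
#' Reads a tab-delimited file of per-SNP association summaries, remaps its
#' headers through `meta$column_map`, coerces and validates each row
#' (biallelic A/C/G/T alleles, positive SE, p in (0, 1], EAF in \[0, 1\]) and
#' drops failing rows with a message. Duplicate SNP identifiers keep the
#' lowest-p row. Indels and multi-allelic rows are rejected.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param meta A [study_meta()] object describing the file.
#' @param quiet Suppress the dropped-row message.
#' @return A `data.frame` with canonical columns (`snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, and
#'   for binary traits `n_cases`/`n_controls`), one row per retained SNP,
#'   with attribute `n_dropped`.
#' @export
read_summary_stats <- function(path, meta, quiet = FALSE) {
  stopifnot(inherits(meta, "study_meta"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  map <- meta$column_map
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- mandatory[!(map[mandatory] %in% names(raw))]
  if (length(missing_cols))
    stop("column_map does not resolve mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  present <- names(map)[map %in% names(raw)]
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                   lapply(stats::setNames(map[present], present),
                          function(col) raw[[col]]))
  numf <- intersect(c("pos", "eaf", "beta", "se", "pvalue", "n",
                      "n_cases", "n_controls"), names(df))
  for (f in numf) df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  chrf <- intersect(c("snp_id", "chrom", "effect_allele", "other_allele"), names(df))
  for (f in chrf) df[[f]] <- toupper(as.character(df[[f]]))
  df$snp_id <- as.character(raw[[map[["snp_id"]]]])

  # fall back on study metadata when the file lacks sample-size columns
  if (!("n" %in% names(df)) || all(!is.finite(df$n))) df$n <- meta$n
  if (meta$trait_type == "binary") {
    if (!("n_cases" %in% names(df)) || all(!is.finite(df$n_cases)))
      df$n_cases <- meta$n_cases
    if (!("n_controls" %in% names(df)) || all(!is.finite(df$n_controls)))
      df$n_controls <- meta$n_controls
  }

  v <- validate_gwas_rows(df)
  out <- v$keep
  n_invalid <- sum(!is.na(v$reason))

  # duplicate snp_id: keep the lowest-p row
  n_dup <- 0L
  if (anyDuplicated(out$snp_id)) {
    out <- out[order(out$pvalue), , drop = FALSE]
    dup <- duplicated(out$snp_id)
    n_dup <- sum(dup)
    out <- out[!dup, , drop = FALSE]
    out <- out[order(as.integer(rownames(out))), , drop = FALSE]
  }
  rownames(out) <- NULL
  if (!quiet && (n_invalid || n_dup))
    message(sprintf("[%s] dropped %d invalid row(s), %d duplicate snp_id row(s)",
                    meta$study_label, n_invalid, n_dup))
  attr(out, "n_dropped") <- n_invalid + n_dup
  attr(out, "study_label") <- meta$study_label
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome effects to a shared effect allele
#'
#' Aligns the outcome (and optionally further traits) to the exposure's
#' effect-allele orientation for every SNP present in both studies. Outcome
#' rows whose alleles are swapped get their beta sign flipped and EAF
#' complemented; rows on the opposite strand are complemented first; A/T and
#' G/C palindromic SNPs are excluded when `drop_palindromes` is set (strand
#' cannot be resolved for them); irreconcilable allele pairs are excluded
#' with reason `"allele_mismatch"`. SNPs absent from the outcome are dropped.
#'
#' @param exposure,outcome Data frames as returned by [read_summary_stats()].
#' @param drop_palindromes Exclude palindromic (A/T, G/C) SNPs. Default TRUE.
#' @return A `data.frame` of class `mr_harmonized` with columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta_exp`,
#'   `se_exp`, `p_exp`, `n_exp`, `beta_out`, `se_out`, `p_out`, `n_out`
#'   (plus case/control counts when present), `flipped`, `palindromic` and
#'   `excluded_reason` (NA for retained rows). Rows with a non-NA
#'   `excluded_reason` are kept in the table for auditing; estimators use
#'   only retained rows.
#' @export
harmonize <- function(exposure, outcome, drop_palindromes = TRUE) {
  common <- intersect(exposure$snp_id, outcome$snp_id)
  ex <- exposure[match(common, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(common, outcome$snp_id), , drop = FALSE]

  h <- data.frame(snp_id = common, stringsAsFactors = FALSE)
  h$chrom <- if ("chrom" %in% names(ex)) ex$chrom else NA_character_
  h$pos <- if ("pos" %in% names(ex)) ex$pos else NA_real_
  h$effect_allele <- ex$effect_allele
  h$other_allele <- ex$other_allele
  h$eaf <- if ("eaf" %in% names(ex)) ex$eaf else NA_real_
  h$beta_exp <- ex$beta; h$se_exp <- ex$se; h$p_exp <- ex$pvalue
  h$n_exp <- ex$n

  o_ea <- ou$effect_allele; o_oa <- ou$other_allele
  o_beta <- ou$beta; o_eaf <- if ("eaf" %in% names(ou)) ou$eaf else rep(NA_real_, nrow(ou))

  same <- o_ea == h$effect_allele & o_oa == h$other_allele
  swap <- o_ea == h$other_allele & o_oa == h$effect_allele
  comp_same <- COMPLEMENT[o_ea] == h$effect_allele & COMPLEMENT[o_oa] == h$other_allele
  comp_swap <- COMPLEMENT[o_ea] == h$other_allele & COMPLEMENT[o_oa] == h$effect_allele
  pal <- is_palindromic(h$effect_allele, h$other_allele)
  # on palindromic SNPs strand complement is indistinguishable from a swap
  comp_same[pal] <- FALSE
  comp_swap[pal] <- FALSE

  flip <- (swap | comp_swap) & !same & !comp_same
  o_beta[flip] <- -o_beta[flip]
  o_eaf[flip] <- 1 - o_eaf[flip]
  ok <- same | swap | comp_same | comp_swap

  h$beta_out <- o_beta; h$se_out <- ou$se; h$p_out <- ou$pvalue
  h$n_out <- ou$n
  if ("n_cases" %in% names(ou)) h$n_cases_out <- ou$n_cases
  if ("n_controls" %in% names(ou)) h$n_controls_out <- ou$n_controls
  h$eaf_out <- o_eaf
  h$flipped <- flip
  h$palindromic <- pal
  h$excluded_reason <- NA_character_
  h$excluded_reason[!ok] <- "allele_mismatch"
  if (drop_palindromes)
    h$excluded_reason[pal & is.na(h$excluded_reason)] <- "palindrome"
  class(h) <- c("mr_harmonized", "data.frame")
  h
}

#' Retained (non-excluded) rows of a harmonized set
#' @param h An `mr_harmonized` data frame.
#' @return The subset of rows with no exclusion reason.
#' @export
retained <- function(h) {
  out <- h[is.na(h$excluded_reason), , drop = FALSE]
  class(out) <- class(h)
  out
}

#' @export
print.mr_harmonized <- function(x, ...) {
  n_keep <- sum(is.na(x$excluded_reason))
  cat(sprintf("Harmonized instrument set: %d SNPs (%d retained, %d excluded)\n",
              nrow(x), n_keep, nrow(x) - n_keep))
  if (n_keep < nrow(x)) {
    tab <- table(x$excluded_reason)
    cat("  exclusions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Write MR estimates to a results TSV
#'
#' One row per estimate with columns `method`, `outcome`, `n_snp`, `beta`,
#' `se`, `or` (= exp(beta)), `ci_low`, `ci_high`, `or_ci_low`, `or_ci_high`,
#' `pvalue`, `q`, `q_pvalue`, `egger_intercept`, `intercept_se`,
#' `intercept_p`. Numbers are written with enough digits to round-trip.
#'
#' @param estimates A list of `mr_estimate` objects (or an `mr_fit`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(estimates, path) {
  df <- estimates_table(estimates)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#' @param path File path.
#' @return A data.frame with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (f in setdiff(names(df), c("method", "outcome")))
    df[[f]] <- as.numeric(df[[f]])
  df
}

# Flatten estimates into the results-table schema.
estimates_table <- function(estimates) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  if (inherits(estimates, "mr_fit")) estimates <- estimates$estimates
  cols <- c("method", "outcome", "n_snp", "beta", "se", "or", "ci_low",
            "ci_high", "or_ci_low", "or_ci_high", "pvalue", "q", "q_pvalue",
            "egger_intercept", "intercept_se", "intercept_p")
  rows <- lapply(estimates, function(e) {
    r <- data.frame(method = e$method,
                    outcome = if (is.null(e$outcome)) NA_character_ else e$outcome,
                    n_snp = e$n_snp, beta = e$beta, se = e$se,
                    or = exp(e$beta), ci_low = e$ci_low, ci_high = e$ci_high,
                    or_ci_low = exp(e$ci_low), or_ci_high = exp(e$ci_high),
                    pvalue = e$pvalue,
                    q = if (is.null(e$q)) NA_real_ else e$q,
                    q_pvalue = if (is.null(e$q_pvalue)) NA_real_ else e$q_pvalue,
                    egger_intercept = if (is.null(e$egger_intercept)) NA_real_ else e$egger_intercept,
                    intercept_se = if (is.null(e$intercept_se)) NA_real_ else e$intercept_se,
                    intercept_p = if (is.null(e$intercept_p)) NA_real_ else e$intercept_p,
                    stringsAsFactors = FALSE)
    r
  })
  if (!length(rows)) {
    df <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  do.call(rbind, rows)
}
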