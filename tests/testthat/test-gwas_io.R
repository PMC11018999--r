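test_that("summary-statistic reader maps columns, validates rows and dedups", {
  df <- records_df(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                   se = c(0.01, 0.02, 0.01))
  path <- write_gwas_tsv(df, tempfile(fileext = ".tsv"))
  rec <- read_summary_stats(path, quant_meta(), quiet = TRUE)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$snp_id, df$snp_id)
  expect_equal(rec$beta, df$beta)
  expect_equal(rec$se, df$se)

  # SE = 0 row dropped and counted
  bad <- df; bad$se[2] <- 0
  path2 <- write_gwas_tsv(bad, tempfile(fileext = ".tsv"))
  rec2 <- read_summary_stats(path2, quant_meta(), quiet = TRUE)
  expect_equal(rec2$snp_id, c("rs1", "rs3"))
  expect_equal(attr(rec2, "n_dropped"), 1L)

  # indel / multi-allelic rows rejected
  indel <- df; indel$other_allele[1] <- "AG"
  path3 <- write_gwas_tsv(indel, tempfile(fileext = ".tsv"))
  expect_equal(nrow(read_summary_stats(path3, quant_meta(), quiet = TRUE)), 2)

  # duplicate snp_id keeps the lowest-p row (p distinct and non-degenerate)
  base <- records_df(c("rs1", "rs2"), beta = c(0.1, 0.2), se = c(0.05, 0.05))
  dup <- rbind(base, records_df("rs1", beta = 0.15, se = 0.05))
  path4 <- write_gwas_tsv(dup, tempfile(fileext = ".tsv"))
  rec4 <- read_summary_stats(path4, quant_meta(), quiet = TRUE)
  expect_equal(sum(rec4$snp_id == "rs1"), 1)
  expect_equal(rec4$beta[rec4$snp_id == "rs1"], 0.15)

  # missing mandatory column is a configuration error
  nose <- df[, setdiff(names(df), "se")]
  path5 <- write_gwas_tsv(nose, tempfile(fileext = ".tsv"))
  expect_error(read_summary_stats(path5, quant_meta(), quiet = TRUE),
               "mandatory")
})

test_that("alternative header dialects read identically through column_map", {
  df <- records_df(c("rs1", "rs2"), beta = c(0.1, -0.2), se = c(0.01, 0.02))
  default_path <- write_gwas_tsv(df, tempfile(fileext = ".tsv"))
  finn_headers <- c(snp_id = "rsids", chrom = "#chrom", pos = "pos",
                    effect_allele = "alt", other_allele = "ref",
                    eaf = "af_alt", beta = "beta", se = "sebeta",
                    pvalue = "pval", n = "n")
  finn_path <- write_gwas_tsv(df, tempfile(fileext = ".tsv"), finn_headers)
  finn_meta <- study_meta("finngen", "quantitative", 437354,
                          column_map = finn_headers)
  a <- read_summary_stats(default_path, quant_meta(), quiet = TRUE)
  b <- read_summary_stats(finn_path, finn_meta, quiet = TRUE)
  attr(a, "study_label") <- attr(b, "study_label") <- NULL
  expect_equal(a, b)
})

test_that("harmonization resolves all allele orientations per the truth table", {
  # exposure rows all EA=A / OA=G, beta 0.1
  cases <- list(
    #    outcome EA/OA  beta  expect_beta flipped reason
    list(c("A", "G"), 0.05, 0.05, FALSE, NA),        # same orientation
    list(c("G", "A"), 0.05, -0.05, TRUE, NA),        # swapped
    list(c("T", "C"), 0.05, 0.05, FALSE, NA),        # strand complement
    list(c("C", "T"), 0.05, -0.05, TRUE, NA),        # complement + swap
    list(c("A", "C"), 0.05, NA, FALSE, "allele_mismatch"),
    list(c("C", "G"), 0.05, NA, FALSE, "allele_mismatch")
  )
  for (cs in cases) {
    ex <- records_df("rs1", beta = 0.1, se = 0.01)
    ou <- records_df("rs1", beta = cs[[2]], se = 0.01,
                     ea = cs[[1]][1], oa = cs[[1]][2])
    h <- harmonize(ex, ou)
    if (is.na(cs[[5]])) {
      expect_true(is.na(h$excluded_reason))
      expect_equal(h$beta_out, cs[[3]])
      expect_equal(h$flipped, cs[[4]])
    } else {
      expect_equal(h$excluded_reason, cs[[5]])
    }
  }
})

test_that("palindromic SNPs are excluded when requested, kept otherwise", {
  ex <- records_df(c("rs1", "rs2"), beta = c(0.1, 0.1), se = c(0.01, 0.01),
                   ea = c("A", "G"), oa = c("T", "C"))
  ou <- records_df(c("rs1", "rs2"), beta = c(0.05, 0.05), se = c(0.01, 0.01),
                   ea = c("A", "G"), oa = c("T", "C"))
  h <- harmonize(ex, ou, drop_palindromes = TRUE)
  expect_equal(h$excluded_reason, c("palindrome", "palindrome"))
  h2 <- harmonize(ex, ou, drop_palindromes = FALSE)
  expect_true(all(is.na(h2$excluded_reason)))
})

test_that("harmonization is idempotent and orientation-invariant downstream", {
  sim <- simulate_two_sample(sim_truth(beta_causal = 0.1, n_snp = 60,
                                       seed = 101))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # re-harmonizing the aligned tables changes nothing
  ou2 <- sim$outcome
  idx <- match(h1$snp_id, ou2$snp_id)
  ou2$effect_allele[idx] <- h1$effect_allele
  ou2$other_allele[idx] <- h1$other_allele
  ou2$beta[idx] <- h1$beta_out
  ou2$eaf[idx] <- h1$eaf_out
  h2 <- harmonize(sim$exposure, ou2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_false(any(h2$flipped))

  # flipping both studies' effect alleles leaves the causal estimate unchanged
  flip_all <- function(df) {
    tmp <- df$effect_allele
    df$effect_allele <- df$other_allele
    df$other_allele <- tmp
    df$beta <- -df$beta
    df$eaf <- 1 - df$eaf
    df
  }
  e1 <- ivw_mre(retained(h1))
  e2 <- ivw_mre(retained(harmonize(flip_all(sim$exposure),
                                   flip_all(sim$outcome))))
  expect_equal(e2$beta, e1$beta, tolerance = 1e-12)
  expect_equal(e2$se, e1$se, tolerance = 1e-12)
})

test_that("exclusion reasons partition the intersected SNPs", {
  sim <- simulate_two_sample(sim_truth(n_snp = 80, palindrome_fraction = 0.2,
                                       seed = 7))
  h <- harmonize(sim$exposure, sim$outcome)
  n_common <- length(intersect(sim$exposure$snp_id, sim$outcome$snp_id))
  expect_equal(sum(is.na(h$excluded_reason)) + sum(!is.na(h$excluded_reason)),
               n_common)
  expect_true(all(h$excluded_reason[!is.na(h$excluded_reason)] %in%
                  c("palindrome", "allele_mismatch")))
})

test_that("results TSV round-trips estimates losslessly", {
  set.seed(3)
  ests <- lapply(1:5, function(i) {
    a <- simulate_arrays(sim_truth(beta_causal = 0.1, n_snp = 20,
                                   seed = 300 + i))
    ivw_mre(a, outcome = paste0("out", i))
  })
  path <- tempfile(fileext = ".tsv")
  write_results(ests, path)
  back <- read_results(path)
  expect_equal(nrow(back), 5)
  for (i in 1:5) {
    expect_equal(back$beta[i], ests[[i]]$beta, tolerance = 1e-9)
    expect_equal(back$se[i], ests[[i]]$se, tolerance = 1e-9)
    expect_equal(back$q[i], ests[[i]]$q, tolerance = 1e-9)
    expect_equal(back$or[i], exp(ests[[i]]$beta), tolerance = 1e-9)
  }

  # empty estimate list -> header-only file
  p2 <- tempfile(fileext = ".tsv")
  write_results(list(), p2)
  expect_equal(nrow(read_results(p2)), 0)
  expect_true("method" %in% names(read_results(p2)))

  # beta = 0 -> OR exactly 1
  e0 <- ivw_mre(list(bx = c(0.1, 0.2), sx = c(0.01, 0.01),
                     by = c(0, 0), sy = c(0.01, 0.01)))
  p3 <- tempfile(fileext = ".tsv")
  write_results(list(e0), p3)
  expect_equal(read_results(p3)$or, 1)
})
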