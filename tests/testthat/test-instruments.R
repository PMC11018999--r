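test_that("significance filter is strict and order-preserving", {
  rec <- records_df(paste0("rs", 1:10),
                    beta = rep(0.1, 10), se = rep(0.01, 10))
  rec$pvalue <- c(5e-8, 1e-9, 0.5, 4.9e-8, 1e-20, 0.04, 5e-8, 1e-10,
                  0.9, 2e-8)
  out <- filter_significant(rec)
  expect_equal(out$snp_id, paste0("rs", c(2, 4, 5, 8, 10)))  # strict <
  all_sig <- rec; all_sig$pvalue <- 1e-9
  expect_equal(filter_significant(all_sig), all_sig)
})

test_that("greedy LD clumping matches a brute-force oracle", {
  # dominance: stronger SNP absorbs a linked one 5 Mb away
  rec <- records_df(c("a", "b"), beta = c(0.1, 0.1), se = c(0.01, 0.011),
                    pos = c(1e6, 6e6))
  rec$pvalue <- c(1e-20, 1e-10)
  ld <- ld_lookup(data.frame(snp_a = "a", snp_b = "b", r2 = 0.5))
  expect_equal(ld_clump(rec, ld)$snp_id, "a")

  # window is scoped to the chromosome
  rec2 <- rec; rec2$chrom <- c("1", "2")
  ld2 <- ld_lookup(data.frame(snp_a = "a", snp_b = "b", r2 = 0.9))
  expect_equal(ld_clump(rec2, ld2)$snp_id, c("a", "b"))

  # 6-SNP block against an independent greedy reimplementation
  set.seed(42)
  ids <- letters[1:6]
  rec6 <- records_df(ids, beta = runif(6, 0.02, 0.1), se = rep(0.003, 6),
                     pos = seq(1e6, 2e6, length.out = 6))
  pairs <- t(combn(6, 2))
  r2v <- round(runif(nrow(pairs)), 2)
  ld_tab <- data.frame(snp_a = ids[pairs[, 1]], snp_b = ids[pairs[, 2]],
                       r2 = r2v)
  oracle_greedy <- function(rec, ld_tab, r2_max) {
    look <- function(x, y) {
      hit <- (ld_tab$snp_a == x & ld_tab$snp_b == y) |
             (ld_tab$snp_a == y & ld_tab$snp_b == x)
      if (any(hit)) ld_tab$r2[hit][1] else 0
    }
    remaining <- rec[order(rec$pvalue, rec$snp_id), ]
    kept <- character()
    while (nrow(remaining)) {
      top <- remaining$snp_id[1]
      kept <- c(kept, top)
      drop <- vapply(remaining$snp_id,
                     function(s) s == top || look(top, s) >= r2_max,
                     logical(1))
      remaining <- remaining[!drop, ]
    }
    kept
  }
  got <- ld_clump(rec6, ld_lookup(ld_tab), r2_max = 0.3)$snp_id
  want <- oracle_greedy(rec6, ld_tab, 0.3)
  expect_setequal(got, want)

  # independence lookup leaves independent SNPs untouched
  expect_equal(ld_clump(rec6, ld_independent())$snp_id, rec6$snp_id)
})

test_that("outcome-associated instruments are excluded at the 5e-5 threshold", {
  h <- hset_df(bx = rep(0.05, 20), sx = rep(0.003, 20),
               by = rep(0.01, 20), sy = rep(0.01, 20))
  h$p_out <- c(rep(1e-6, 2), 4.9e-5, rep(0.5, 17))
  h2 <- exclude_outcome_associated(h)
  expect_equal(sum(h2$excluded_reason %in% "outcome_associated"), 3)
  expect_equal(sum(is.na(h2$excluded_reason)), 17)
  h3 <- exclude_outcome_associated(hset_df(0.05, 0.003, 0.01, 0.01,
                                           p_out = 0.5))
  expect_true(is.na(h3$excluded_reason))
})

test_that("variance explained and F statistic match their closed forms", {
  expect_equal(variance_explained(0.5, 0.1), 0.005)
  expect_equal(variance_explained(0.5, 0), 0)
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(1, 0.3), 0)
  expect_equal(f_statistic(1001, 10, 0.1), 11)
  expect_equal(f_statistic(1001, 10, 0), 0)
  expect_error(f_statistic(1001, 10, 1), "r2")
})

test_that("per-SNP F screen excludes weak instruments at F < 10", {
  # choose beta so that F straddles 10 at n = 437354, eaf = 0.5
  f_of <- function(beta) f_statistic(437354, 1, variance_explained(0.5, beta))
  b_weak <- 0.006    # F just below 10
  b_strong <- 0.008  # F comfortably above 10
  expect_lt(f_of(b_weak), 10)
  expect_gt(f_of(b_strong), 10)
  h <- hset_df(bx = c(b_weak, b_strong, b_strong),
               sx = rep(0.002, 3), by = rep(0.01, 3), sy = rep(0.01, 3))
  h2 <- weak_instrument_filter(h)
  expect_equal(h2$excluded_reason, c("weak_instrument", NA, NA))
  expect_equal(h2$f_snp, f_of(c(b_weak, b_strong, b_strong)))
})

test_that("Steiger filter drops SNPs that explain more outcome variance", {
  em <- quant_meta(); om <- binary_meta()
  # strong exposure SNP, no outcome effect: retained
  good <- hset_df(bx = 0.05, sx = 0.003, by = 0.005, sy = 0.01)
  expect_true(is.na(steiger_filter(good, em, om)$excluded_reason))
  # outcome-primary SNP: large outcome z, negligible exposure effect
  bad <- hset_df(bx = 0.001, sx = 0.003, by = 0.08, sy = 0.01)
  expect_equal(steiger_filter(bad, em, om)$excluded_reason, "steiger_fail")
})

test_that("true reverse-effect SNPs are Steiger-excluded in nearly all draws", {
  em <- quant_meta(); om <- binary_meta()
  set.seed(99)
  n <- 500
  se_x <- 0.003; se_y <- 0.0095
  # SNPs affecting only the outcome (log-odds 0.05), pure noise on exposure
  h <- hset_df(bx = rnorm(n, 0, se_x), sx = rep(se_x, n),
               by = rnorm(n, 0.05, se_y), sy = rep(se_y, n))
  h2 <- steiger_filter(h, em, om)
  expect_gte(mean(h2$excluded_reason %in% "steiger_fail"), 0.95)
})

test_that("selection pipeline only removes rows, in a fixed logged order", {
  sim <- simulate_two_sample(sim_truth(beta_causal = 0.1, n_snp = 200,
                                       palindrome_fraction = 0.1, seed = 5))
  sel <- select_instruments(sim$exposure, sim$outcome, quant_meta(),
                            binary_meta())
  att <- attr(sel, "attrition")
  expect_named(att, c("input", "significant", "clumped", "harmonized",
                      "outcome_filtered", "steiger", "strong"))
  expect_true(all(diff(att) <= 0))
  d <- attr(sel, "diagnostics")
  expect_equal(d$k, sum(is.na(sel$excluded_reason)))
  expect_gte(d$r2_sum, 0)
  expect_gte(d$f_overall, 0)
})

test_that("summed variance explained is invariant to allele flips", {
  eaf <- c(0.2, 0.7, 0.4); beta <- c(0.05, -0.03, 0.08)
  expect_equal(sum(variance_explained(eaf, beta)),
               sum(variance_explained(1 - eaf, -beta)))
})
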