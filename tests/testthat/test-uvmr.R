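test_that("Wald ratio follows the first-order formula", {
  w <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(w$ratio, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.01)$ratio, 0)
  # joint sign flip leaves the ratio unchanged
  expect_equal(wald_ratio(-0.1, 0.01, -0.05, 0.01)$ratio, 0.5)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01), "zero exposure")
})

test_that("IVW-MRE matches hand-computed fixtures", {
  e <- ivw_mre(list(bx = c(0.1, 0.2), sx = c(0.01, 0.01),
                    by = c(0.05, 0.10), sy = c(0.01, 0.01)))
  expect_equal(e$beta, 0.5)
  expect_equal(e$q, 0, tolerance = 1e-20)
  expect_equal(e$se, sqrt(1 / 500))

  e2 <- ivw_mre(list(bx = c(1, 1), sx = c(0.1, 0.1),
                     by = c(0.4, 0.6), sy = c(0.1, 0.1)))
  expect_equal(e2$beta, 0.5)
  expect_equal(e2$q, 2)

  e0 <- ivw_mre(list(bx = c(0.1, 0.2), sx = c(0.01, 0.01),
                     by = c(0, 0), sy = c(0.01, 0.01)))
  expect_equal(e0$beta, 0)

  expect_error(ivw_mre(list(bx = 0.1, sx = 0.01, by = 0.1, sy = 0.01)),
               "at least 2")
})

test_that("IVW-MRE equals weighted least squares through the origin", {
  set.seed(11)
  J <- 40
  bx <- abs(rnorm(J, 0, 0.05)); sy <- runif(J, 0.005, 0.02)
  by <- 0.2 * bx + rnorm(J, 0, 2 * sy)  # over-dispersed so Q/(J-1) > 1
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  e <- ivw_mre(list(bx = bx, sx = rep(0.003, J), by = by, sy = sy))
  expect_equal(e$beta, unname(coef(fit)), tolerance = 1e-10)
  expect_gt(e$dispersion, 1)
  # with dispersion > 1 the MRE SE equals the weighted-lm SE exactly
  expect_equal(e$se, unname(sqrt(diag(vcov(fit)))), tolerance = 1e-10)
})

test_that("MRE dispersion floors at the fixed-effect SE and grows with Q", {
  homo <- ivw_mre(list(bx = c(0.1, 0.2, 0.3), sx = rep(0.01, 3),
                       by = c(0.05, 0.10, 0.15), sy = rep(0.01, 3)))
  w <- 1 / rep(0.01, 3)^2
  expect_equal(homo$se, sqrt(1 / sum(w * c(0.1, 0.2, 0.3)^2)))  # Q = 0 floor
  het <- ivw_mre(list(bx = c(0.1, 0.2, 0.3), sx = rep(0.01, 3),
                      by = c(0.02, 0.14, 0.12), sy = rep(0.01, 3)))
  expect_gt(het$q, homo$q)
  expect_gt(het$se, homo$se)
})

test_that("MR-Egger recovers an exact linear law and reports the intercept", {
  bx <- c(0.1, 0.2, 0.3)
  e <- egger(list(bx = bx, sx = rep(0.01, 3), by = 0.02 + 0.5 * bx,
                  sy = rep(0.01, 3)))
  expect_equal(e$beta, 0.5, tolerance = 1e-12)
  expect_equal(e$egger_intercept, 0.02, tolerance = 1e-12)
  expect_equal(e$q, 0, tolerance = 1e-18)
  expect_error(egger(list(bx = bx[1:2], sx = rep(0.01, 2), by = bx[1:2],
                          sy = rep(0.01, 2))), "at least 3")
})

test_that("Egger matches a weighted lm oracle on noisy data", {
  set.seed(21)
  J <- 50
  bx <- abs(rnorm(J, 0.05, 0.02)); sy <- runif(J, 0.005, 0.02)
  by <- 0.01 + 0.3 * bx + rnorm(J, 0, 2 * sy)
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  e <- egger(list(bx = bx, sx = rep(0.003, J), by = by, sy = sy))
  expect_equal(e$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(e$egger_intercept, unname(coef(fit)[1]), tolerance = 1e-10)
})

test_that("weighted median interpolates the ordered ratios at half weight", {
  # symmetric: plain median
  e <- weighted_median(list(bx = c(1, 1, 1), sx = rep(0.01, 3),
                            by = c(0.4, 0.5, 0.6), sy = rep(0.1, 3)),
                       n_boot = 10, seed = 1)
  expect_equal(e$beta, 0.5)
  # hand-interpolated fixture: ratios (0.1, 0.2, 0.3), weights (0.2, 0.3, 0.5)
  # cumulative midpoints (0.1, 0.35, 0.75) -> interpolate at 0.5 -> 0.2375
  sy <- c(1, 1, 1)
  bx <- sqrt(c(0.2, 0.3, 0.5))           # (bx/sy)^2 proportional to weights
  by <- bx * c(0.1, 0.2, 0.3)
  e2 <- weighted_median(list(bx = bx, sx = rep(0.001, 3), by = by, sy = sy),
                        n_boot = 10, seed = 1)
  expect_equal(e2$beta, 0.2375)
})

test_that("estimators are invariant to SNP order and joint sign flips", {
  set.seed(31)
  a <- simulate_arrays(sim_truth(beta_causal = 0.1, n_snp = 30, seed = 31))
  perm <- sample(30)
  ap <- lapply(a[c("bx", "sx", "by", "sy")], `[`, perm)
  af <- list(bx = -a$bx, sx = a$sx, by = -a$by, sy = a$sy)
  for (f in list(ivw_mre, egger)) {
    base <- f(a)
    expect_equal(f(ap)$beta, base$beta, tolerance = 1e-12)
    expect_equal(f(af)$beta, base$beta, tolerance = 1e-12)
    expect_equal(f(af)$se, base$se, tolerance = 1e-12)
  }
  expect_equal(weighted_median(ap, n_boot = 5, seed = 2)$beta,
               weighted_median(a, n_boot = 5, seed = 2)$beta,
               tolerance = 1e-12)
  expect_equal(weighted_median(af, n_boot = 5, seed = 2)$beta,
               weighted_median(a, n_boot = 5, seed = 2)$beta,
               tolerance = 1e-12)
})

test_that("MR-PRESSO global test is calm on homogeneous data", {
  bx <- seq(0.02, 0.1, length.out = 10)
  a <- list(bx = bx, sx = rep(0.001, 10), by = 0.5 * bx,
            sy = rep(0.01, 10))
  p <- presso(a, n_sim = 200, seed = 4)
  expect_gte(p$global_p, 0.95)  # identical ratios: RSS at its minimum
  expect_length(p$outliers, 0)
  expect_equal(p$corrected$beta, p$raw$beta)
  expect_true(is.na(p$distortion_p))
})

test_that("MR-PRESSO flags an injected outlier and corrects exactly", {
  a <- simulate_arrays(sim_truth(beta_causal = 0.1, n_snp = 20,
                                 gamma_sd = 0.1, seed = 5003))
  j <- which.min(abs(a$bx - median(a$bx)))
  a$by[j] <- a$by[j] + 9 * 0.1 * a$bx[j]   # Wald ratio ~10x the truth
  p <- presso(a, n_sim = 1000, seed = 17)
  expect_true(j %in% p$outliers)
  keep <- setdiff(seq_along(a$bx), p$outliers)
  manual <- ivw_mre(lapply(a[c("bx", "sx", "by", "sy")], `[`, keep))
  expect_identical(p$corrected$beta, manual$beta)
  expect_identical(p$corrected$se, manual$se)
  expect_false(is.na(p$distortion_p))
  expect_error(presso(lapply(a[c("bx", "sx", "by", "sy")], `[`, 1:3)),
               "at least 4")
})

test_that("Bonferroni threshold and significance labels follow alpha/n", {
  expect_equal(bonferroni_threshold(0.05, 9), 0.05 / 9)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(significance_label(0.01, n_outcomes = 9), "suggestive")
  expect_equal(significance_label(0.001, n_outcomes = 9), "significant")
  expect_equal(significance_label(0.2, n_outcomes = 9), "ns")
})

test_that("mr_fit bundles estimators with standard accessors", {
  a <- simulate_arrays(sim_truth(beta_causal = 0.1, n_snp = 50, seed = 77))
  h <- hset_df(a$bx, a$sx, a$by, a$sy)
  fit <- mr_fit(h, methods = c("ivw_mre", "egger", "weighted_median"),
                n_boot = 20, seed = 1)
  expect_s3_class(fit, "mr_fit")
  expect_named(coef(fit), c("ivw_mre", "egger", "weighted_median"))
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  s <- summary(fit)
  expect_true(all(c("method", "beta", "or", "q") %in% names(s)))
  expect_output(print(fit), "ivw_mre")
})
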