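test_that("Wald ratio: direct ratio, identity denominator, sign symmetry", {
  r <- wald_ratio(E = 0.1, E_se = 0.01, D = 0.05, D_se = 0.01)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)

  r <- wald_ratio(E = 1, E_se = 0.01, D = 0.37, D_se = 0.04)
  expect_equal(r$beta, 0.37)
  expect_equal(r$se, 0.04)

  for (seed in 1:5) {
    set.seed(seed)
    E <- rnorm(1, 0.1, 0.05); D <- rnorm(1); s <- runif(1, 0.01, 0.1)
    a <- wald_ratio(E, 0.01, D, s)
    b <- wald_ratio(-E, 0.01, -D, s)
    expect_equal(a$beta, b$beta)
    expect_equal(a$se, b$se)
  }
  expect_error(wald_ratio(0, 0.01, 0.1, 0.01), "null exposure")
})

test_that("IVW matches its closed form and collapses to Wald at k = 1", {
  h <- toy_harmonised(E = c(1, 1, 1), D = c(2, 2, 2), D_se = c(1, 1, 1))
  r <- mr_ivw(h)
  expect_equal(r$beta, 2)
  expect_equal(r$se, 1 / sqrt(3))
  expect_equal(r$ci_low, 2 - 1.96 / sqrt(3))

  h1 <- toy_harmonised(E = 0.08, D = 0.03, D_se = 0.012)
  expect_equal(mr_ivw(h1)$beta, wald_ratio(0.08, 0.01, 0.03, 0.012)$beta)
  expect_equal(mr_ivw(h1)$se, wald_ratio(0.08, 0.01, 0.03, 0.012)$se)
})

test_that("IVW and Egger agree with brute-force normal-equations oracles", {
  for (seed in 1:20) {
    h <- random_instance(10, seed)
    o <- oracle_ivw(h$E, h$D, h$D_se)
    r <- mr_ivw(h)
    expect_equal(r$beta, unname(o["beta"]), tolerance = 1e-12)
    expect_equal(r$se, unname(o["se"]), tolerance = 1e-12)

    oe <- oracle_egger(h$E, h$D, h$D_se)
    re <- mr_egger(h)
    expect_equal(re$beta, unname(oe["slope"]), tolerance = 1e-10)
    expect_equal(re$intercept, unname(oe["intercept"]), tolerance = 1e-10)
    expect_equal(re$se, unname(oe["slope_se"]), tolerance = 1e-10)
    expect_equal(re$intercept_se, unname(oe["intercept_se"]), tolerance = 1e-10)
  }
})

test_that("weighted median: unweighted cases and the percentile oracle", {
  # equal weights, odd count: plain middle ratio
  h <- toy_harmonised(E = c(1, 1, 1), D = c(1, 2, 9), D_se = c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 2)

  # dominant-weight instance, frozen from the exhaustive percentile oracle:
  # ratios (0, 0, 5), normalised weights (0.05, 0.05, 0.9) give percentiles
  # (2.5, 7.5, 55); interpolating to the 50th -> 4.473684...
  r <- c(5, 0, 0)
  w <- c(0.9, 0.05, 0.05)
  expect_equal(oracle_weighted_median(r, w), 4.473684210526316)
  h <- toy_harmonised(E = c(1, 1, 1), D = r, D_se = 1 / sqrt(w))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta,
               4.473684210526316)

  # random instances against the oracle
  for (seed in 21:35) {
    h <- random_instance(7 + seed %% 4, seed)
    est <- mr_weighted_median(h, n_boot = 10, seed = 1)$beta
    expect_equal(est, oracle_weighted_median(h$D / h$E, h$E^2 / h$D_se^2),
                 tolerance = 1e-12)
  }
})

test_that("weighted median with equal weights equals the simple median", {
  for (k in c(5, 6, 9, 10)) {
    set.seed(k)
    ratios <- rnorm(k)
    h <- toy_harmonised(E = rep(1, k), D = ratios, D_se = rep(1, k))
    expect_equal(mr_weighted_median(h, n_boot = 10, seed = 2)$beta,
                 median(ratios), label = paste("k =", k))
  }
})

test_that("weighted median requires a seed and >= 3 SNPs", {
  h <- toy_harmonised(E = c(1, 1, 1), D = c(1, 2, 3), D_se = c(1, 1, 1))
  expect_error(mr_weighted_median(h, n_boot = 10), "seed")
  expect_error(mr_weighted_median(h[1:2, ], n_boot = 10, seed = 1), "3 SNPs")
  # fixed seed reproduces the bootstrap SE exactly
  a <- mr_weighted_median(h, n_boot = 100, seed = 9)
  b <- mr_weighted_median(h, n_boot = 100, seed = 9)
  expect_identical(a$se, b$se)
})

test_that("Egger recovers an exact line and rejects degenerate designs", {
  delta <- c(0.1, 0.2, 0.4)
  h <- toy_harmonised(E = delta, D = 0.1 + 0.5 * delta, D_se = rep(1, 3))
  r <- mr_egger(h)
  expect_equal(r$intercept, 0.1, tolerance = 1e-12)
  expect_equal(r$beta, 0.5, tolerance = 1e-12)

  h_bad <- toy_harmonised(E = c(0.2, 0.2, 0.2), D = c(1, 2, 3),
                          D_se = rep(1, 3))
  expect_error(mr_egger(h_bad), "not identifiable")
  expect_error(mr_egger(h[1:2, ]), "3 SNPs")
})

test_that("estimators are invariant under per-SNP sign flips", {
  h <- random_instance(12, 99)
  flip <- c(2, 5, 7)
  h2 <- h
  h2$E[flip] <- -h2$E[flip]
  h2$D[flip] <- -h2$D[flip]
  expect_equal(mr_ivw(h)$beta, mr_ivw(h2)$beta)
  expect_equal(mr_ivw(h)$se, mr_ivw(h2)$se)
  expect_equal(mr_weighted_median(h, n_boot = 10, seed = 4)$beta,
               mr_weighted_median(h2, n_boot = 10, seed = 4)$beta)
  expect_equal(mr_egger(h)$beta, mr_egger(h2)$beta)
  expect_equal(mr_egger(h)$intercept, mr_egger(h2)$intercept)
})

test_that("instrument strength: closed forms and missing-eaf handling", {
  s <- toy_set(toy_records("rs1", "A", "G", beta = 0, eaf = 0.5))
  st <- instrument_strength(s, n_sample = 1000)
  expect_equal(st$r_squared, 0)
  expect_equal(st$f_statistic, 0)

  # k = 1, R2 = 0.5, n = 3 -> F = 1
  b <- sqrt(0.5 / (2 * 0.5 * 0.5))
  s <- toy_set(toy_records("rs1", "A", "G", beta = b, eaf = 0.5))
  st <- instrument_strength(s, n_sample = 3)
  expect_equal(st$r_squared, 0.5)
  expect_equal(st$f_statistic, 1)

  rec <- toy_records(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                     beta = c(0.1, 0.1), eaf = c(0.25, NA))
  expect_warning(st <- instrument_strength(toy_set(rec), 5000), "skipped")
  expect_equal(st$n_snps, 1)
  expect_equal(st$coverage, 0.5)
  expect_equal(st$r_squared, 2 * 0.25 * 0.75 * 0.01)
})

test_that("simulated instruments recover the target variance explained", {
  truth <- simulation_truth(n_snps = 77, r2_exposure = 0.024, seed = 13)
  sim <- simulate_summary_stats(truth)
  st <- instrument_strength(sim$traits$exposure$instruments,
                            n_sample = truth$n_exposure)
  # observed betas add noise around the exactly-calibrated true effects
  expect_equal(st$r_squared, 0.024, tolerance = 0.15)
  # F follows the closed form exactly; at R2 = 0.024, k = 77, n = 322,154
  # that is ~103 ("very large" in the weak-instrument sense of F >> 10)
  expect_equal(st$f_statistic,
               ((st$n_sample - st$n_snps - 1) / st$n_snps) *
                 st$r_squared / (1 - st$r_squared))
  expect_gt(st$f_statistic, 100)
  # and the true effects hit the target exactly
  eff <- sim$truth$snp_effects
  own <- eff$owner == "exposure"
  expect_equal(sum(2 * eff$maf[own] * (1 - eff$maf[own]) * eff$gamma[own]^2),
               0.024, tolerance = 1e-12)
})
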