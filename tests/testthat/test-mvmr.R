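toy_hset <- function(data, mediators = character(), outcome_type = "continuous") {
  structure(list(exposure_name = "X", outcome_name = "Y",
                 outcome_type = outcome_type, mediator_names = mediators,
                 palindrome_policy = "keep", eaf_window = c(0.42, 0.58),
                 data = data, exclusion_log = data.frame()),
            class = "harmonised_set")
}

test_that("MVMR with no or null mediators collapses to univariable IVW", {
  h <- toy_hset(random_instance(15, 1))
  mv <- mvmr_ivw(h)
  iv <- mr_ivw(h$data)
  expect_equal(mv$direct_beta, iv$beta, tolerance = 1e-14)
  expect_equal(mv$direct_se, iv$se, tolerance = 1e-14)

  d <- random_instance(15, 2)
  d$M_null <- 0
  d$M_null_se <- 0.01
  h <- toy_hset(d, mediators = "null")
  mv <- mvmr_ivw(h)
  # identically-zero mediator column: direct effect equals univariable IVW
  expect_equal(mv$direct_beta, mr_ivw(d)$beta, tolerance = 1e-12)
  expect_equal(nrow(mv$mediators), 1)
})

test_that("MVMR matches a weighted normal-equations oracle", {
  set.seed(42)
  k <- 25
  d <- toy_harmonised(E = rnorm(k, 0.1, 0.05), D = rnorm(k),
                      D_se = runif(k, 0.01, 0.05))
  d$M_med <- rnorm(k, 0.05, 0.03)
  d$M_med_se <- 0.01
  h <- toy_hset(d, mediators = "med")
  mv <- mvmr_ivw(h)
  # brute-force WLS through the origin on (E, M)
  w <- 1 / d$D_se^2
  X <- cbind(d$E, d$M_med)
  A <- matrix(0, 2, 2); b <- c(0, 0)
  for (i in seq_len(k)) {
    A <- A + w[i] * X[i, ] %o% X[i, ]
    b <- b + w[i] * X[i, ] * d$D[i]
  }
  coef <- solve(A, b)
  expect_equal(mv$direct_beta, coef[1], tolerance = 1e-10)
  expect_equal(mv$mediators$beta, coef[2], tolerance = 1e-10)
  expect_equal(mv$direct_se, sqrt(solve(A)[1, 1]), tolerance = 1e-10)
})

test_that("MVMR errors are informative", {
  d <- random_instance(10, 3)
  d$M_dup <- 2 * d$E  # exactly collinear with the exposure column
  d$M_dup_se <- 0.01
  h <- toy_hset(d, mediators = "dup")
  expect_error(mvmr_ivw(h), "collinear")

  h2 <- toy_hset(random_instance(1, 4))
  expect_error(mvmr_ivw(h2), "more SNPs")
  expect_error(mvmr_ivw(toy_hset(random_instance(10, 5)), mediators = "ghost"),
               "no mediator column")
})

test_that("MVMR recovers a simulated mediation chain over replicates", {
  direct <- numeric(30)
  medcoef <- numeric(30)
  for (r in seq_len(30)) {
    truth <- simulation_truth(
      n_snps = 40, beta_direct = 0.1,
      mediators = list(M = list(theta_xm = 0.2, beta_my = 1.0, n_snps = 40)),
      seed = 1000 + r)
    sim <- simulate_summary_stats(truth)
    ids <- union(sim$traits$exposure$instruments$records$variant_id,
                 sim$traits$M$instruments$records$variant_id)
    exp_assoc <- sim$traits$exposure$associations
    combined <- instrument_set(
      "exposure", "continuous", "SD",
      exp_assoc$records[exp_assoc$records$variant_id %in% ids, ])
    h <- harmonise(combined, sim$traits$outcome$associations,
                   mediators = list(M = sim$traits$M$associations),
                   palindrome_policy = "keep")
    mv <- mvmr_ivw(h)
    direct[r] <- mv$direct_beta
    medcoef[r] <- mv$mediators$beta
  }
  expect_lt(abs(mean(direct) - 0.1), 0.02)
  expect_lt(abs(mean(medcoef) - 1.0), 0.05)
})

test_that("a mediator with no SNP association leaves the direct effect alone", {
  set.seed(7)
  k <- 40
  E <- runif(k, 0.05, 0.2)
  d <- toy_harmonised(E = E, D = 0.5 * E + rnorm(k, 0, 0.01),
                      D_se = rep(0.01, k))
  d$M_inert <- rnorm(k, 0, 1e-3)  # no association with anything
  d$M_inert_se <- 0.01
  h0 <- toy_hset(d)
  h1 <- toy_hset(d, mediators = "inert")
  expect_lt(abs(mvmr_ivw(h1)$direct_beta - mvmr_ivw(h0)$direct_beta), 0.02)
})

test_that("proportion mediated arithmetic and guards", {
  total <- mrmediate:::mr_result("ivw", beta = 0.3716, se = 0.05, n_snps = 50,
                                 exposure = "X", outcome = "Y")
  direct <- list(exposure_name = "X", outcome_name = "Y",
                 mediator_names = "M", direct_beta = 0.1484,
                 direct_se = 0.05)
  class(direct) <- "mvmr_result"
  pm <- proportion_mediated(total, direct)
  expect_equal(pm$proportion_mediated, 100 * (1 - 0.1484 / 0.3716))
  expect_equal(round(pm$proportion_mediated, 1), 60.1)
  expect_identical(pm$formula_tag, "one_minus_direct_over_total_pct")

  direct$direct_beta <- total$beta
  expect_equal(proportion_mediated(total, direct)$proportion_mediated, 0)
  direct$direct_beta <- 0
  expect_equal(proportion_mediated(total, direct)$proportion_mediated, 100)

  expect_error(proportion_mediated(total, direct, mediator_binary = TRUE),
               "binary")
  total0 <- mrmediate:::mr_result("ivw", beta = 0, se = 0.05, n_snps = 50,
                                  exposure = "X", outcome = "Y")
  expect_error(proportion_mediated(total0, direct), "undefined")
  direct$outcome_name <- "Z"
  expect_error(proportion_mediated(total, direct), "same exposure/outcome")
})

fake_res <- function(beta, se) {
  mrmediate:::mr_result("ivw", beta = beta, se = se, n_snps = 20)
}

triple <- function(b_ivw, s_ivw, b_med, s_med, b_egg, s_egg) {
  list(ivw = fake_res(b_ivw, s_ivw), weighted_median = fake_res(b_med, s_med),
       egger = fake_res(b_egg, s_egg))
}

test_that("mediator triage applies the two-step concordance rule", {
  strong <- triple(0.5, 0.1, 0.45, 0.1, 0.55, 0.1)      # all CIs exclude 0
  egger_weak <- triple(0.5, 0.1, 0.45, 0.1, 0.3, 0.2)   # Egger CI spans 0
  ivw_null <- triple(-0.05, 0.07, -0.01, 0.03, -0.10, 0.04)  # IVW CI spans 0
  discordant <- triple(0.5, 0.1, 0.45, 0.1, -0.5, 0.1)

  tr <- mediator_triage(
    step1 = list(A = strong, B = ivw_null, C = strong, D = discordant,
                 E = strong),
    step2 = list(A = strong, B = strong, C = egger_weak, D = strong,
                 E = list(ivw = fake_res(0.5, 0.1))))
  expect_equal(tr$status[tr$mediator == "A"], "pass")
  expect_equal(tr$status[tr$mediator == "B"], "fail")      # step-one IVW null
  expect_equal(tr$status[tr$mediator == "C"], "pass")      # Egger CI may span 0
  expect_equal(tr$status[tr$mediator == "D"], "fail")      # sign discordance
  expect_equal(tr$status[tr$mediator == "E"], "not_evaluable")
  expect_error(mediator_triage(list(), list()), "no candidate")
})
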