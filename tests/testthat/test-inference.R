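test_that("ncc_combine applies the correction on both scales", {
  expect_equal(ncc_combine(7.27, 0.77, "difference"), 6.50)
  expect_equal(ncc_combine(6.22, -0.37, "difference"), 6.59)
  expect_equal(ncc_combine(3, 0, "difference"), 3)
  expect_equal(ncc_combine(0.42, 0.77, "rate_ratio"), 0.42 / 0.77,
               tolerance = 1e-12)
  expect_equal(ncc_combine(c(1, 2), c(1, 4), "difference"), c(0, -2))
  expect_error(ncc_combine(0.5, -0.2, "rate_ratio"), "positive")
  expect_error(ncc_combine(0, 0.5, "rate_ratio"), "positive")
})

test_that("corrected effects obey the exact combination identity", {
  coh <- simulate_cohort(scenario_config("scenario3", n_g1 = 120,
                                         n_g0 = 120, seed = 6))
  for (cmp in c("time_period", "genotype")) {
    et <- suppressWarnings(estimate_ncc(coh, cmp, B = 30, seed = 2))
    expect_identical(et$nccte$point, et$nte$point - et$nce$point)
  }
  ccoh <- simulate_count_cohort(
    scenario_config("scenario3", n_g1 = 200, n_g0 = 200, seed = 6))
  etc <- suppressWarnings(estimate_ncc(ccoh, "time_period", B = 30,
                                       seed = 2))
  expect_identical(etc$nccte$log_point,
                   etc$nte$log_point - etc$nce$log_point)
  expect_equal(etc$nccte$point, exp(etc$nte$log_point - etc$nce$log_point),
               tolerance = 0)
})

test_that("label-switched NCE equals the direct fit on the subcohort", {
  coh <- simulate_cohort(scenario_config("scenario3", n_g1 = 80,
                                         n_g0 = 80, seed = 14))
  nce <- fit_step_slope(build_contrast(coh, "NCE_P"))
  # direct fit: the G = 0 subcohort with the period as treatment label
  df <- as.data.frame(coh)[coh$genotype == 0L, ]
  rownames(df) <- NULL
  df$X <- df$period
  direct <- structure(df, contrast = "NCE_P", covariate_spec = NULL,
                      outcome_kind = "continuous",
                      max_visits = max_visits(coh),
                      class = c("ncc_analysis_set", "data.frame"))
  expect_identical(fit_step_slope(direct)$coefficients, nce$coefficients)
})

test_that("scenario 1: negative control effects are null, corrected
           equals naive", {
  cfg <- scenario_config("scenario1", n_g1 = 1500, n_g0 = 1500,
                         seed = 19)
  coh <- simulate_cohort(cfg)
  et <- estimate_ncc(coh, "genotype", B = 150, seed = 19)
  se <- (et$nce$ci_high - et$nce$ci_low) / (2 * 1.96)
  expect_lt(abs(et$nce$point["step"]), 3 * se["step"])
  expect_lt(abs(et$nce$point["slope"]), 3 * se["slope"])
  se_ncc <- (et$nccte$ci_high - et$nccte$ci_low) / (2 * 1.96)
  expect_lt(abs(et$nccte$point["step"] - 5), 3 * se_ncc["step"])
})

test_that("scenario 3: the naive/negative-control/corrected decomposition
           recovers beta_G, delta_St", {
  cfg <- scenario_config("scenario3", n_g1 = 1200, n_g0 = 1200, seed = 23)
  coh <- simulate_cohort(cfg)
  et <- estimate_ncc(coh, "genotype", B = 150, seed = 23)
  se <- function(e, comp) (e$ci_high[comp] - e$ci_low[comp]) / (2 * 1.96)
  expect_lt(abs(et$nte$point["step"] - 7), 3 * se(et$nte, "step"))
  expect_lt(abs(et$nce$point["step"] - 2), 3 * se(et$nce, "step"))
  expect_lt(abs(et$nccte$point["step"] - 5), 3 * se(et$nccte, "step"))
})

test_that("scenario 2: conditional adjustment removes covariate-channel
           bias that the unadjusted naive effect keeps", {
  cfg <- scenario_config("scenario2", n_g1 = 2000, n_g0 = 2000,
                         seed = 37)
  coh <- simulate_cohort(cfg)
  unadj <- suppressWarnings(estimate_ncc(coh, "genotype", B = 50,
                                         seed = 37))
  adj <- suppressWarnings(estimate_ncc(coh, "genotype", "conditional",
                                       covariate_spec = "h_baseline",
                                       B = 50, seed = 37))
  gt <- ground_truth(cfg)
  se <- function(e, comp) (e$ci_high[comp] - e$ci_low[comp]) / (2 * 1.96)
  # unadjusted NTE is biased by effect * dG = -1; conditional is not
  expect_lt(abs(unadj$nte$point["step"] - gt$genotype$nte_step),
            3 * se(unadj$nte, "step"))
  expect_false(abs(unadj$nte$point["step"] - 5) <
                 3 * se(unadj$nte, "step"))
  expect_lt(abs(adj$nte$point["step"] - 5), 3 * se(adj$nte, "step"))
})

test_that("a missing group fails with the group named", {
  df <- data.frame(person_id = c("a", "b", "d"),
                   genotype = c(1L, 1L, 0L), period = c(0L, 1L, 1L),
                   visit = 0L, outcome = c(70, 78, 72))
  coh <- ncc_cohort(df) # no group C
  expect_error(suppressWarnings(estimate_ncc(coh, "genotype", B = 10)),
               "group C")
})

test_that("bootstrap is reproducible and degenerate data collapse its
           interval", {
  coh <- simulate_cohort(scenario_config("scenario3", n_g1 = 60,
                                         n_g0 = 60, seed = 41))
  est_step <- function(c_) {
    fit_step_slope(build_contrast(c_, "NTE_G"))$coefficients["beta_St"]
  }
  b1 <- bootstrap_effect(coh, est_step, B = 200, seed = 7)
  b2 <- bootstrap_effect(coh, est_step, B = 200, seed = 7)
  expect_identical(b1, b2)
  b3 <- bootstrap_effect(coh, est_step, B = 200, seed = 8)
  expect_false(identical(b1$ci_low, b3$ci_low))

  # constant outcomes: every resample returns the same point
  const <- panel_cohort(function(g, p, j) rep(70, length(j)), n = 20)
  bc <- bootstrap_effect(const, est_step, B = 150, seed = 1)
  expect_equal(unname(bc$ci_low), unname(bc$point))
  expect_equal(unname(bc$ci_high), unname(bc$point))

  expect_warning(bootstrap_effect(coh, est_step, B = 50, seed = 1),
                 "unstable")
  # two estimate_ncc runs with one seed are bit-identical
  e1 <- estimate_ncc(coh, "genotype", B = 200, seed = 3)
  e2 <- estimate_ncc(coh, "genotype", B = 200, seed = 3)
  expect_identical(e1, e2)
})

test_that("count-outcome triples report per-year rate ratios near truth", {
  cfg <- scenario_config("scenario3", n_g1 = 800, n_g0 = 800, seed = 51,
                         count_params = list(
                           log_rate = log(15),
                           log_rr_years = log(c(0.5, 0.4, 0.4, 0.4)),
                           dispersion = 0.4,
                           beta_P = -0.25, beta_G = -0.05))
  coh <- simulate_count_cohort(cfg)
  et <- estimate_ncc(coh, "time_period", B = 100, seed = 51)
  gt <- ground_truth(cfg)
  expect_equal(unname(et$nccte$point),
               unname(gt$count$time_period$nccte_rr),
               tolerance = 0.12)
  expect_equal(et$scale, "rate_ratio")
  expect_true(all(et$nccte$ci_low <= et$nccte$ci_high))
})
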