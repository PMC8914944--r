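test_that("noise-free step/slope data are interpolated exactly", {
  # X=0 outcomes 50 + j, X=1 outcomes 55 + 2j, under the NTE_G pairing
  coh <- panel_cohort(function(g, p, j) {
    x <- as.integer(g == 1 & p == 1)
    50 + j + x * (5 + j)
  })
  fit <- fit_step_slope(build_contrast(coh, "NTE_G"))
  expect_equal(fit$coefficients,
               c(beta_0 = 50, beta_St = 5, beta_Sl = 1, beta_J = 1),
               tolerance = 1e-12)
  # unbalanced panel shapes do not change the exact interpolation
  sub <- as.data.frame(coh)
  sub <- sub[-(seq(2, nrow(sub), by = 5)), ]
  fit2 <- fit_step_slope(build_contrast(ncc_cohort(sub), "NTE_G"))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-12)
})

test_that("step/slope estimates equal the normal-equations oracle", {
  for (seed in 1:10) {
    aset <- random_aset(seed)
    fit <- fit_step_slope(aset)
    D <- cbind(1, aset$X, aset$X * aset$visit, aset$visit)
    beta <- ols_oracle(D, aset$outcome)
    expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8,
                 label = paste("seed", seed))
  }
  # adjusted fit against the oracle on the extended design
  aset <- random_aset(99, with_covariate = TRUE)
  fit <- fit_step_slope(aset)
  D <- cbind(1, aset$X, aset$X * aset$visit, aset$visit, aset$h)
  beta <- ols_oracle(D, aset$outcome)
  expect_equal(unname(c(fit$coefficients, fit$covariate_coefficients)),
               beta, tolerance = 1e-8)
})

test_that("record order never changes the estimates", {
  aset <- random_aset(4)
  fit <- fit_step_slope(aset)
  perm <- sample(nrow(aset))
  aset2 <- aset[perm, ]
  attributes(aset2)[c("contrast", "covariate_spec", "outcome_kind",
                      "max_visits")] <-
    attributes(aset)[c("contrast", "covariate_spec", "outcome_kind",
                       "max_visits")]
  class(aset2) <- class(aset)
  fit2 <- fit_step_slope(aset2)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-10)
})

test_that("degenerate designs raise informative errors", {
  coh <- panel_cohort(function(g, p, j) 50 + j)
  aset <- build_contrast(coh, "NTE_G")
  one_level <- aset[aset$X == 1L, ]
  attributes(one_level)[c("contrast", "covariate_spec", "outcome_kind",
                          "max_visits")] <-
    attributes(aset)[c("contrast", "covariate_spec", "outcome_kind",
                       "max_visits")]
  class(one_level) <- class(aset)
  expect_error(fit_step_slope(one_level), "X levels")
  # collinear covariate: a copy of the genotype indicator duplicates X
  # in the genotype contrast
  df <- as.data.frame(coh)
  df$gdup <- as.numeric(df$genotype)
  coh2 <- ncc_cohort(df, covariates = "gdup")
  expect_error(fit_step_slope(build_contrast(coh2, "NTE_G", "gdup")),
               "rank deficient")
  expect_error(fit_count_effects(aset), "count outcome")
})

test_that("noise-free multiplicative counts give exact rate ratios", {
  # X=0 rate 10 at every visit; X=1 rates (5, 4, 3) at j = 0, 1, 2
  coh <- panel_cohort(function(g, p, j) {
    if (g == 1 && p == 1) c(5, 4, 3)[j + 1] else rep(10, length(j))
  }, n = 4, J = 3, outcome_kind = "count")
  fit <- fit_count_effects(build_contrast(coh, "NTE_G"))
  expect_equal(unname(fit$rate_ratios), c(0.5, 0.4, 0.3),
               tolerance = 1e-8)
})

test_that("count estimates equal the hand-rolled IRLS oracle", {
  for (seed in 1:10) {
    aset <- random_aset(seed, count = TRUE)
    fit <- fit_count_effects(aset)
    K <- length(unique(aset$visit))
    D <- nccdid:::.count_design(aset$X, aset$visit, K, "saturated")
    beta <- irls_oracle(D, aset$outcome)
    got <- c(fit$gamma_0, fit$gamma_J, fit$gamma_X)
    expect_equal(unname(got), unname(beta), tolerance = 1e-6,
                 label = paste("seed", seed))
  }
})

test_that("overdispersion does not bias count point estimates", {
  cfg <- synthetic_config(
    n_g1 = 1000, n_g0 = 1000, p_both_periods = 1, seed = 77,
    p_missing_visit = 0, J = 3,
    count_params = list(log_rate = log(10),
                        log_rr_years = log(c(0.5, 0.4, 0.4)),
                        dispersion = 0.6))
  coh <- simulate_count_cohort(cfg)
  fit <- fit_count_effects(build_contrast(coh, "NTE_P"))
  expect_gt(fit$dispersion, 2) # overdispersion really present
  expect_equal(unname(fit$rate_ratios), c(0.5, 0.4, 0.4),
               tolerance = 0.05)
})

test_that("an all-zero treatment-year cell is a divergence error", {
  df <- expand.grid(person_id = sprintf("p%02d", 1:8), visit = 0:1)
  df$genotype <- as.integer(as.integer(sub("p", "", df$person_id)) > 4)
  df$period <- 1L
  df$outcome <- ifelse(df$genotype == 1 & df$visit == 0, 0L, 3L)
  df <- rbind(df, data.frame(person_id = "c1", visit = 0L, genotype = 0L,
                             period = 0L, outcome = 2L))
  coh <- ncc_cohort(df, outcome_kind = "count", max_visits = 2L)
  expect_error(fit_count_effects(build_contrast(coh, "NTE_G")),
               "all outcomes are zero")
})

test_that("count-baseline encoding expands to indicator plus linear part", {
  spec <- covariate_spec("ivdays", "count_baseline")
  v <- c(0, 0, 3, 12, 1)
  M <- encode_covariates(spec, data.frame(ivdays = v))
  expect_identical(colnames(M), c("ivdays_pos", "ivdays_posval"))
  expect_equal(M[, "ivdays_pos"], as.numeric(v > 0))
  # multiplying back reproduces the raw covariate on the nonzero entries
  expect_equal((M[, "ivdays_pos"] * M[, "ivdays_posval"])[v > 0],
               v[v > 0])
  expect_error(encode_covariates(covariate_spec("b", "binary"),
                                 data.frame(b = c(0, 2))),
               "outside")
  expect_error(covariate_spec("x", "spline"), "unknown encoding")
})

test_that("standardization collapses, enumerates strata, and matches the
           conditional fit when H is balanced", {
  # two-stratum hand enumeration
  df <- data.frame(
    person_id = sprintf("p%02d", 1:12),
    genotype = rep(c(0L, 1L), each = 6), period = 1L, visit = 0L,
    h = rep(c(0, 0, 0, 1, 1, 1), 2),
    outcome = c(10, 12, 14, 20, 22, 24,   # X=0: mean 12 (h=0), 22 (h=1)
                15, 17, 19, 30, 32, 34))  # X=1: mean 17 (h=0), 32 (h=1)
  coh <- ncc_cohort(df, covariates = "h", max_visits = 1L)
  aset <- build_contrast(coh, "NTE_G", covariate_spec("h", "binary"))
  # E(Y | X=1) = 24.5; standardized X=0 mean over the X=1 h-distribution
  # (half and half) = 0.5*12 + 0.5*22 = 17; hand value 7.5
  expect_equal(standardize_effect(aset, at_visit = 0), 24.5 - 17)

  # with H balanced and a linear no-interaction outcome model the
  # standardized and conditional estimates agree
  set.seed(5)
  n <- 400
  df2 <- data.frame(
    person_id = sprintf("q%04d", 1:(2 * n)),
    genotype = rep(c(0L, 1L), each = n), period = 1L, visit = 0L,
    h = rep(rnorm(n), 2))
  df2$outcome <- 50 + 4 * df2$genotype + 2 * df2$h + rnorm(2 * n, 0, 1)
  coh2 <- ncc_cohort(df2, covariates = "h", max_visits = 1L)
  aset2 <- build_contrast(coh2, "NTE_G", "h")
  std <- standardize_effect(aset2, 0)
  D <- cbind(1, aset2$X, aset2$h)
  cond <- ols_oracle(D, aset2$outcome)[2]
  expect_equal(std, cond, tolerance = 1e-6)

  # overlap violation for a discrete stratum
  df3 <- df
  df3$h[df3$genotype == 0L] <- 0
  coh3 <- ncc_cohort(df3, covariates = "h", max_visits = 1L)
  aset3 <- build_contrast(coh3, "NTE_G", covariate_spec("h", "binary"))
  expect_error(standardize_effect(aset3, 0), "overlap")
})
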