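# Run code with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so simulation/bootstrap calls do not perturb it.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for the synthetic registry generator
#'
#' Bundles and validates the generative parameters of the synthetic
#' two-genotype, two-period registry. The untreated-world mean follows
#' \deqn{E(Y^{X=0} | P, G) = \alpha + \beta_P P + \beta_G G +
#'   \gamma_{PG} P G,}
#' with a common visit trend `beta_J * j`; treated records
#' (G = 1, P = 1) additionally receive the step and slope treatment
#' effects `delta_St + delta_Sl * j`. Within-person correlation comes
#' from a Gaussian random intercept shared across a person's two periods
#' (continuous outcome) or a gamma frailty (count outcome).
#'
#' @param n_g1,n_g0 persons per genotype group.
#' @param p_both_periods probability a person contributes to both
#'   periods (otherwise one period at random).
#' @param J annual visits per period.
#' @param alpha untreated baseline mean (outcome units).
#' @param beta_P,beta_G,gamma_PG period, genotype and period-by-genotype
#'   effects on the untreated outcome.
#' @param beta_J common visit slope (outcome units per visit).
#' @param delta_St,delta_Sl true treatment step and slope effects,
#'   applied only to (G = 1, P = 1) records.
#' @param sd_person within-person random-intercept SD.
#' @param sd_noise residual SD.
#' @param covariate_specs list of per-covariate generative rules, each a
#'   list with fields `name`, `type` (`"normal"` or `"binary"`), `base`
#'   (mean or prevalence), `sd` (normal only), `dG`, `dP` (additive shift
#'   of the mean/prevalence per unit of G and P) and `effect`
#'   (coefficient on the continuous outcome).
#' @param count_params list for the count generator: `log_rate` (baseline
#'   log rate, must be finite, i.e. positive baseline rate),
#'   `log_rr_years` (vector of per-treatment-year log rate ratios),
#'   `dispersion` (gamma-frailty variance; 0 = Poisson), and optional
#'   log-scale `beta_P`, `beta_G`, `gamma_PG`, `beta_J` (default 0).
#' @param p_missing_visit probability each visit record is missing
#'   (completely at random).
#' @param seed integer seed.
#' @return validated list of class `ncc_synth_config`.
#' @seealso [scenario_config()] for the named scenario presets.
#' @export
synthetic_config <- function(n_g1 = 500L, n_g0 = 2000L,
                             p_both_periods = 0.7, J = 4L,
                             alpha = 70, beta_P = 0, beta_G = 0,
                             gamma_PG = 0, beta_J = -1,
                             delta_St = 5, delta_Sl = 0.5,
                             sd_person = 8, sd_noise = 4,
                             covariate_specs = list(),
                             count_params = list(
                               log_rate = log(18),
                               log_rr_years = log(c(0.5, 0.4, 0.4, 0.4)),
                               dispersion = 0.5),
                             p_missing_visit = 0.1, seed = 1L) {
  cp_defaults <- list(beta_P = 0, beta_G = 0, gamma_PG = 0, beta_J = 0)
  for (nm in names(cp_defaults)) {
    if (is.null(count_params[[nm]])) count_params[[nm]] <- cp_defaults[[nm]]
  }
  cfg <- list(n_g1 = as.integer(n_g1), n_g0 = as.integer(n_g0),
              p_both_periods = p_both_periods, J = as.integer(J),
              alpha = alpha, beta_P = beta_P, beta_G = beta_G,
              gamma_PG = gamma_PG, beta_J = beta_J,
              delta_St = delta_St, delta_Sl = delta_Sl,
              sd_person = sd_person, sd_noise = sd_noise,
              covariate_specs = covariate_specs,
              count_params = count_params,
              p_missing_visit = p_missing_visit, seed = as.integer(seed))
  if (cfg$n_g1 < 1L || cfg$n_g0 < 1L) {
    stop("sample sizes must be >= 1", call. = FALSE)
  }
  if (cfg$J < 1L) stop("J must be >= 1", call. = FALSE)
  if (cfg$sd_person < 0 || cfg$sd_noise < 0) {
    stop("SDs must be >= 0", call. = FALSE)
  }
  if (cfg$p_both_periods < 0 || cfg$p_both_periods > 1 ||
      cfg$p_missing_visit < 0 || cfg$p_missing_visit > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(cfg$count_params$log_rate)) {
    stop("count baseline rate must be positive (finite log_rate)",
         call. = FALSE)
  }
  if (cfg$count_params$dispersion < 0) {
    stop("dispersion must be >= 0", call. = FALSE)
  }
  for (cv in cfg$covariate_specs) {
    need <- c("name", "type", "base", "dG", "dP", "effect")
    if (!all(need %in% names(cv))) {
      stop("covariate spec must have fields ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (!(cv$type %in% c("normal", "binary"))) {
      stop("covariate type must be 'normal' or 'binary'", call. = FALSE)
    }
    if (cv$type == "binary") {
      for (g in 0:1) for (p in 0:1) {
        pr <- cv$base + cv$dG * g + cv$dP * p
        if (pr < 0 || pr > 1) {
          stop("binary covariate '", cv$name, "' has prevalence ", pr,
               " outside [0, 1] in cell (G=", g, ", P=", p, ")",
               call. = FALSE)
        }
      }
    }
  }
  structure(cfg, class = "ncc_synth_config")
}

#' Named scenario presets for the generator
#'
#' Three canonical data-generating scenarios:
#'
#' * `scenario1` — genotype and period do not affect the untreated
#'   outcome at all (`beta_P = beta_G = gamma_PG = 0`, no covariates):
#'   naive effects are unbiased and negative control effects are null.
#' * `scenario2` — genotype and period affect the untreated outcome only
#'   through a measured baseline-health covariate `h_baseline`:
#'   unadjusted naive effects are biased, covariate-adjusted ones are
#'   not.
#' * `scenario3` — genotype and period affect the untreated outcome
#'   directly (`beta_P = 0.8`, `beta_G = 2`): naive effects are biased
#'   even after adjustment, and only the negative-control-corrected
#'   effects recover the treatment effect (when `gamma_PG = 0`).
#'
#' All presets share `delta_St = 5`, `delta_Sl = 0.5`,
#' `alpha = 70`, `beta_J = -1` (an annual lung-function decline on the
#' ppFEV1 scale), `sd_person = 8`, `sd_noise = 4`.
#'
#' @param scenario `"scenario1"`, `"scenario2"` or `"scenario3"`.
#' @param ... overrides passed on to [synthetic_config()] (e.g. sample
#'   sizes, `delta_St = 0` for a null scenario, `seed`).
#' @return an `ncc_synth_config`.
#' @export
scenario_config <- function(scenario = c("scenario1", "scenario2",
                                         "scenario3"), ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    scenario1 = list(beta_P = 0, beta_G = 0, gamma_PG = 0),
    scenario2 = list(beta_P = 0, beta_G = 0, gamma_PG = 0,
                     covariate_specs = list(list(
                       name = "h_baseline", type = "normal", base = 0,
                       sd = 5, dG = -2, dP = 1, effect = 0.5))),
    scenario3 = list(beta_P = 0.8, beta_G = 2, gamma_PG = 0))
  over <- list(...)
  base[names(over)] <- over
  do.call(synthetic_config, base)
}

# Draw the panel skeleton: persons, periods, visits, covariates, random
# intercepts.  Shared between the continuous and count generators.
.simulate_panel <- function(cfg) {
  n <- cfg$n_g1 + cfg$n_g0
  person_id <- sprintf("p%06d", seq_len(n))
  genotype <- c(rep(1L, cfg$n_g1), rep(0L, cfg$n_g0))
  both <- stats::runif(n) < cfg$p_both_periods
  only_period <- ifelse(stats::runif(n) < 0.5, 1L, 0L)
  # auxiliary genotype labels: ineligible persons carry a mutation-pair
  # label used by the sensitivity-restriction filter
  label <- ifelse(genotype == 1L, "gating",
                  sample(c("F508del/F508del", "F508del/other",
                           "other/other"),
                         n, replace = TRUE, prob = c(0.54, 0.36, 0.10)))
  rows <- list()
  k <- 0L
  for (p in 0:1) {
    in_period <- both | (only_period == p)
    idx <- which(in_period)
    if (length(idx) == 0L) next
    k <- k + 1L
    per <- data.frame(person_id = person_id[idx],
                      genotype = genotype[idx],
                      period = p, stringsAsFactors = FALSE)
    per$genotype_label <- label[idx]
    # baseline covariates measured anew in each period
    for (cv in cfg$covariate_specs) {
      loc <- cv$base + cv$dG * per$genotype + cv$dP * p
      per[[cv$name]] <- if (cv$type == "normal") {
        stats::rnorm(nrow(per), mean = loc, sd = cv$sd)
      } else {
        as.numeric(stats::runif(nrow(per)) < loc)
      }
    }
    rows[[k]] <- per[rep(seq_len(nrow(per)), each = cfg$J), , drop = FALSE]
    rows[[k]]$visit <- rep(0:(cfg$J - 1L), times = nrow(per))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  b <- stats::setNames(stats::rnorm(n, 0, cfg$sd_person), person_id)
  list(df = df, intercepts = b)
}

# Apply completely-at-random visit missingness, then drop persons left
# with no records at all.
.apply_missingness <- function(df, p_miss) {
  if (p_miss > 0) {
    keep <- stats::runif(nrow(df)) >= p_miss
    df <- df[keep, , drop = FALSE]
  }
  df
}

#' Simulate a continuous-outcome registry cohort
#'
#' Draws a cohort from the generative model described in
#' [synthetic_config()]: per-person genotype by design counts, period
#' membership, per-period baseline covariates, a shared Gaussian random
#' intercept, the untreated mean structure plus step/slope treatment
#' effects in the treated cell, Gaussian residual noise, and
#' completely-at-random visit missingness. Fully reproducible from
#' `config$seed`.
#'
#' @param config an [synthetic_config()] / [scenario_config()].
#' @return an [ncc_cohort()] with a continuous outcome and the
#'   config's covariates attached.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ncc_synth_config"))
  .with_seed(config$seed, {
    panel <- .simulate_panel(config)
    df <- panel$df
    mu <- config$alpha +
      config$beta_P * df$period +
      config$beta_G * df$genotype +
      config$gamma_PG * df$period * df$genotype +
      config$beta_J * df$visit
    for (cv in config$covariate_specs) {
      mu <- mu + cv$effect * df[[cv$name]]
    }
    treated <- df$genotype == 1L & df$period == 1L
    mu <- mu + treated * (config$delta_St + config$delta_Sl * df$visit)
    df$outcome <- mu + panel$intercepts[df$person_id] +
      stats::rnorm(nrow(df), 0, config$sd_noise)
    df <- .apply_missingness(df, config$p_missing_visit)
    ncc_cohort(df, outcome_kind = "continuous", max_visits = config$J,
               covariates = vapply(config$covariate_specs, `[[`, "", "name"))
  })
}

#' Simulate a count-outcome registry cohort
#'
#' Draws annual count outcomes (e.g. IV-antibiotic days) with log mean
#' `log_rate + beta_P P + beta_G G + gamma_PG P G + beta_J j` (log-scale
#' coefficients from `count_params`) plus the treatment-year-specific log
#' rate ratios `log_rr_years[j + 1]` in the treated cell. Overdispersion
#' and within-person correlation come from a person-level gamma frailty
#' with mean 1 and variance `dispersion` (Poisson when 0). Visit
#' missingness as in [simulate_cohort()].
#'
#' @inheritParams simulate_cohort
#' @return an [ncc_cohort()] with a count outcome.
#' @export
simulate_count_cohort <- function(config) {
  stopifnot(inherits(config, "ncc_synth_config"))
  cp <- config$count_params
  .with_seed(config$seed + 1L, {
    panel <- .simulate_panel(config)
    df <- panel$df
    log_mu <- cp$log_rate +
      cp$beta_P * df$period +
      cp$beta_G * df$genotype +
      cp$gamma_PG * df$period * df$genotype +
      cp$beta_J * df$visit
    treated <- df$genotype == 1L & df$period == 1L
    yr <- pmin(df$visit + 1L, length(cp$log_rr_years))
    log_mu <- log_mu + treated * cp$log_rr_years[yr]
    n <- config$n_g1 + config$n_g0
    frailty <- if (cp$dispersion > 0) {
      stats::setNames(stats::rgamma(n, shape = 1 / cp$dispersion,
                                    scale = cp$dispersion),
                      names(panel$intercepts))
    } else {
      stats::setNames(rep(1, n), names(panel$intercepts))
    }
    df$outcome <- stats::rpois(nrow(df),
                               frailty[df$person_id] * exp(log_mu))
    df <- .apply_missingness(df, config$p_missing_visit)
    ncc_cohort(df, outcome_kind = "count", max_visits = config$J,
               covariates = vapply(config$covariate_specs, `[[`, "", "name"))
  })
}

#' Closed-form ground truth for a generator configuration
#'
#' Derives, from the configuration's mean structure alone, the population
#' values targeted by the naive, negative control and corrected
#' estimators. Covariate-induced mean shifts enter the marginal
#' (unadjusted) naive and negative control truths and cancel exactly in
#' the corrected effect; `*_conditional` values strip the covariate
#' contributions and are the targets of covariate-adjusted fits.
#'
#' Step-change truths (difference scale), writing `dG`/`dP` for a
#' covariate's dependence on genotype/period and `e` for its outcome
#' effect:
#' * time-period comparison: NTE = `delta_St + gamma_PG + beta_P + sum(e*dP)`,
#'   NCE = `beta_P + sum(e*dP)`, NCCTE = `delta_St + gamma_PG`;
#' * genotype comparison: NTE = `delta_St + gamma_PG + beta_G + sum(e*dG)`,
#'   NCE = `beta_G + sum(e*dG)`, NCCTE = `delta_St + gamma_PG`.
#'
#' Slope-change truths: NTE = NCCTE = `delta_Sl`, NCE = 0 (the generator
#' has a common visit trend). Count-scale truths are the log-scale
#' analogues built from `count_params`, reported per treatment year.
#'
#' Because the interaction cell (P = 1, G = 1) is the fully treated cell,
#' a nonzero `gamma_PG` is indistinguishable within the generator from an
#' extra step effect: the causal step effect in the treated equals
#' `delta_St + gamma_PG`, and the corrected estimator remains aligned
#' with it. `gamma_PG` therefore probes the interpretation of the
#' no-interaction assumption rather than creating an estimable bias.
#'
#' @param config an `ncc_synth_config`.
#' @return list of class `ncc_ground_truth` with elements `cte_step`,
#'   `cte_slope`, `time_period` and `genotype` (each with `nte_step`,
#'   `nce_step`, `nccte_step`, conditional variants, and slope
#'   analogues), and `count` (per-year `nte_log_rr`, `nce_log_rr`,
#'   `nccte_log_rr` and `nccte_rr`).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "ncc_synth_config"))
  covP <- 0
  covG <- 0
  for (cv in config$covariate_specs) {
    covP <- covP + cv$effect * cv$dP
    covG <- covG + cv$effect * cv$dG
  }
  cte_step <- config$delta_St + config$gamma_PG
  comp <- function(beta_main, cov_shift) {
    list(nte_step = cte_step + beta_main + cov_shift,
         nce_step = beta_main + cov_shift,
         nccte_step = cte_step,
         nte_step_conditional = cte_step + beta_main,
         nce_step_conditional = beta_main,
         nccte_step_conditional = cte_step,
         nte_slope = config$delta_Sl,
         nce_slope = 0,
         nccte_slope = config$delta_Sl)
  }
  cp <- config$count_params
  K <- length(cp$log_rr_years)
  count_comp <- function(beta_main) {
    out <- list(nte_log_rr = cp$log_rr_years + cp$gamma_PG + beta_main,
                nce_log_rr = rep(beta_main, K),
                nccte_log_rr = cp$log_rr_years + cp$gamma_PG)
    out$nccte_rr <- exp(out$nccte_log_rr)
    out
  }
  count <- list(time_period = count_comp(cp$beta_P),
                genotype = count_comp(cp$beta_G))
  structure(list(
    cte_step = cte_step,
    cte_slope = config$delta_Sl,
    time_period = comp(config$beta_P, covP),
    genotype = comp(config$beta_G, covG),
    count = count
  ), class = "ncc_ground_truth")
}
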