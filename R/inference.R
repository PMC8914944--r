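#' Combine naive and negative control effects
#'
#' The difference-in-differences correction: on the difference scale the
#' corrected effect is `nte - nce`; on the rate-ratio scale it is
#' `nte / nce` (subtraction on the log scale). Vectorised.
#'
#' @param nte_point,nce_point naive and negative control point
#'   estimate(s), on the stated scale.
#' @param scale `"difference"` or `"rate_ratio"`.
#' @return the corrected point estimate(s).
#' @export
#' @examples
#' ncc_combine(7.27, 0.77, "difference")          # 6.50
#' ncc_combine(6.22, -0.37, "difference")         # 6.59
#' 100 * (1 - ncc_combine(0.42, 0.77, "rate_ratio")) # % reduction
ncc_combine <- function(nte_point, nce_point,
                        scale = c("difference", "rate_ratio")) {
  scale <- match.arg(scale)
  if (scale == "difference") {
    nte_point - nce_point
  } else {
    if (any(nte_point <= 0) || any(nce_point <= 0)) {
      stop("rate ratios must be strictly positive", call. = FALSE)
    }
    exp(log(nte_point) - log(nce_point))
  }
}

# Percentile-bootstrap p-value by interval inversion: the smallest alpha
# on a grid for which the (1 - alpha) percentile interval excludes the
# null.  qlo is nondecreasing and qhi nonincreasing in alpha, so the
# first exclusion is the minimum.
.boot_p <- function(draws, null) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0L) return(NA_real_)
  alphas <- seq(0.001, 0.999, by = 0.001)
  qlo <- stats::quantile(draws, alphas / 2, names = FALSE)
  qhi <- stats::quantile(draws, 1 - alphas / 2, names = FALSE)
  excl <- null < qlo | null > qhi
  if (any(excl)) alphas[which(excl)[1L]] else 1
}

.boot_summary <- function(point, draws, null) {
  # draws: B x ncomp matrix (failed rows removed); point: named vector
  ci_low <- apply(draws, 2L, stats::quantile, probs = 0.025, names = FALSE)
  ci_high <- apply(draws, 2L, stats::quantile, probs = 0.975, names = FALSE)
  p <- apply(draws, 2L, .boot_p, null = null)
  list(point = point,
       ci_low = stats::setNames(ci_low, names(point)),
       ci_high = stats::setNames(ci_high, names(point)),
       p_value = stats::setNames(p, names(point)))
}

#' Person-level (cluster) bootstrap of an arbitrary estimator
#'
#' Resamples persons with replacement — carrying all of a sampled
#' person's records in both periods, since the person is the dependence
#' unit — recomputes the estimator on each resample, and returns 95%
#' percentile confidence intervals and p-values by percentile-interval
#' inversion. Resamples on which the estimator fails (e.g. an analysis
#' group emptied by resampling) are dropped and counted; more than 5%
#' failures is an error.
#'
#' @param cohort an [ncc_cohort()].
#' @param estimator function taking a cohort and returning a numeric
#'   scalar or named vector; must succeed on `cohort` itself.
#' @param B number of resamples (default 1000; below 100 a warning is
#'   issued as percentile CIs are unstable).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @param null_value null value for the p-value inversion (0 for
#'   differences, 1 for rate ratios).
#' @return object of class `ncc_bootstrap`: list with `point`, `ci_low`,
#'   `ci_high`, `p_value` (each named like the estimator's return),
#'   `B`, `seed`, `n_failed`.
#' @export
bootstrap_effect <- function(cohort, estimator, B = 1000L, seed = 1L,
                             null_value = 0) {
  stopifnot(inherits(cohort, "ncc_cohort"), is.function(estimator), B >= 1)
  if (B < 100) {
    warning("B = ", B, " resamples; percentile intervals are unstable ",
            "below 100", call. = FALSE)
  }
  point <- estimator(cohort)
  if (is.null(names(point))) {
    names(point) <- if (length(point) == 1L) "estimate"
                    else paste0("estimate", seq_along(point))
  }
  df <- as.data.frame(cohort)
  person_rows <- split(seq_len(nrow(df)), df$person_id)
  np <- length(person_rows)
  draws <- matrix(NA_real_, nrow = B, ncol = length(point))
  .with_seed(seed, {
    for (b in seq_len(B)) {
      ids <- sample.int(np, np, replace = TRUE)
      rows <- person_rows[ids]
      rdf <- df[unlist(rows, use.names = FALSE), , drop = FALSE]
      # re-label clusters so duplicated persons stay distinct clusters
      rdf$person_id <- rep(sprintf("b%06d", seq_along(ids)),
                           times = lengths(rows))
      rcoh <- ncc_cohort(rdf, outcome_kind = outcome_kind(cohort),
                         max_visits = max_visits(cohort),
                         covariates = covariate_names(cohort),
                         validate = FALSE)
      est <- tryCatch(estimator(rcoh), error = function(e) NULL)
      if (!is.null(est) && all(is.finite(est))) draws[b, ] <- est
    }
  })
  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  if (n_failed / B > 0.05) {
    stop("estimator failed in ", n_failed, " of ", B,
         " bootstrap resamples (> 5%)", call. = FALSE)
  }
  out <- .boot_summary(point, draws[ok, , drop = FALSE], null_value)
  out$B <- as.integer(B)
  out$seed <- as.integer(seed)
  out$n_failed <- n_failed
  class(out) <- "ncc_bootstrap"
  out
}

#' @export
print.ncc_bootstrap <- function(x, ...) {
  cat("<ncc_bootstrap> B = ", x$B, " (", x$n_failed, " failed), seed ",
      x$seed, "\n", sep = "")
  tab <- data.frame(point = x$point, ci_low = x$ci_low,
                    ci_high = x$ci_high, p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

# ---- fast joint engine used by estimate_ncc ------------------------------

# Precompute everything the resampling loop needs as flat vectors.
.ncc_prep <- function(cohort, comparison, adjustment, covariate_spec,
                      n_treatment_years, visit_trend) {
  df <- as.data.frame(cohort)
  df <- df[!is.na(df$outcome), , drop = FALSE]
  if (adjustment != "unadjusted") {
    if (is.null(covariate_spec)) {
      stop("adjustment '", adjustment, "' requires a covariate_spec",
           call. = FALSE)
    }
    cc <- stats::complete.cases(df[covariate_spec$names])
    if (any(!cc)) {
      message("dropped ", sum(!cc),
              " record(s) with missing covariate values (complete case)")
      df <- df[cc, , drop = FALSE]
    }
  }
  kinds <- if (comparison == "time_period") c("NTE_P", "NCE_P")
           else c("NTE_G", "NCE_G")
  grp <- assign_group(df$genotype, df$period)
  for (kind in kinds) {
    pair <- contrast_groups(kind)
    for (g in c(pair$x0, pair$x1)) {
      if (!any(grp == g)) {
        stop("contrast ", kind, " requires group ", g,
             ", which is empty in this cohort", call. = FALSE)
      }
    }
  }
  covmat <- if (adjustment != "unadjusted") {
    encode_covariates(covariate_spec, df)
  } else NULL
  sel <- lapply(kinds, function(kind) {
    pair <- contrast_groups(kind)
    list(kind = kind,
         inset = grp %in% c(pair$x0, pair$x1),
         x = as.integer(grp == pair$x1))
  })
  names(sel) <- c("nte", "nce")
  list(y = df$outcome, j = as.numeric(df$visit), sel = sel,
       covmat = covmat,
       person_rows = split(seq_len(nrow(df)), df$person_id),
       outcome_kind = outcome_kind(cohort),
       K = if (is.null(n_treatment_years))
         length(unique(df$visit)) else as.integer(n_treatment_years),
       visit_trend = visit_trend,
       adjustment = adjustment)
}

# One step/slope fit on a row subset; returns c(step, slope) or NULL on a
# degenerate resample.
.fast_step_slope <- function(prep, s, rows) {
  r <- rows[s$inset[rows]]
  X <- s$x[r]
  if (length(r) == 0L || all(X == 1L) || all(X == 0L)) return(NULL)
  j <- prep$j[r]
  D <- cbind(1, X, X * j, j)
  if (!is.null(prep$covmat)) D <- cbind(D, prep$covmat[r, , drop = FALSE])
  fit <- stats::.lm.fit(D, prep$y[r])
  beta <- fit$coefficients
  if (anyNA(beta) || fit$rank < ncol(D)) return(NULL)
  c(step = beta[2L], slope = beta[3L])
}

# Standardized (g-computation) step and slope: per-visit standardized
# mean differences d_v; step = d_0, slope = least-squares slope of d_v
# on v.
.fast_standardized <- function(prep, s, rows) {
  r <- rows[s$inset[rows]]
  X <- s$x[r]
  if (length(r) == 0L || all(X == 1L) || all(X == 0L)) return(NULL)
  j <- prep$j[r]
  visits <- sort(unique(j))
  d <- rep(NA_real_, length(visits))
  for (i in seq_along(visits)) {
    at <- j == visits[i]
    r0 <- r[at & X == 0L]
    r1 <- r[at & X == 1L]
    if (length(r0) == 0L || length(r1) == 0L) return(NULL)
    M0 <- prep$covmat[r0, , drop = FALSE]
    M1 <- prep$covmat[r1, , drop = FALSE]
    D0 <- cbind(1, M0)
    fit <- stats::.lm.fit(D0, prep$y[r0])
    if (anyNA(fit$coefficients) || fit$rank < ncol(D0)) return(NULL)
    pred1 <- drop(cbind(1, M1) %*% fit$coefficients)
    d[i] <- mean(prep$y[r1]) - mean(pred1)
  }
  slope <- if (length(visits) > 1L) {
    stats::cov(visits, d) / stats::var(visits)
  } else NA_real_
  c(step = d[which(visits == min(visits))], slope = slope)
}

# One count fit on a row subset; returns per-year log rate ratios.
.fast_count <- function(prep, s, rows) {
  r <- rows[s$inset[rows]]
  X <- s$x[r]
  if (length(r) == 0L || all(X == 1L) || all(X == 0L)) return(NULL)
  j <- prep$j[r]
  y <- prep$y[r]
  # diverging cells: any modeled (X, visit) cell with an all-zero sum
  cell <- interaction(X, j, drop = TRUE)
  if (any(tapply(y, cell, sum) == 0)) return(NULL)
  covmat <- if (!is.null(prep$covmat)) prep$covmat[r, , drop = FALSE]
            else NULL
  D <- .count_design(X, j, prep$K, prep$visit_trend, covmat)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(D, y, family = stats::poisson(),
                                    control = stats::glm.control(
                                      epsilon = 1e-10, maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
    return(NULL)
  }
  gam <- stats::setNames(fit$coefficients, colnames(D))
  lrr <- gam[paste0("gamma_X", seq_len(prep$K))]
  stats::setNames(unname(lrr), paste0("year", seq_len(prep$K)))
}

# Standardized count effect: per-year ratio of the observed X=1 mean to
# the g-computation standardized mean from the X=0 outcome model.
.fast_count_standardized <- function(prep, s, rows) {
  r <- rows[s$inset[rows]]
  X <- s$x[r]
  if (length(r) == 0L || all(X == 1L) || all(X == 0L)) return(NULL)
  j <- prep$j[r]
  y <- prep$y[r]
  out <- rep(NA_real_, prep$K)
  for (k in seq_len(prep$K)) {
    at <- j == (k - 1)
    r0 <- which(at & X == 0L)
    r1 <- which(at & X == 1L)
    if (length(r0) == 0L || length(r1) == 0L) return(NULL)
    if (sum(y[r0]) == 0 || sum(y[r1]) == 0) return(NULL)
    M0 <- prep$covmat[r[r0], , drop = FALSE]
    M1 <- prep$covmat[r[r1], , drop = FALSE]
    D0 <- cbind(1, M0)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(D0, y[r0],
                                      family = stats::poisson(),
                                      control = stats::glm.control(
                                        epsilon = 1e-10, maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
      return(NULL)
    }
    pred1 <- exp(drop(cbind(1, M1) %*% fit$coefficients))
    out[k] <- log(mean(y[r1])) - log(mean(pred1))
  }
  stats::setNames(out, paste0("year", seq_len(prep$K)))
}

# Dispatch one (contrast, rows) evaluation to the right fitter; returns
# the component vector on the working scale (difference, or log RR).
.fast_fit <- function(prep, s, rows) {
  if (prep$outcome_kind == "continuous") {
    if (prep$adjustment == "standardized") {
      .fast_standardized(prep, s, rows)
    } else {
      .fast_step_slope(prep, s, rows)
    }
  } else {
    if (prep$adjustment == "standardized") {
      .fast_count_standardized(prep, s, rows)
    } else {
      .fast_count(prep, s, rows)
    }
  }
}

#' Estimate naive, negative control and corrected treatment effects
#'
#' The package's main entry point. For the chosen comparison it builds
#' the naive contrast (`NTE_P` for `time_period`: treated group B versus
#' its historical controls A; `NTE_G` for `genotype`: B versus the
#' contemporaneous ineligible group D) and the matching label-switched
#' negative control contrast (`NCE_P`: the ineligible genotype across
#' periods, D versus C; `NCE_G`: the pre-introduction outcomes across
#' genotypes, A versus C), fits the step/slope model (continuous
#' outcome) or the year-specific rate-ratio model (count outcome) to
#' each, and combines them into the negative-control-corrected effect:
#' NCCTE = NTE - NCE on the difference scale, NTE / NCE on the
#' rate-ratio scale.
#'
#' All three effects are bootstrapped jointly: one person-level resample
#' of the whole cohort per iteration feeds the naive and negative control
#' fits together, so the corrected effect's interval reflects joint
#' resampling of all four groups and of persons contributing to two
#' groups.
#'
#' @param cohort an [ncc_cohort()] containing all four groups.
#' @param comparison `"time_period"` or `"genotype"`.
#' @param adjustment `"unadjusted"`, `"conditional"` (covariates in the
#'   outcome model) or `"standardized"` (g-computation over the treated
#'   group's covariate distribution).
#' @param covariate_spec a [covariate_spec()] (or character vector),
#'   required unless `adjustment = "unadjusted"`.
#' @param B bootstrap resamples (default 1000).
#' @param seed integer seed for the resampling stream.
#' @param n_treatment_years,visit_trend count-model options, see
#'   [fit_count_effects()].
#' @return object of class `ncc_effect_triple`: list with `comparison`,
#'   `scale` (`"difference"` or `"rate_ratio"`), `adjustment`, `B`,
#'   `seed`, `n_failed`, and effect records `nte`, `nce`, `nccte`, each
#'   holding named `point`, `ci_low`, `ci_high`, `p_value` (plus
#'   `log_point` on the rate-ratio scale, where the corrected log point
#'   is exactly the difference of the component log points).
#' @export
#' @examples
#' coh <- simulate_cohort(scenario_config("scenario3", n_g1 = 150,
#'                                        n_g0 = 150, seed = 7))
#' estimate_ncc(coh, "genotype", B = 100, seed = 7)
estimate_ncc <- function(cohort,
                         comparison = c("time_period", "genotype"),
                         adjustment = c("unadjusted", "conditional",
                                        "standardized"),
                         covariate_spec = NULL, B = 1000L, seed = 1L,
                         n_treatment_years = NULL,
                         visit_trend = c("saturated", "linear")) {
  stopifnot(inherits(cohort, "ncc_cohort"), B >= 1)
  comparison <- match.arg(comparison)
  adjustment <- match.arg(adjustment)
  visit_trend <- match.arg(visit_trend)
  if (is.character(covariate_spec)) {
    covariate_spec <- covariate_spec(covariate_spec)
  }
  if (B < 100) {
    warning("B = ", B, " resamples; percentile intervals are unstable ",
            "below 100", call. = FALSE)
  }
  prep <- .ncc_prep(cohort, comparison, adjustment, covariate_spec,
                    n_treatment_years, visit_trend)
  scale <- if (prep$outcome_kind == "continuous") "difference"
           else "rate_ratio"
  all_rows <- seq_along(prep$y)
  nte0 <- .fast_fit(prep, prep$sel$nte, all_rows)
  nce0 <- .fast_fit(prep, prep$sel$nce, all_rows)
  if (is.null(nte0) || is.null(nce0)) {
    stop("effect estimation failed on the full cohort (degenerate ",
         "contrast)", call. = FALSE)
  }
  np <- length(prep$person_rows)
  ncomp <- length(nte0)
  nte_d <- matrix(NA_real_, B, ncomp)
  nce_d <- matrix(NA_real_, B, ncomp)
  .with_seed(seed, {
    for (b in seq_len(B)) {
      ids <- sample.int(np, np, replace = TRUE)
      rows <- unlist(prep$person_rows[ids], use.names = FALSE)
      en <- .fast_fit(prep, prep$sel$nte, rows)
      ec <- .fast_fit(prep, prep$sel$nce, rows)
      if (!is.null(en) && !is.null(ec) &&
          all(is.finite(en)) && all(is.finite(ec))) {
        nte_d[b, ] <- en
        nce_d[b, ] <- ec
      }
    }
  })
  ok <- stats::complete.cases(cbind(nte_d, nce_d))
  n_failed <- sum(!ok)
  if (n_failed / B > 0.05) {
    stop("effect estimation failed in ", n_failed, " of ", B,
         " bootstrap resamples (> 5%)", call. = FALSE)
  }
  nte_d <- nte_d[ok, , drop = FALSE]
  nce_d <- nce_d[ok, , drop = FALSE]
  ncc_d <- nte_d - nce_d          # working scale: difference or log RR
  mk <- function(point_work, draws_work) {
    if (scale == "difference") {
      out <- .boot_summary(point_work, draws_work, null = 0)
    } else {
      out <- .boot_summary(exp(point_work), exp(draws_work), null = 1)
      out$log_point <- point_work
    }
    out
  }
  nms <- names(nte0)
  eff <- list(
    nte = mk(stats::setNames(nte0, nms), nte_d),
    nce = mk(stats::setNames(nce0, nms), nce_d),
    nccte = mk(stats::setNames(nte0 - nce0, nms), ncc_d))
  structure(list(comparison = comparison, scale = scale,
                 adjustment = adjustment,
                 nte = eff$nte, nce = eff$nce, nccte = eff$nccte,
                 B = as.integer(B), seed = as.integer(seed),
                 n_failed = n_failed),
            class = "ncc_effect_triple")
}

#' @export
print.ncc_effect_triple <- function(x, ...) {
  cat("<ncc_effect_triple> ", x$comparison, " comparison, ", x$scale,
      " scale, ", x$adjustment, " (B = ", x$B, ", ", x$n_failed,
      " failed, seed ", x$seed, ")\n", sep = "")
  for (nm in c("nte", "nce", "nccte")) {
    e <- x[[nm]]
    cat("  ", toupper(nm), ":\n", sep = "")
    tab <- data.frame(point = e$point, ci_low = e$ci_low,
                      ci_high = e$ci_high, p = e$p_value)
    if (x$scale == "difference") {
      tab[, 1:3] <- round(tab[, 1:3], 2)
    } else {
      tab$pct_reduction <- round(100 * (1 - e$point))
      tab[, 1:3] <- round(tab[, 1:3], 3)
    }
    tab$p <- signif(tab$p, 3)
    print(tab)
  }
  invisible(x)
}

#' Flatten an effect triple to a data.frame
#'
#' @param x an `ncc_effect_triple`.
#' @param ... unused.
#' @return data.frame with one row per (effect, component).
#' @export
as.data.frame.ncc_effect_triple <- function(x, ...) {
  rows <- list()
  for (nm in c("nte", "nce", "nccte")) {
    e <- x[[nm]]
    rows[[nm]] <- data.frame(
      comparison = x$comparison, scale = x$scale,
      adjustment = x$adjustment, effect = toupper(nm),
      component = names(e$point), point = unname(e$point),
      ci_low = unname(e$ci_low), ci_high = unname(e$ci_high),
      p_value = unname(e$p_value), B = x$B, seed = x$seed,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
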