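#' Covariate specification and encodings
#'
#' Declares the baseline covariates entering an adjusted analysis and how
#' each is encoded into design-matrix columns:
#'
#' * `"identity"` — one column, the covariate as-is (continuous).
#' * `"binary"` — one column, validated to contain only 0/1.
#' * `"count_baseline"` — two columns for a baseline count covariate: an
#'   indicator of a nonzero count, and a linear term for the nonzero
#'   counts (zero elsewhere). This captures the common spike-at-zero shape
#'   of, e.g., baseline annual IV-antibiotic days.
#'
#' @param names ordered character vector of covariate names (unique).
#' @param encodings character vector, one encoding per name (recycled if
#'   length 1); defaults to `"identity"` for every covariate.
#' @return an object of class `ncc_covariate_spec`.
#' @export
covariate_spec <- function(names, encodings = "identity") {
  stopifnot(is.character(names), !anyDuplicated(names))
  encodings <- rep_len(encodings, length(names))
  ok <- encodings %in% c("identity", "binary", "count_baseline")
  if (!all(ok)) {
    stop("unknown encoding(s): ",
         paste(unique(encodings[!ok]), collapse = ", "), call. = FALSE)
  }
  structure(list(names = names, encodings = stats::setNames(encodings, names)),
            class = "ncc_covariate_spec")
}

#' Encode covariates into a numeric design block
#'
#' @param spec a [covariate_spec()].
#' @param data data.frame holding the covariate columns.
#' @return numeric matrix with one row per row of `data`; `identity` and
#'   `binary` encodings contribute one column each (named after the
#'   covariate), `count_baseline` contributes `<name>_pos` (nonzero
#'   indicator) and `<name>_posval` (value among nonzeros, else 0).
#' @export
encode_covariates <- function(spec, data) {
  stopifnot(inherits(spec, "ncc_covariate_spec"))
  cols <- list()
  for (nm in spec$names) {
    v <- as.numeric(data[[nm]])
    enc <- spec$encodings[[nm]]
    if (enc == "identity") {
      cols[[nm]] <- v
    } else if (enc == "binary") {
      if (any(!is.na(v) & !(v %in% c(0, 1)))) {
        stop("covariate '", nm, "' declared binary but has values ",
             "outside {0, 1}", call. = FALSE)
      }
      cols[[nm]] <- v
    } else { # count_baseline
      pos <- as.numeric(v > 0)
      cols[[paste0(nm, "_pos")]] <- pos
      cols[[paste0(nm, "_posval")]] <- v * pos
    }
  }
  do.call(cbind, cols)
}

# Rank check via pivoted QR; errors naming the collinear columns.
# tol is relative to the largest diagonal of R (proxy for largest
# singular value at this scale).
.check_full_rank <- function(M, tol = 1e-8) {
  qrd <- qr(M, tol = tol)
  if (qrd$rank < ncol(M)) {
    bad <- colnames(M)[qrd$pivot[(qrd$rank + 1L):ncol(M)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Build the step/slope design for an analysis set (or raw vectors).
.step_slope_design <- function(X, j, covmat = NULL) {
  D <- cbind(`(Intercept)` = 1, X = X, `X:j` = X * j, j = j)
  if (!is.null(covmat)) D <- cbind(D, covmat)
  D
}

# Cluster-robust (person-level) sandwich covariance for a least-squares
# fit: bread = (X'X)^-1, meat = sum_c (X_c' r_c)(X_c' r_c)'.
.sandwich_cluster <- function(D, resid, cluster) {
  bread <- chol2inv(chol(crossprod(D)))
  sc <- rowsum(D * resid, cluster)
  meat <- crossprod(as.matrix(sc))
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(D), colnames(D))
  V
}

#' Fit the step-change / slope-change linear model
#'
#' Fits the marginal mean model
#' \deqn{E(Y_{ij} | X_i) = \beta_0 + \beta_{St} X_i + \beta_{Sl} X_i j
#'   + \beta_J j}
#' to a continuous outcome by estimating equations with an independence
#' working correlation. `beta_St` is the step-change effect (level shift
#' at visit 0) and `beta_Sl` the slope-change effect (change in the
#' annual trend); `beta_J` is the trend shared by both X levels. With an
#' independence working correlation the point estimates coincide with
#' ordinary least squares on the stacked person-visit rows; within-person
#' dependence is handled at the inference stage (cluster bootstrap, see
#' [bootstrap_effect()]). A person-clustered sandwich covariance is
#' attached as a diagnostic but is not the package's reported interval.
#'
#' When the analysis set carries a covariate specification the encoded
#' covariate columns are added to the design, giving conditional
#' (covariate-adjusted) effects.
#'
#' @param aset an `ncc_analysis_set` with a continuous outcome.
#' @return an object of class `step_slope_fit`: list with `coefficients`
#'   (named `beta_0`, `beta_St`, `beta_Sl`, `beta_J`),
#'   `covariate_coefficients`, `vcov_cluster` (diagnostic sandwich
#'   covariance), `n_persons`, `n_records`, `contrast`.
#' @export
fit_step_slope <- function(aset) {
  stopifnot(inherits(aset, "ncc_analysis_set"))
  if (outcome_kind(aset) == "count") {
    stop("fit_step_slope requires a continuous outcome; use ",
         "fit_count_effects for count outcomes", call. = FALSE)
  }
  df <- as.data.frame(aset)
  if (length(unique(df$X)) < 2L) {
    stop("both X levels must be present", call. = FALSE)
  }
  for (lev in c(0L, 1L)) {
    np <- length(unique(df$person_id[df$X == lev]))
    if (np < 2L) {
      stop("X = ", lev, " has fewer than 2 persons", call. = FALSE)
    }
  }
  cs <- attr(aset, "covariate_spec")
  covmat <- if (!is.null(cs)) encode_covariates(cs, df) else NULL
  D <- .step_slope_design(df$X, df$visit, covmat)
  .check_full_rank(D)
  fit <- stats::.lm.fit(D, df$outcome)
  beta <- stats::setNames(fit$coefficients, colnames(D))
  resid <- df$outcome - drop(D %*% beta)
  structure(list(
    coefficients = c(beta_0 = unname(beta["(Intercept)"]),
                     beta_St = unname(beta["X"]),
                     beta_Sl = unname(beta["X:j"]),
                     beta_J = unname(beta["j"])),
    covariate_coefficients =
      if (!is.null(covmat)) beta[colnames(covmat)] else NULL,
    vcov_cluster = .sandwich_cluster(D, resid, df$person_id),
    n_persons = length(unique(df$person_id)),
    n_records = nrow(df),
    contrast = attr(aset, "contrast")
  ), class = "step_slope_fit")
}

#' @export
print.step_slope_fit <- function(x, ...) {
  cat("<step_slope_fit> contrast ", x$contrast, " (", x$n_persons,
      " persons, ", x$n_records, " records)\n", sep = "")
  print(round(x$coefficients, 4))
  if (!is.null(x$covariate_coefficients)) {
    cat("covariate coefficients:\n")
    print(round(x$covariate_coefficients, 4))
  }
  invisible(x)
}

# Count-model design: intercept, visit terms (saturated indicators by
# default, or a single linear term), and one X x 1(j = k-1) column per
# treatment year k.
.count_design <- function(X, j, n_treatment_years,
                          visit_trend = c("saturated", "linear"),
                          covmat = NULL) {
  visit_trend <- match.arg(visit_trend)
  D <- cbind(`(Intercept)` = rep(1, length(X)))
  if (visit_trend == "saturated") {
    for (v in sort(unique(j))) {
      if (v == min(j)) next
      col <- matrix(as.numeric(j == v), ncol = 1,
                    dimnames = list(NULL, paste0("j", v)))
      D <- cbind(D, col)
    }
  } else {
    D <- cbind(D, j = j)
  }
  for (k in seq_len(n_treatment_years)) {
    col <- matrix(as.numeric(X == 1 & j == (k - 1L)), ncol = 1,
                  dimnames = list(NULL, paste0("gamma_X", k)))
    D <- cbind(D, col)
  }
  if (!is.null(covmat)) D <- cbind(D, covmat)
  D
}

#' Fit the year-specific rate-ratio count model
#'
#' Fits the marginal log-rate model
#' \deqn{\log E(Y_{ij} | X_i) = \gamma_0 + (\textrm{visit terms}) +
#'   \sum_k \gamma_{Xk} X_i 1(j = k - 1)}
#' to a nonnegative-integer count outcome (e.g. annual IV-antibiotic
#' days) by log-link quasi-score estimating equations with an
#' independence working correlation and variance proportional to the
#' mean. Point estimates coincide with a Poisson GLM on the stacked rows,
#' and are consistent under overdispersion. `exp(gamma_Xk)` is the rate
#' ratio after k years of treatment (treatment year k is visit j = k - 1
#' of the post-introduction period). Secular visit terms are saturated
#' indicators by default, or a single linear-in-j trend.
#'
#' @param aset an `ncc_analysis_set` with a count outcome.
#' @param n_treatment_years number of year-specific treatment terms
#'   (default: the number of distinct visit indices present).
#' @param visit_trend `"saturated"` (default) or `"linear"`.
#' @return object of class `count_effects_fit`: list with `gamma_0`,
#'   `gamma_J` (visit-term coefficients), `gamma_X` (named
#'   `gamma_X1`, ...), `rate_ratios` (= `exp(gamma_X)`), `dispersion`
#'   (Pearson), `covariate_coefficients`, `n_persons`, `n_records`,
#'   `contrast`.
#' @export
fit_count_effects <- function(aset, n_treatment_years = NULL,
                              visit_trend = c("saturated", "linear")) {
  stopifnot(inherits(aset, "ncc_analysis_set"))
  visit_trend <- match.arg(visit_trend)
  if (outcome_kind(aset) != "count") {
    stop("fit_count_effects requires a count outcome", call. = FALSE)
  }
  df <- as.data.frame(aset)
  y <- df$outcome
  if (any(y < 0 | y != round(y))) {
    stop("count outcomes must be nonnegative integers", call. = FALSE)
  }
  if (length(unique(df$X)) < 2L) {
    stop("both X levels must be present", call. = FALSE)
  }
  if (is.null(n_treatment_years)) {
    n_treatment_years <- length(unique(df$visit))
  }
  # each modeled (X, visit) cell must contain a positive count, else the
  # corresponding log rate diverges to -Inf
  for (x in c(0L, 1L)) for (v in sort(unique(df$visit))) {
    cell <- df$X == x & df$visit == v
    if (any(cell) && sum(y[cell]) == 0) {
      stop("all outcomes are zero in the cell X = ", x, ", visit = ", v,
           "; its log rate is -Inf", call. = FALSE)
    }
  }
  cs <- attr(aset, "covariate_spec")
  covmat <- if (!is.null(cs)) encode_covariates(cs, df) else NULL
  D <- .count_design(df$X, df$visit, n_treatment_years, visit_trend, covmat)
  .check_full_rank(D)
  fit <- suppressWarnings(
    stats::glm.fit(D, y, family = stats::poisson(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)))
  if (!fit$converged) {
    stop("count-model estimating equations did not converge",
         call. = FALSE)
  }
  gam <- stats::setNames(fit$coefficients, colnames(D))
  xnames <- paste0("gamma_X", seq_len(n_treatment_years))
  mu <- fit$fitted.values
  disp <- sum((y - mu)^2 / mu) / (nrow(D) - ncol(D))
  jnames <- setdiff(colnames(D), c("(Intercept)", xnames,
                                   colnames(covmat)))
  structure(list(
    gamma_0 = unname(gam["(Intercept)"]),
    gamma_J = gam[jnames],
    gamma_X = gam[xnames],
    rate_ratios = exp(gam[xnames]),
    dispersion = disp,
    covariate_coefficients =
      if (!is.null(covmat)) gam[colnames(covmat)] else NULL,
    n_persons = length(unique(df$person_id)),
    n_records = nrow(df),
    contrast = attr(aset, "contrast")
  ), class = "count_effects_fit")
}

#' @export
print.count_effects_fit <- function(x, ...) {
  cat("<count_effects_fit> contrast ", x$contrast, " (", x$n_persons,
      " persons, ", x$n_records, " records)\n", sep = "")
  cat("rate ratios by treatment year:\n")
  print(round(x$rate_ratios, 4))
  cat("Pearson dispersion:", round(x$dispersion, 3), "\n")
  invisible(x)
}

#' Standardized (g-computation) treatment effect at one visit
#'
#' Computes the covariate-standardized mean difference at a given visit:
#' an outcome regression on the encoded covariates is fitted among the
#' X = 0 records at that visit, its predictions are averaged over the
#' empirical covariate distribution of the X = 1 records at the same
#' visit, and that standardized mean is subtracted from the observed
#' X = 1 mean. With no covariates this collapses to the unadjusted
#' difference in means; when the covariate distribution is identical in
#' both X levels and the outcome model is linear with no X-by-covariate
#' interaction it agrees with the conditional (covariate-in-model)
#' estimate.
#'
#' Support overlap is checked for discrete covariates (`binary` and the
#' nonzero indicator of `count_baseline`): a stratum present under X = 1
#' but absent under X = 0 is an error. For continuous covariates a
#' warning is issued when X = 1 values fall outside the observed X = 0
#' range (extrapolation).
#'
#' @param aset an `ncc_analysis_set` carrying a nonempty covariate
#'   specification.
#' @param at_visit visit index at which to standardize (default 0, the
#'   step-change visit).
#' @return the standardized mean difference (outcome units), a scalar.
#' @export
standardize_effect <- function(aset, at_visit = 0L) {
  stopifnot(inherits(aset, "ncc_analysis_set"))
  cs <- attr(aset, "covariate_spec")
  if (is.null(cs) || length(cs$names) == 0L) {
    stop("standardize_effect requires a nonempty covariate_spec ",
         "(use the plain difference in means otherwise)", call. = FALSE)
  }
  df <- as.data.frame(aset)
  df <- df[df$visit == at_visit, , drop = FALSE]
  d0 <- df[df$X == 0L, , drop = FALSE]
  d1 <- df[df$X == 1L, , drop = FALSE]
  if (nrow(d0) == 0L || nrow(d1) == 0L) {
    stop("no records at visit ", at_visit, " in one of the X levels",
         call. = FALSE)
  }
  M0 <- encode_covariates(cs, d0)
  M1 <- encode_covariates(cs, d1)
  for (cc in colnames(M0)) {
    discrete <- all(M0[, cc] %in% c(0, 1)) && all(M1[, cc] %in% c(0, 1))
    if (discrete) {
      missing_lvl <- setdiff(unique(M1[, cc]), unique(M0[, cc]))
      if (length(missing_lvl) > 0L) {
        stop("no overlap: stratum ", cc, " = ", missing_lvl[1L],
             " present under X=1 but absent under X=0", call. = FALSE)
      }
    } else if (any(M1[, cc] > max(M0[, cc]) | M1[, cc] < min(M0[, cc]))) {
      warning("continuous covariate column '", cc, "' has X=1 values ",
              "outside the X=0 support; standardization extrapolates",
              call. = FALSE)
    }
  }
  D0 <- cbind(`(Intercept)` = 1, M0)
  .check_full_rank(D0)
  beta <- stats::.lm.fit(D0, d0$outcome)$coefficients
  pred1 <- drop(cbind(1, M1) %*% beta)
  mean(d1$outcome) - mean(pred1)
}
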