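# Small hand-built cohorts used across the unit tests.

# One person per group, one visit each.
tiny_cohort <- function(outcomes = c(A = 71, B = 78, C = 70, D = 72)) {
  ncc_cohort(data.frame(
    person_id = c("pa", "pb", "pc", "pd"),
    genotype = c(1L, 1L, 0L, 0L),
    period = c(0L, 1L, 0L, 1L),
    visit = 0L,
    outcome = unname(outcomes[c("A", "B", "C", "D")])))
}

# Balanced noise-free panel: n persons per group, J visits, outcome a
# deterministic function mean_fun(G, P, j).
panel_cohort <- function(mean_fun, n = 3L, J = 4L,
                         outcome_kind = "continuous") {
  rows <- list()
  id <- 0L
  for (g in 0:1) for (p in 0:1) for (i in seq_len(n)) {
    id <- id + 1L
    rows[[id]] <- data.frame(
      person_id = sprintf("p%03d", id), genotype = g, period = p,
      visit = 0:(J - 1L), outcome = mean_fun(g, p, 0:(J - 1L)))
  }
  ncc_cohort(do.call(rbind, rows), outcome_kind = outcome_kind,
             max_visits = J)
}

# Random small analysis set for oracle-equivalence checks.
random_aset <- function(seed, n_persons = 20L, J = 4L, count = FALSE,
                        with_covariate = FALSE) {
  set.seed(seed)
  rows <- list()
  full <- c(1L, as.integer(n_persons / 2) + 1L) # one full panel per arm
  for (i in seq_len(n_persons)) {
    nv <- if (i %in% full) J else sample(1:J, 1L)
    g <- as.integer(i > n_persons / 2)
    h <- round(rnorm(1, 10, 3), 2)
    y <- if (count) {
      rpois(nv, exp(1.5 + 0.1 * (0:(nv - 1)) - 0.4 * g))
    } else {
      50 + 2 * g + 0.5 * (0:(nv - 1)) + rnorm(nv, 0, 3)
    }
    rows[[i]] <- data.frame(
      person_id = sprintf("p%03d", i), genotype = g,
      period = 1L, visit = 0:(nv - 1L), outcome = y, h = h)
  }
  df <- do.call(rbind, rows)
  # fabricate the other group of the NTE_G pair (D = G0/P1, B = G1/P1)
  coh <- ncc_cohort(df, outcome_kind = if (count) "count" else "continuous",
                    max_visits = J, covariates = "h")
  build_contrast(coh, "NTE_G",
                 covariate_spec = if (with_covariate) "h" else NULL)
}

# Independent least-squares oracle: explicit normal-equations solve.
ols_oracle <- function(D, y) {
  drop(solve(crossprod(D), crossprod(D, y)))
}

# Independent Poisson-score oracle: hand-rolled IRLS.
irls_oracle <- function(D, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(D))
  beta[1] <- log(mean(y) + 0.1)
  for (it in seq_len(maxit)) {
    eta <- drop(D %*% beta)
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    new <- drop(solve(crossprod(D, D * W), crossprod(D, W * z)))
    if (max(abs(new - beta)) < tol * (1 + max(abs(beta)))) {
      return(new)
    }
    beta <- new
  }
  beta
}
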