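#' Two-group analysis sets by treatment-label switching
#'
#' `build_contrast()` extracts the two groups of a comparison from the
#' cohort and tags each record with a pseudo-treatment label X. Four
#' contrasts are defined:
#'
#' * `NTE_P` — time-period naive effect: groups A (X = 0) and B (X = 1).
#' * `NTE_G` — genotype naive effect: groups D (X = 0) and B (X = 1).
#' * `NCE_P` — time-period negative control effect: groups C (X = 0) and
#'   D (X = 1). The "treatment" label is switched onto group D, so X
#'   tracks the period among persons whose genotype makes them ineligible
#'   for treatment in either period.
#' * `NCE_G` — genotype negative control effect: groups C (X = 0) and A
#'   (X = 1). The label is switched onto group A, so X tracks the
#'   genotype using only pre-introduction outcomes, which treatment
#'   cannot have affected.
#'
#' A nonzero negative control effect flags bias in the matching naive
#' effect; subtracting it (difference-in-differences) gives the corrected
#' effect, see [estimate_ncc()].
#'
#' @param cohort an [ncc_cohort()].
#' @param kind one of `"NTE_P"`, `"NTE_G"`, `"NCE_P"`, `"NCE_G"`.
#' @param covariate_spec `NULL` for an unadjusted set, or a
#'   [covariate_spec()] (or plain character vector of covariate names,
#'   encoded as identity). Records missing any named covariate are dropped
#'   (complete case) with a message reporting the count.
#' @return An `ncc_analysis_set`: the selected records with an added `X`
#'   column, plus attributes `contrast`, `covariate_spec`, `outcome_kind`
#'   and `max_visits`.
#' @export
#' @examples
#' coh <- simulate_cohort(scenario_config("scenario3", n_g1 = 30, n_g0 = 30))
#' aset <- build_contrast(coh, "NCE_G")
#' table(aset$X, assign_group(aset$genotype, aset$period))
build_contrast <- function(cohort, kind = c("NTE_P", "NTE_G", "NCE_P", "NCE_G"),
                           covariate_spec = NULL) {
  stopifnot(inherits(cohort, "ncc_cohort"))
  kind <- match.arg(kind)
  if (is.character(covariate_spec)) {
    covariate_spec <- covariate_spec(covariate_spec)
  }
  pair <- contrast_groups(kind)
  df <- as.data.frame(cohort)
  grp <- assign_group(df$genotype, df$period)
  for (g in c(pair$x0, pair$x1)) {
    if (!any(grp == g)) {
      stop("contrast ", kind, " requires group ", g,
           ", which is empty in this cohort", call. = FALSE)
    }
  }
  sel <- grp %in% c(pair$x0, pair$x1)
  df <- df[sel, , drop = FALSE]
  df$X <- as.integer(grp[sel] == pair$x1)
  if (!is.null(covariate_spec)) {
    nms <- covariate_spec$names
    missing_cov <- setdiff(nms, names(df))
    if (length(missing_cov) > 0L) {
      stop("covariate(s) not present in cohort: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    cc <- stats::complete.cases(df[nms])
    if (any(!cc)) {
      message("dropped ", sum(!cc),
              " record(s) with missing covariate values (complete case)")
      df <- df[cc, , drop = FALSE]
    }
  }
  if (length(unique(df$X)) < 2L) {
    stop("both X levels must be nonempty after filtering", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df,
            contrast = kind,
            covariate_spec = covariate_spec,
            outcome_kind = outcome_kind(cohort),
            max_visits = max_visits(cohort),
            class = c("ncc_analysis_set", "data.frame"))
}

#' @rdname build_contrast
#' @return `contrast_groups()` returns `list(x0 = , x1 = )`, the group
#'   labels receiving X = 0 and X = 1 under each contrast.
#' @export
contrast_groups <- function(kind = c("NTE_P", "NTE_G", "NCE_P", "NCE_G")) {
  kind <- match.arg(kind)
  switch(kind,
         NTE_P = list(x0 = "A", x1 = "B"),
         NTE_G = list(x0 = "D", x1 = "B"),
         NCE_P = list(x0 = "C", x1 = "D"),
         NCE_G = list(x0 = "C", x1 = "A"))
}

#' @export
print.ncc_analysis_set <- function(x, ...) {
  pair <- contrast_groups(attr(x, "contrast"))
  cat("<ncc_analysis_set> contrast ", attr(x, "contrast"), ": group ",
      pair$x0, " (X=0, ", sum(x$X == 0L), " records) vs group ", pair$x1,
      " (X=1, ", sum(x$X == 1L), " records)\n", sep = "")
  cs <- attr(x, "covariate_spec")
  if (!is.null(cs)) {
    cat("  adjusted for:", paste(cs$names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Restrict the ineligible-genotype group to a genotype subset
#'
#' Sensitivity analyses re-run the comparisons with the G = 0 group
#' restricted to a genotype subset (e.g. persons homozygous for a common
#' mutation), using the free-text `genotype_label` column. Eligible
#' (G = 1) persons are always retained.
#'
#' @param cohort an `ncc_cohort` with a `genotype_label` column.
#' @param keep either a character vector of labels to keep, or a predicate
#'   function mapping a label vector to a logical vector.
#' @return the restricted `ncc_cohort`.
#' @export
restrict_genotype_subset <- function(cohort, keep) {
  stopifnot(inherits(cohort, "ncc_cohort"))
  df <- as.data.frame(cohort)
  if (!("genotype_label" %in% names(df))) {
    stop("cohort has no genotype_label column", call. = FALSE)
  }
  ok <- if (is.function(keep)) keep(df$genotype_label)
        else df$genotype_label %in% keep
  ok[is.na(ok)] <- FALSE
  sel <- df$genotype == 1L | ok
  if (!any(df$genotype == 0L & sel)) {
    stop("genotype-subset restriction removes every G=0 person",
         call. = FALSE)
  }
  ncc_cohort(df[sel, , drop = FALSE], outcome_kind = outcome_kind(cohort),
             max_visits = max_visits(cohort),
             covariates = covariate_names(cohort))
}

#' Baseline characteristics by analysis group
#'
#' Summarises baseline covariates per group A-D using one baseline row per
#' person per period (covariates are constant within a person-period, so
#' the first record of each person-period carries the baseline value). A
#' covariate whose observed values are all in \{0, 1\} is treated as
#' binary and summarised as count (%); other covariates are summarised as
#' mean (SD). The SD of a single observation is reported as `NA`
#' (undefined); empty groups are reported with zero persons.
#'
#' @param cohort an `ncc_cohort`.
#' @param covariates character vector of covariate names to summarise;
#'   defaults to all covariates carried by the cohort.
#' @return a data.frame with one row per (group, covariate) plus one
#'   `n_persons` row per group; columns `group`, `variable`, `n`, `mean`,
#'   `sd`, `count`, `percent`.
#' @export
summarize_baseline <- function(cohort, covariates = covariate_names(cohort)) {
  stopifnot(inherits(cohort, "ncc_cohort"))
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0L) {
    stop("covariate(s) not present in cohort: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(cohort)
  df$group <- assign_group(df$genotype, df$period)
  # one baseline row per person-period
  pp <- paste(df$person_id, df$period, sep = "\r")
  base <- df[!duplicated(pp), , drop = FALSE]
  rows <- list()
  for (g in c("A", "B", "C", "D")) {
    bg <- base[base$group == g, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, variable = "n_persons", n = nrow(bg),
      mean = NA_real_, sd = NA_real_, count = NA_real_,
      percent = NA_real_, stringsAsFactors = FALSE)
    for (cv in covariates) {
      v <- bg[[cv]]
      v <- v[!is.na(v)]
      is_binary <- length(v) > 0L && all(v %in% c(0, 1))
      if (is_binary) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, variable = cv, n = length(v),
          mean = NA_real_, sd = NA_real_, count = sum(v),
          percent = if (length(v) > 0L) 100 * mean(v) else NA_real_,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, variable = cv, n = length(v),
          mean = if (length(v) > 0L) mean(v) else NA_real_,
          sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
          count = NA_real_, percent = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
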