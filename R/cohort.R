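#' Two-genotype, two-period longitudinal cohort
#'
#' Construct a validated cohort object from long-format person-visit data.
#' Each row is one annual review visit for one person in one calendar
#' period: `genotype` is 1 for the treatment-eligible genotype and 0
#' otherwise, `period` is 1 for the post-introduction period and 0 for the
#' pre-introduction period, and `visit` is the 0-based annual visit index
#' within the period. A person may contribute rows to both periods; the
#' pair (genotype, period) places every row in exactly one of the four
#' analysis groups A-D (see [assign_group()]).
#'
#' Baseline covariates are measured in the year before visit 0 of each
#' period, so they are constant across a person's visits within a period
#' but may differ between that person's two periods.
#'
#' @param data data.frame with columns `person_id`, `genotype`, `period`,
#'   `visit`, `outcome`, optionally `genotype_label` (free-text auxiliary
#'   genotype annotation used by [restrict_genotype_subset()]), plus any
#'   covariate columns named in `covariates`.
#' @param outcome_kind `"continuous"` (e.g. ppFEV1, percentage points) or
#'   `"count"` (nonnegative integers, e.g. annual IV-antibiotic days).
#' @param max_visits maximum number of annual visits per period (J);
#'   `visit` must lie in `0:(max_visits - 1)`.
#' @param covariates character vector naming the baseline covariate
#'   columns carried by the cohort (may be empty).
#' @param validate set to `FALSE` to skip invariant checks (internal use,
#'   e.g. inside bootstrap resampling where invariants hold by
#'   construction).
#'
#' @return An object of class `ncc_cohort`: the (column-standardised)
#'   data.frame with attributes `outcome_kind`, `max_visits` and
#'   `covariates`.
#' @seealso [read_long_table()], [build_contrast()], [simulate_cohort()]
#' @export
#' @examples
#' df <- data.frame(person_id = c("a", "a", "b"),
#'                  genotype = c(1, 1, 0), period = c(0, 1, 0),
#'                  visit = c(0, 0, 0), outcome = c(71, 78, 70))
#' coh <- ncc_cohort(df)
#' coh
ncc_cohort <- function(data, outcome_kind = c("continuous", "count"),
                       max_visits = 4L, covariates = character(),
                       validate = TRUE) {
  outcome_kind <- match.arg(outcome_kind)
  stopifnot(is.data.frame(data))
  core <- c("person_id", "genotype", "period", "visit", "outcome")
  missing_cols <- setdiff(c(core, covariates), names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- c(core,
            if ("genotype_label" %in% names(data)) "genotype_label",
            covariates)
  data <- as.data.frame(data)[keep]
  data$person_id <- as.character(data$person_id)
  data$genotype <- as.integer(data$genotype)
  data$period <- as.integer(data$period)
  data$visit <- as.integer(data$visit)
  data$outcome <- as.numeric(data$outcome)
  rownames(data) <- NULL
  obj <- structure(data,
                   outcome_kind = outcome_kind,
                   max_visits = as.integer(max_visits),
                   covariates = covariates,
                   class = c("ncc_cohort", "data.frame"))
  if (validate) validate_cohort(obj)
  obj
}

#' Validate cohort invariants
#'
#' Checks the structural invariants of an [ncc_cohort()]: binary genotype
#' and period, visit index within range, no duplicate
#' (person, period, visit) rows, count outcomes nonnegative integers, and
#' covariates constant within (person, period). Errors name the first
#' offending row.
#'
#' @param x an `ncc_cohort`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "ncc_cohort"))
  df <- as.data.frame(x)
  bad <- which(!(df$genotype %in% c(0L, 1L)) | is.na(df$genotype))
  if (length(bad) > 0L) {
    stop("genotype must be 0 or 1; first violation at row ", bad[1L],
         " (value ", df$genotype[bad[1L]], ")", call. = FALSE)
  }
  bad <- which(!(df$period %in% c(0L, 1L)) | is.na(df$period))
  if (length(bad) > 0L) {
    stop("period must be 0 or 1; first violation at row ", bad[1L],
         " (value ", df$period[bad[1L]], ")", call. = FALSE)
  }
  J <- max_visits(x)
  bad <- which(is.na(df$visit) | df$visit < 0L | df$visit >= J)
  if (length(bad) > 0L) {
    stop("visit must lie in 0:", J - 1L, "; first violation at row ",
         bad[1L], " (value ", df$visit[bad[1L]], ")", call. = FALSE)
  }
  key <- paste(df$person_id, df$period, df$visit, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate (person_id, period, visit) at row ", dup[1L], " (",
         df$person_id[dup[1L]], ", period ", df$period[dup[1L]],
         ", visit ", df$visit[dup[1L]], ")", call. = FALSE)
  }
  if (outcome_kind(x) == "count") {
    y <- df$outcome
    bad <- which(!is.na(y) & (y < 0 | y != round(y)))
    if (length(bad) > 0L) {
      stop("count outcomes must be nonnegative integers; first violation ",
           "at row ", bad[1L], " (value ", y[bad[1L]], ")", call. = FALSE)
    }
  }
  for (cv in covariate_names(x)) {
    pp <- paste(df$person_id, df$period, sep = "\r")
    vals <- df[[cv]]
    n_distinct <- tapply(vals, pp, function(v) length(unique(v)))
    if (any(n_distinct > 1L)) {
      stop("covariate '", cv, "' is not constant within (person, period); ",
           "first violation for ", names(which(n_distinct > 1L))[1L],
           call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.ncc_cohort <- function(x, ...) {
  df <- as.data.frame(x)
  grp <- assign_group(df$genotype, df$period)
  npp <- tapply(df$person_id, grp, function(p) length(unique(p)))
  npp[is.na(npp)] <- 0L
  cat("<ncc_cohort> ", length(unique(df$person_id)), " persons, ",
      nrow(df), " person-visit records (", outcome_kind(x),
      " outcome, J = ", max_visits(x), ")\n", sep = "")
  for (g in c("A", "B", "C", "D")) {
    n <- sum(grp == g)
    cat("  group ", g, ": ",
        if (g %in% names(npp)) npp[[g]] else 0L, " persons, ",
        n, " records\n", sep = "")
  }
  if (length(covariate_names(x)) > 0L) {
    cat("  covariates:", paste(covariate_names(x), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cohort accessors
#'
#' @param x an `ncc_cohort` or `ncc_analysis_set`.
#' @return `outcome_kind()` the outcome kind string; `max_visits()` the
#'   visit count J; `covariate_names()` the covariate column names;
#'   `n_persons()` the number of distinct persons.
#' @export
outcome_kind <- function(x) attr(x, "outcome_kind")

#' @rdname outcome_kind
#' @export
max_visits <- function(x) attr(x, "max_visits")

#' @rdname outcome_kind
#' @export
covariate_names <- function(x) attr(x, "covariates")

#' @rdname outcome_kind
#' @export
n_persons <- function(x) length(unique(x$person_id))

#' Map genotype and period to the analysis group A-D
#'
#' The four groups partition the cohort: A is the eligible genotype before
#' treatment introduction (P = 0, G = 1), B the eligible genotype after
#' (P = 1, G = 1; the only treated group), C the ineligible genotype
#' before (P = 0, G = 0) and D the ineligible genotype after
#' (P = 1, G = 0).
#'
#' @param genotype 0/1 vector. @param period 0/1 vector.
#' @return character vector of group labels `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
#' @examples
#' assign_group(genotype = c(1, 1, 0, 0), period = c(0, 1, 0, 1)) # A B C D
assign_group <- function(genotype, period) {
  if (any(!(genotype %in% c(0, 1))) || any(!(period %in% c(0, 1)))) {
    stop("genotype and period must both be 0 or 1", call. = FALSE)
  }
  c("C", "A", "D", "B")[1L + genotype + 2L * period]
}
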