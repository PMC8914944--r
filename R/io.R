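#' Read a long-format cohort table
#'
#' Reads a delimited text file (CSV, or TSV when the extension is `.tsv`
#' or `.txt`) with one row per person-visit into an [ncc_cohort()]. Rows
#' with a missing outcome are dropped with a message reporting the count;
#' rows violating the cohort invariants raise an error naming the row.
#' Missing values are encoded as empty fields.
#'
#' @param path file to read.
#' @param schema named list mapping roles to column names in the file:
#'   `person_id`, `genotype`, `period`, `visit`, `outcome` (all required),
#'   plus optional `covariates` (character vector) and `genotype_label`
#'   (single column name). Roles omitted from `schema` default to the
#'   role name itself; a `genotype_label` column in the file is carried
#'   automatically when present.
#' @param outcome_kind,max_visits passed to [ncc_cohort()].
#' @return an `ncc_cohort`.
#' @export
read_long_table <- function(path, schema = list(),
                            outcome_kind = c("continuous", "count"),
                            max_visits = 4L) {
  outcome_kind <- match.arg(outcome_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sch <- list(person_id = "person_id", genotype = "genotype",
              period = "period", visit = "visit", outcome = "outcome",
              covariates = character(), genotype_label = NULL)
  unknown <- setdiff(names(schema), names(sch))
  if (length(unknown) > 0L) {
    stop("unknown schema role(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sch[names(schema)] <- schema
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.csv(path, sep = sep, na.strings = "",
                         check.names = FALSE, stringsAsFactors = FALSE)
  # a genotype_label column is carried automatically when present
  if (is.null(sch$genotype_label) && "genotype_label" %in% names(raw)) {
    sch$genotype_label <- "genotype_label"
  }
  need <- c(unlist(sch[c("person_id", "genotype", "period", "visit",
                         "outcome")]),
            sch$covariates, sch$genotype_label)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("input file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(person_id = raw[[sch$person_id]],
                   genotype = raw[[sch$genotype]],
                   period = raw[[sch$period]],
                   visit = raw[[sch$visit]],
                   outcome = raw[[sch$outcome]],
                   stringsAsFactors = FALSE)
  if (!is.null(sch$genotype_label)) {
    df$genotype_label <- as.character(raw[[sch$genotype_label]])
  }
  for (cv in sch$covariates) df[[cv]] <- raw[[cv]]
  n_missing <- sum(is.na(df$outcome))
  if (n_missing > 0L) {
    message("dropped ", n_missing, " row(s) with missing outcome")
    df <- df[!is.na(df$outcome), , drop = FALSE]
  }
  ncc_cohort(df, outcome_kind = outcome_kind, max_visits = max_visits,
             covariates = sch$covariates)
}

#' Write a cohort to a long-format CSV
#'
#' Writes the cohort with a deterministic column order (`person_id`,
#' `genotype`, `period`, `visit`, `outcome`, then `genotype_label` if
#' present, then covariates in their declared order) and row order
#' (person_id, period, visit). Numeric fields are written with 17
#' significant digits so that a write/read round trip is lossless; missing
#' values are written as empty fields.
#'
#' @param cohort an `ncc_cohort`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "ncc_cohort"))
  df <- as.data.frame(cohort)
  if (nrow(df) > 0L) {
    df <- df[order(df$person_id, df$period, df$visit), , drop = FALSE]
  }
  out <- df
  for (nm in names(out)) {
    v <- out[[nm]]
    if (is.double(v)) {
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[nm]] <- s
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", na = "", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
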