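## Subject-level cohort tables: validation and delimited-text I/O.
##
## A cohort table is a plain data.frame with one row per subject, a binary
## outcome column coded strictly 0/1, and numeric covariate columns.  More
## than one outcome column may be present (e.g. the same cohort observed at
## several outcome incidences); estimator functions select one by name.

#' Validate a subject-level cohort table
#'
#' Checks the contract every estimator in the package relies on: the table
#' has at least one row, the named outcome column exists and contains only
#' 0 or 1 (no missing values), and the requested covariate columns exist,
#' are numeric and complete.  Missing covariate values are rejected rather
#' than imputed.
#'
#' @param table data.frame with one row per subject.
#' @param outcome name of the binary outcome column.
#' @param covariates optional character vector of covariate columns to
#'   check; defaults to all non-outcome columns.
#' @return `table`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_cohort <- function(table, outcome, covariates = NULL) {
  if (!is.data.frame(table))
    stop_validation("cohort table must be a data.frame")
  if (nrow(table) < 1L)
    stop_validation("cohort table must contain at least one subject")
  if (!is.character(outcome) || length(outcome) != 1L)
    stop_validation("'outcome' must be a single column name")
  if (!outcome %in% names(table))
    stop_io("outcome column '", outcome, "' not found in table")
  y <- table[[outcome]]
  bad <- which(is.na(y) | !(y %in% c(0, 1)))
  if (length(bad))
    stop_validation("outcome column '", outcome,
                    "' must be coded 0/1; offending row(s): ",
                    paste(utils::head(bad, 5L), collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(table), c(outcome, ".provenance"))
  missing_cols <- setdiff(covariates, names(table))
  if (length(missing_cols))
    stop_validation("covariate column(s) not found: ",
                    paste(missing_cols, collapse = ", "))
  for (v in covariates) {
    x <- table[[v]]
    if (!is.numeric(x))
      stop_validation("covariate '", v, "' must be numeric")
    if (anyNA(x))
      stop_validation("covariate '", v, "' contains missing values")
  }
  invisible(table)
}

#' Read a subject-level cohort from delimited text
#'
#' Reads a header-ed CSV (or other single-character-delimited) file into a
#' cohort table and validates it.  The outcome column must contain only the
#' tokens 0 and 1; values such as "yes"/"no" are refused rather than
#' guessed at.
#'
#' @param path file to read.
#' @param outcome name of the binary outcome column.
#' @param delimiter field separator, default comma; use `"\t"` for TSV.
#' @return a validated data.frame (one row per subject).
#' @seealso [write_cohort()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_cohort(data.frame(y = c(0, 1, 1), A = c(0, 1, 0)), tf)
#' read_cohort(tf, outcome = "y")
read_cohort <- function(path, outcome, delimiter = ",") {
  if (!file.exists(path))
    stop_io("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(tab, outcome)
  tab
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: writes a header row followed by one line per
#' subject.  Numeric values are written as plain tokens so a round trip
#' through `write_cohort()` and `read_cohort()` reproduces the table.
#'
#' @param table cohort data.frame.
#' @param path destination file.
#' @param outcome outcome column used for validation before writing;
#'   defaults to the first column.
#' @param delimiter field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, outcome = names(table)[1L],
                         delimiter = ",") {
  validate_cohort(table, outcome)
  if (ncol(table) < 2L)
    stop_validation("cohort table must have at least one covariate column")
  ok <- tryCatch({
    utils::write.table(table, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_io("could not write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Cross-tabulate a binary covariate against the outcome
#'
#' Collapses a cohort to the exposed/unexposed by case/non-case 2x2 table
#' used by the closed-form estimators.
#'
#' @param table cohort data.frame.
#' @param covariate name of a binary 0/1 covariate column.
#' @param outcome name of the binary outcome column.
#' @return a [two_by_two()] object with counts `a1` (exposed cases), `b1`
#'   (exposed non-cases), `a0` (unexposed cases), `b0` (unexposed
#'   non-cases).
#' @export
#' @examples
#' ref <- build_reference_cohort()
#' cross_tabulate(ref, "A", "y50")   # 409 / 191 / 91 / 309
cross_tabulate <- function(table, covariate, outcome) {
  validate_cohort(table, outcome, covariates = covariate)
  x <- table[[covariate]]
  if (!all(x %in% c(0, 1)))
    stop_validation("covariate '", covariate,
                    "' is not binary 0/1; cannot cross-tabulate")
  y <- table[[outcome]]
  two_by_two(a1 = sum(x == 1 & y == 1), b1 = sum(x == 1 & y == 0),
             a0 = sum(x == 0 & y == 1), b0 = sum(x == 0 & y == 0))
}
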