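## The provisional duplicated dataset: the core trick of the method.

#' Duplicate all cases as relabelled non-cases
#'
#' Builds the provisional dataset in which every case row appears a second
#' time with the outcome relabelled to non-case and all covariates
#' unchanged.  Within any covariate pattern of the result, the odds of
#' being a case equal the risk of the outcome in the original data — so an
#' ordinary logistic regression fitted to the duplicated data estimates
#' log relative risks.
#'
#' Row order is the original rows in input order followed by the duplicate
#' rows in case order.  A `.provenance` column ("original"/"duplicate")
#' records which is which, and the result carries attributes `n_original`
#' and `n_cases`.  The transform refuses an already-duplicated table: a
#' second application would duplicate cases again and break the odds-equal-
#' risk identity.
#'
#' @param table cohort data.frame (one row per subject).
#' @param outcome name of the binary outcome column to duplicate on.
#' @return a data.frame of class `duplicated_cohort` with
#'   `nrow(table) + sum(cases)` rows.
#' @seealso [estimate_rr_duplicated()], which composes this transform with
#'   [fit_logistic()].
#' @export
#' @examples
#' ref <- build_reference_cohort()
#' dup <- duplicate_cases(ref, "y50")
#' nrow(dup)            # 1500: 1000 originals + 500 duplicated cases
#' sum(dup$y50)         # still 500 cases
duplicate_cases <- function(table, outcome) {
  if (inherits(table, "duplicated_cohort") || ".provenance" %in% names(table))
    stop_validation("input already contains duplicated cases; ",
                    "applying the transform twice is not meaningful")
  validate_cohort(table, outcome)
  cases <- table[table[[outcome]] == 1, , drop = FALSE]
  dups <- cases
  if (nrow(dups)) dups[[outcome]] <- 0
  out <- rbind(table, dups)
  out$.provenance <- rep(c("original", "duplicate"),
                         c(nrow(table), nrow(dups)))
  rownames(out) <- NULL
  attr(out, "n_original") <- nrow(table)
  attr(out, "n_cases") <- nrow(cases)
  class(out) <- c("duplicated_cohort", "data.frame")
  out
}
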