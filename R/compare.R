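## Method-comparison grids: all four estimators over predictors x
## outcomes, unadjusted and adjusted, plus SE inflation factors.

estimator_set <- c("log_binomial", "logistic", "cox_constant_robust",
                   "duplicated_logistic")

fit_one <- function(table, outcome, covariates, estimator, ci_level) {
  spec <- model_spec(outcome, covariates, estimator = estimator,
                     ci_level = ci_level)
  switch(estimator,
         logistic = fit_logistic(table, spec),
         log_binomial = fit_log_binomial(table, spec),
         cox_constant_robust = fit_cox_constant(table, spec),
         duplicated_logistic = estimate_rr_duplicated(table, spec))
}

#' Run all estimators over predictors and outcomes
#'
#' For each outcome and predictor, fits every estimator twice: unadjusted
#' (the predictor alone) and adjusted (all predictors together — always
#' the full list, no model selection).  The Cox estimator reports robust
#' standard errors; the duplicated-logistic estimator reports model-based
#' ones, which is how each is meant to be used.  Individual estimator
#' failures are recorded in their cells and never abort the grid.
#' Standard-error inflation factors (duplicated-method SE over log-binomial
#' SE, unadjusted) are computed wherever both fits converged.
#'
#' @param table cohort data.frame containing all predictor and outcome
#'   columns.
#' @param predictors character vector of predictor columns.
#' @param outcomes character vector of outcome columns (e.g. the same
#'   cohort at several outcome incidences).
#' @param ci_level two-sided confidence level, default 0.95.
#' @param estimators subset of the four estimators to run.
#' @return an object of class `rr_comparison`: a `cells` data.frame (one
#'   row per outcome x predictor x adjustment x estimator, with effect, CI
#'   bounds, SE, convergence flag and note), an `inflation` data.frame
#'   (one row per outcome x predictor), and metadata.
#' @export
#' @examples
#' ref <- build_reference_cohort()
#' cmp <- compare_methods(ref, c("A", "B", "C"), c("y50", "y20", "y5"))
#' subset(cmp$cells, outcome == "y50" & adjustment == "unadjusted")
compare_methods <- function(table, predictors, outcomes, ci_level = 0.95,
                            estimators = estimator_set) {
  estimators <- match.arg(estimators, estimator_set, several.ok = TRUE)
  for (oc in outcomes) validate_cohort(table, oc, predictors)
  cells <- list()
  add_cell <- function(outcome, predictor, adjustment, estimator, fit) {
    if (inherits(fit, "error")) {
      row <- data.frame(outcome = outcome, predictor = predictor,
                        adjustment = adjustment, estimator = estimator,
                        effect = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, se = NA_real_,
                        converged = FALSE,
                        note = conditionMessage(fit),
                        stringsAsFactors = FALSE)
    } else {
      est <- fit$estimates[fit$estimates$term == predictor, ]
      row <- data.frame(outcome = outcome, predictor = predictor,
                        adjustment = adjustment, estimator = estimator,
                        effect = est$effect, ci_low = est$ci_low,
                        ci_high = est$ci_high, se = est$se,
                        converged = fit$converged,
                        note = if (length(fit$notes))
                          paste(fit$notes, collapse = "; ") else "",
                        stringsAsFactors = FALSE)
    }
    cells[[length(cells) + 1L]] <<- row
  }
  for (oc in outcomes) {
    for (est in estimators) {
      for (pr in predictors) {
        fit <- tryCatch(fit_one(table, oc, pr, est, ci_level),
                        error = function(e) e)
        add_cell(oc, pr, "unadjusted", est, fit)
      }
      if (length(predictors) > 1L) {
        fit <- tryCatch(fit_one(table, oc, predictors, est, ci_level),
                        error = function(e) e)
        for (pr in predictors) add_cell(oc, pr, "adjusted", est, fit)
      } else {
        fit <- tryCatch(fit_one(table, oc, predictors, est, ci_level),
                        error = function(e) e)
        add_cell(oc, predictors, "adjusted", est, fit)
      }
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  infl <- list()
  for (oc in outcomes) {
    for (pr in predictors) {
      pick <- function(est) cells[cells$outcome == oc &
                                    cells$predictor == pr &
                                    cells$adjustment == "unadjusted" &
                                    cells$estimator == est, ]
      dup <- pick("duplicated_logistic")
      lb <- pick("log_binomial")
      if (nrow(dup) && nrow(lb) && isTRUE(dup$converged) &&
          isTRUE(lb$converged)) {
        infl[[length(infl) + 1L]] <-
          data.frame(outcome = oc, predictor = pr,
                     incidence = mean(table[[oc]]),
                     inflation = inflation_factor(dup$se, lb$se),
                     stringsAsFactors = FALSE)
      }
    }
  }
  infl <- if (length(infl)) do.call(rbind, infl) else
    data.frame(outcome = character(), predictor = character(),
               incidence = numeric(), inflation = numeric())
  rownames(infl) <- NULL
  structure(list(cells = cells, inflation = infl,
                 meta = list(n = nrow(table),
                             cases = vapply(outcomes, function(oc)
                               sum(table[[oc]] == 1), numeric(1)),
                             ci_level = ci_level)),
            class = "rr_comparison")
}

#' Standard-error inflation profile
#'
#' One row per predictor and outcome with the ratio of the
#' duplicated-method (unadjusted) standard error to the log-binomial one.
#' Across outcomes of increasing incidence the factor rises: the rarer the
#' outcome, the smaller the precision cost of duplicating the cases.
#'
#' @param report an `rr_comparison` from [compare_methods()].
#' @return data.frame with columns `predictor`, `outcome`, `incidence`,
#'   `inflation`, ordered by predictor then incidence.
#' @export
inflation_profile <- function(report) {
  stopifnot(inherits(report, "rr_comparison"))
  out <- report$inflation[, c("predictor", "outcome", "incidence",
                              "inflation")]
  out[order(out$predictor, out$incidence), , drop = FALSE]
}

#' Serialize a comparison report
#'
#' `format = "csv"` gives one machine-readable row per cell (effects at
#' full precision); `format = "text"` gives an aligned human-readable
#' table with effects and CI bounds rounded to `digits` decimals.
#' Rounding happens only at render time.
#'
#' @param report an `rr_comparison`.
#' @param format `"csv"` or `"text"`.
#' @param path optional file to write to.
#' @param digits decimals for the text rendering, default 2.
#' @return character vector of output lines, invisibly if `path` is given.
#' @export
render_report <- function(report, format = c("csv", "text"), path = NULL,
                          digits = 2) {
  stopifnot(inherits(report, "rr_comparison"))
  format <- match.arg(format)
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(report$cells, con, row.names = FALSE)
    close(con)
    if (nrow(report$inflation)) {
      con <- textConnection("out2", "w", local = TRUE)
      utils::write.csv(report$inflation, con, row.names = FALSE)
      close(con)
      out <- c(out, "", out2)
    }
  } else {
    fmt_cell <- function(r) {
      if (is.na(r$effect)) return(sprintf("failed [%s]", r$note))
      flag <- if (isTRUE(r$converged)) "" else " (not converged)"
      sprintf("%.*f (%.*f - %.*f)%s", digits, r$effect, digits, r$ci_low,
              digits, r$ci_high, flag)
    }
    out <- character()
    for (oc in unique(report$cells$outcome)) {
      out <- c(out, sprintf("Outcome %s (n = %d, cases = %d)", oc,
                            report$meta$n, report$meta$cases[[oc]]),
               sprintf("  %-10s %-10s %-22s %-22s %-22s %-22s", "predictor",
                       "adjust", "log-binomial RR", "logistic OR",
                       "Cox robust RR", "dup. logistic RR"))
      sub <- report$cells[report$cells$outcome == oc, ]
      for (pr in unique(sub$predictor)) {
        for (adj in unique(sub$adjustment)) {
          g <- sub[sub$predictor == pr & sub$adjustment == adj, ]
          cell <- function(est) {
            r <- g[g$estimator == est, ]
            if (!nrow(r)) "-" else fmt_cell(r[1L, ])
          }
          out <- c(out, sprintf("  %-10s %-10s %-22s %-22s %-22s %-22s",
                                pr, adj, cell("log_binomial"),
                                cell("logistic"),
                                cell("cox_constant_robust"),
                                cell("duplicated_logistic")))
        }
      }
      out <- c(out, "")
    }
    if (nrow(report$inflation)) {
      out <- c(out, "SE inflation (duplicated / log-binomial, unadjusted):")
      pf <- inflation_profile(report)
      out <- c(out, sprintf("  %-10s %-8s %-10s %s", "predictor", "outcome",
                            "incidence", "factor"))
      for (i in seq_len(nrow(pf)))
        out <- c(out, sprintf("  %-10s %-8s %-10.3f %.3f", pf$predictor[i],
                              pf$outcome[i], pf$incidence[i],
                              pf$inflation[i]))
    }
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @export
print.rr_comparison <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
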