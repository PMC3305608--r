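## Exact closed-form estimators for a single 2x2 table.  These are the
## independent oracle layer: every regression engine must agree with them
## to numerical precision on single-binary-predictor data.

#' Construct a 2x2 exposure-by-outcome table
#'
#' @param a1 exposed cases.
#' @param b1 exposed non-cases.
#' @param a0 unexposed cases.
#' @param b0 unexposed non-cases.
#' @return an object of class `two_by_two` with the four counts and the arm
#'   totals `n1 = a1 + b1`, `n0 = a0 + b0`.
#' @export
two_by_two <- function(a1, b1, a0, b0) {
  counts <- c(a1 = a1, b1 = b1, a0 = a0, b0 = b0)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_validation("2x2 counts must be non-negative integers")
  out <- list(a1 = a1, b1 = b1, a0 = a0, b0 = b0,
              n1 = a1 + b1, n0 = a0 + b0)
  if (out$n1 == 0 || out$n0 == 0)
    stop_validation("both exposure arms must contain at least one subject")
  class(out) <- "two_by_two"
  out
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a1, x$b1, x$n1, x$a0, x$b0, x$n0), nrow = 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("cases", "non-cases", "total")))
  print(m)
  invisible(x)
}

#' Expand a 2x2 table to subject-level rows
#'
#' Produces the one-row-per-subject cohort whose cross-tabulation is `t`,
#' which is how the regression engines consume count data.
#'
#' @param t a [two_by_two()] object.
#' @param covariate,outcome column names for the expanded table.
#' @return data.frame with `t$n1 + t$n0` rows.
#' @export
expand_two_by_two <- function(t, covariate = "x", outcome = "y") {
  stopifnot(inherits(t, "two_by_two"))
  out <- data.frame(
    x = rep(c(1, 1, 0, 0), c(t$a1, t$b1, t$a0, t$b0)),
    y = rep(c(1, 0, 1, 0), c(t$a1, t$b1, t$a0, t$b0)))
  names(out) <- c(covariate, outcome)
  out[, c(outcome, covariate)]
}

rr_estimate <- function(effect, se, measure, conf.level) {
  ci <- wald_interval(log(effect), se, conf.level)
  structure(list(effect = effect, log_effect = log(effect), se = se,
                 conf.low = ci[[1L]], conf.high = ci[[2L]],
                 conf.level = conf.level, measure = measure),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("%s %.*f (%.0f%% CI %.*f - %.*f), SE(log) %.4f\n",
              x$measure, digits, x$effect, 100 * x$conf.level,
              digits, x$conf.low, digits, x$conf.high, x$se))
  invisible(x)
}

#' Closed-form risk ratio from a 2x2 table
#'
#' RR = (a1/n1) / (a0/n0), with the delta-method standard error of the log
#' risk ratio, `sqrt(b1/(n1*a1) + b0/(n0*a0))` — identical to the
#' model-based SE of a saturated log-binomial fit.
#'
#' @param t a [two_by_two()] object with cases in both arms.
#' @param conf.level two-sided Wald confidence level, default 0.95.
#' @return an `rr_estimate`: effect, log effect, SE and Wald CI bounds.
#' @export
#' @examples
#' risk_ratio(two_by_two(409, 191, 91, 309))  # RR 3.00
risk_ratio <- function(t, conf.level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$a1 == 0 || t$a0 == 0)
    stop_validation("risk ratio undefined: zero cases in an exposure arm")
  rr <- (t$a1 / t$n1) / (t$a0 / t$n0)
  se <- sqrt(t$b1 / (t$n1 * t$a1) + t$b0 / (t$n0 * t$a0))
  rr_estimate(rr, se, "RR", conf.level)
}

#' Closed-form odds ratio from a 2x2 table
#'
#' OR = (a1*b0)/(b1*a0) with the Woolf standard error
#' `sqrt(1/a1 + 1/b1 + 1/a0 + 1/b0)` — identical to the model-based SE of a
#' saturated logistic fit.
#'
#' @inheritParams risk_ratio
#' @return an `rr_estimate` with measure "OR".
#' @export
#' @examples
#' odds_ratio(two_by_two(398, 102, 102, 398))  # OR 15.23
odds_ratio <- function(t, conf.level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$a1 == 0 || t$b1 == 0 || t$a0 == 0 || t$b0 == 0)
    stop_validation("odds ratio undefined: zero cell in the 2x2 table")
  or <- (t$a1 * t$b0) / (t$b1 * t$a0)
  se <- sqrt(1 / t$a1 + 1 / t$b1 + 1 / t$a0 + 1 / t$b0)
  rr_estimate(or, se, "OR", conf.level)
}

#' Closed-form case-duplication estimate from a 2x2 table
#'
#' Applies the duplication bookkeeping — every case also counted once as a
#' non-case, so the non-case count of each arm becomes the arm total — and
#' returns the odds ratio of the transformed table.  The point estimate
#' equals the risk ratio exactly; the model-based standard error,
#' `sqrt(1/a1 + 1/n1 + 1/a0 + 1/n0)`, is strictly larger than the
#' log-binomial SE (the squared-SE difference is 2/n per arm), which is the
#' precision cost of the method.
#'
#' @inheritParams risk_ratio
#' @return an `rr_estimate` with measure "RR".
#' @export
#' @examples
#' duplicated_rr(two_by_two(409, 191, 91, 309))  # RR 3.00, wider CI
duplicated_rr <- function(t, conf.level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$a1 == 0 || t$a0 == 0)
    stop_validation("duplicated estimate undefined: zero cases in an arm")
  rr <- (t$a1 / t$n1) / (t$a0 / t$n0)
  se <- sqrt(1 / t$a1 + 1 / t$n1 + 1 / t$a0 + 1 / t$n0)
  rr_estimate(rr, se, "RR", conf.level)
}

#' Standard-error inflation factor
#'
#' Ratio of the standard error of a method to the standard error of
#' log-binomial regression (the reference method) for the same coefficient;
#' quantifies the precision cost of the case-duplication method.
#'
#' @param se_method SE from the method under study (log scale).
#' @param se_binomial reference SE from log-binomial regression (log scale).
#' @return `se_method / se_binomial`.
#' @export
inflation_factor <- function(se_method, se_binomial) {
  if (any(!is.finite(se_binomial)) || any(se_binomial <= 0))
    stop_validation("reference standard error must be positive")
  if (any(!is.finite(se_method)) || any(se_method < 0))
    stop_validation("method standard error must be non-negative")
  se_method / se_binomial
}
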