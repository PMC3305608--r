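## Binomial-family regression engines (logit and log links), the
## case-duplication RR estimator built on them, sandwich variances and
## Wald intervals.

#' Specify a model for the estimator functions
#'
#' Bundles the outcome, the covariates, the estimator and the variance
#' choice passed to [fit_logistic()], [fit_log_binomial()],
#' [fit_cox_constant()] and [estimate_rr_duplicated()].
#'
#' @param outcome name of the binary outcome column.
#' @param covariates non-empty character vector of covariate columns, in
#'   the order they enter the linear predictor.
#' @param estimator one of `"logistic"`, `"log_binomial"`,
#'   `"cox_constant_robust"`, `"duplicated_logistic"`.
#' @param ci_level two-sided confidence level, strictly between 0 and 1.
#' @param variance `"default"` resolves to robust for the Cox estimator and
#'   model-based for all others (the convention the method comparison
#'   uses); `"model_based"` or `"robust"` force a choice.
#' @return an object of class `rr_model_spec`.
#' @export
model_spec <- function(outcome, covariates,
                       estimator = c("logistic", "log_binomial",
                                     "cox_constant_robust",
                                     "duplicated_logistic"),
                       ci_level = 0.95,
                       variance = c("default", "model_based", "robust")) {
  estimator <- match.arg(estimator)
  variance <- match.arg(variance)
  if (!is.character(outcome) || length(outcome) != 1L)
    stop_validation("'outcome' must be a single column name")
  if (!is.character(covariates) || length(covariates) < 1L)
    stop_validation("'covariates' must name at least one column")
  if (anyDuplicated(covariates))
    stop_validation("'covariates' contains duplicated names")
  if (!is.numeric(ci_level) || length(ci_level) != 1L ||
      ci_level <= 0 || ci_level >= 1)
    stop_validation("'ci_level' must lie strictly between 0 and 1")
  structure(list(outcome = outcome, covariates = covariates,
                 estimator = estimator, ci_level = ci_level,
                 variance = variance),
            class = "rr_model_spec")
}

#' Wald confidence interval on the effect scale
#'
#' `exp(beta -/+ z * se)` with `z` the two-sided standard-normal quantile of
#' `ci_level` (1.959964 at 95%).  Vectorised over `beta` and `se`.
#'
#' @param beta log-scale effect estimate(s).
#' @param se standard error(s), non-negative.
#' @param ci_level two-sided confidence level in (0, 1).
#' @return a list with components `low` and `high` on the effect scale.
#' @export
#' @examples
#' wald_interval(log(3), 0.13267)  # approximately (2.31, 3.89)
wald_interval <- function(beta, se, ci_level = 0.95) {
  if (any(se < 0)) stop_validation("standard errors must be non-negative")
  if (ci_level <= 0 || ci_level >= 1)
    stop_validation("'ci_level' must lie strictly between 0 and 1")
  z <- qnorm((1 + ci_level) / 2)
  list(low = exp(beta - z * se), high = exp(beta + z * se))
}

## Fit a binomial-family GLM, capturing warnings and convergence trouble
## instead of letting them escape.  For the log link the starting values
## are intercept = log(overall risk), slopes = 0, the standard remedy for
## the boundary problem; glm's internal step-halving keeps iterates inside
## the parameter space.
fit_binomial_glm <- function(table, outcome, covariates, link) {
  validate_cohort(table, outcome, covariates)
  dat <- table[, c(outcome, covariates), drop = FALSE]
  fml <- as.formula(paste0("`", outcome, "` ~ ",
                           paste0("`", covariates, "`", collapse = " + ")))
  start <- NULL
  if (link == "log")
    start <- c(log(mean(dat[[outcome]])), rep(0, length(covariates)))
  msgs <- character()
  fit <- withCallingHandlers(
    tryCatch(
      glm(fml, family = binomial(link = link), data = dat, start = start,
          control = glm.control(epsilon = 1e-14, maxit = 100L)),
      error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error"))
    return(list(glm = NULL, converged = FALSE, boundary = FALSE,
                messages = c(msgs, conditionMessage(fit))))
  if (anyNA(coef(fit)))
    stop_validation("design matrix is rank deficient: ",
                    paste(names(coef(fit))[is.na(coef(fit))],
                          collapse = ", "))
  boundary <- isTRUE(fit$boundary) ||
    (link == "log" && max(fitted(fit)) >= 1 - 1e-8)
  separated <- link == "logit" &&
    (max(abs(coef(fit)[-1L])) > 20 ||
       any(grepl("numerically 0 or 1 occurred", msgs)))
  converged <- isTRUE(fit$converged) && !separated &&
    !(link == "log" && boundary)
  if (separated)
    msgs <- c(msgs, "possible separation: diverging coefficients")
  list(glm = fit, converged = converged, boundary = boundary,
       messages = msgs)
}

## Model-based covariance evaluated at the final coefficients.  glm's own
## vcov() uses the IRLS weights of the penultimate iterate, which lags the
## coefficients by one Newton step; recomputing the expected information at
## the solution removes that lag so saturated fits match the closed-form
## SEs to full precision.
model_vcov_glm <- function(fit) {
  X <- model.matrix(fit)
  mu <- fitted(fit)
  w <- switch(fit$family$link,
              logit = mu * (1 - mu),
              log = mu / pmax(1 - mu, .Machine$double.eps))
  V <- tryCatch(solve(crossprod(X * sqrt(w))),
                error = function(e) vcov(fit))  # boundary fits: fall back
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

make_rr_fit <- function(state, spec, measure, estimator, n, n_cases,
                        extra = list()) {
  fit <- state$glm
  if (is.null(fit)) {
    terms <- data.frame(term = spec$covariates, beta = NA_real_,
                        se = NA_real_, effect = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE)
    res <- list(estimates = terms, intercept = NA_real_, vcov = NULL,
                measure = measure, estimator = estimator,
                variance = "model_based", ci_level = spec$ci_level,
                converged = FALSE, boundary = state$boundary,
                n_iterations = NA_integer_, n = n, n_cases = n_cases,
                notes = state$messages, glm = NULL)
    return(structure(c(res, extra), class = "rr_fit"))
  }
  variance <- if (spec$variance == "default") "model_based" else spec$variance
  V <- if (variance == "robust") sandwich_vcov(fit) else model_vcov_glm(fit)
  beta <- coef(fit)
  idx <- match(paste0("`", spec$covariates, "`"), names(beta))
  idx[is.na(idx)] <- match(spec$covariates, names(beta))[is.na(idx)]
  se <- sqrt(diag(V))[idx]
  ci <- wald_interval(beta[idx], se, spec$ci_level)
  terms <- data.frame(term = spec$covariates, beta = unname(beta[idx]),
                      se = unname(se), effect = unname(exp(beta[idx])),
                      ci_low = unname(ci$low), ci_high = unname(ci$high),
                      stringsAsFactors = FALSE)
  res <- list(estimates = terms, intercept = unname(beta[1L]), vcov = V,
              measure = measure, estimator = estimator, variance = variance,
              ci_level = spec$ci_level, converged = state$converged,
              boundary = state$boundary, n_iterations = fit$iter,
              n = n, n_cases = n_cases, notes = state$messages, glm = fit)
  structure(c(res, extra), class = "rr_fit")
}

#' Ordinary logistic regression
#'
#' Maximum-likelihood logistic fit; exponentiated coefficients are odds
#' ratios.  Apparent separation (diverging coefficients) is reported as
#' non-convergence with a diagnostic note rather than silently returning
#' huge estimates.
#'
#' @param table cohort data.frame (or a duplicated table, in which case the
#'   odds ratios are the case-duplication RR estimates).
#' @param spec an [model_spec()]; its `variance` choice selects model-based
#'   (default) or HC0 sandwich standard errors.
#' @return an object of class `rr_fit`: a per-covariate table of log
#'   effects, SEs, exponentiated effects and Wald CI bounds, plus the
#'   intercept and convergence diagnostics.
#' @export
#' @examples
#' d <- expand_two_by_two(two_by_two(409, 191, 91, 309))
#' fit_logistic(d, model_spec("y", "x"))  # OR 7.27 (5.44 - 9.72)
fit_logistic <- function(table, spec) {
  stopifnot(inherits(spec, "rr_model_spec"))
  state <- fit_binomial_glm(table, spec$outcome, spec$covariates, "logit")
  make_rr_fit(state, spec, measure = "OR", estimator = "logistic",
              n = nrow(table), n_cases = sum(table[[spec$outcome]] == 1))
}

#' Log-binomial regression
#'
#' Binomial-family fit with log link; exponentiated coefficients are
#' relative risks (prevalence ratios for cross-sectional data).  Because
#' fitted probabilities must stay below 1, the likelihood can have its
#' maximum on the boundary of the parameter space and the fit may fail to
#' converge; such fits are returned with `converged = FALSE` and the last
#' iterate rather than being silently repaired.
#'
#' @inheritParams fit_logistic
#' @return an `rr_fit` with measure "RR".
#' @export
#' @examples
#' d <- expand_two_by_two(two_by_two(398, 102, 102, 398))
#' fit_log_binomial(d, model_spec("y", "x"))  # RR 3.90 (3.26 - 4.67)
fit_log_binomial <- function(table, spec) {
  stopifnot(inherits(spec, "rr_model_spec"))
  state <- fit_binomial_glm(table, spec$outcome, spec$covariates, "log")
  make_rr_fit(state, spec, measure = "RR", estimator = "log_binomial",
              n = nrow(table), n_cases = sum(table[[spec$outcome]] == 1))
}

#' Relative risk by case-duplication logistic regression
#'
#' The method this package exists for: composes [duplicate_cases()] with
#' [fit_logistic()].  On the duplicated data the stratum odds of being a
#' case equal the original risk, so the exponentiated logistic coefficients
#' are direct relative-risk estimates.  Standard errors are the ordinary
#' model-based logistic SEs from the duplicated fit; they are inflated
#' relative to log-binomial regression because every case is counted twice,
#' which is the price of the method (see [inflation_factor()]).
#'
#' @param table an original (non-duplicated) cohort data.frame.
#' @param spec an [model_spec()].  Variance is always model-based: the
#'   method as formulated does not correct for the case/duplicate pairing.
#' @return an `rr_fit` with measure "RR" and attributes `n_original` and
#'   `n_after_duplication` recorded as list components.
#' @export
#' @examples
#' d <- expand_two_by_two(two_by_two(409, 191, 91, 309))
#' estimate_rr_duplicated(d, model_spec("y", "x"))  # RR 3.00 (2.31 - 3.89)
estimate_rr_duplicated <- function(table, spec) {
  stopifnot(inherits(spec, "rr_model_spec"))
  if (inherits(table, "duplicated_cohort") ||
      ".provenance" %in% names(table))
    stop_validation("'table' is already duplicated; pass the original ",
                    "cohort")
  dup <- duplicate_cases(table, spec$outcome)
  spec2 <- spec
  spec2$variance <- "model_based"
  state <- fit_binomial_glm(dup, spec$outcome, spec$covariates, "logit")
  make_rr_fit(state, spec2, measure = "RR",
              estimator = "duplicated_logistic",
              n = nrow(dup), n_cases = attr(dup, "n_cases"),
              extra = list(n_original = attr(dup, "n_original"),
                           n_after_duplication = nrow(dup)))
}

#' Huber-White sandwich covariance for a binomial GLM
#'
#' Information-sandwich (HC0) covariance: bread = inverse observed
#' information, meat = sum of outer products of per-subject score
#' contributions.  `df_correction = TRUE` applies the n/(n-p) small-sample
#' multiplier (HC1); the default matches the plain robust option.
#'
#' @param fit a fitted `glm` object, or an `rr_fit` carrying one.
#' @param df_correction apply the HC1 degrees-of-freedom correction?
#' @return covariance matrix of the coefficient vector.
#' @export
sandwich_vcov <- function(fit, df_correction = FALSE) {
  if (inherits(fit, "rr_fit")) {
    if (is.null(fit$glm))
      stop_validation("fit did not converge; no covariance available")
    fit <- fit$glm
  }
  stopifnot(inherits(fit, "glm"))
  sandwich::vcovHC(fit, type = if (df_correction) "HC1" else "HC0")
}

#' @export
print.rr_fit <- function(x, digits = 2, ...) {
  lab <- c(logistic = "Ordinary logistic regression",
           log_binomial = "Log-binomial regression",
           duplicated_logistic = "Case-duplication logistic regression",
           cox_constant_robust = "Cox regression, constant time")
  cat(lab[[x$estimator]], sprintf("(n = %d, cases = %d)\n", x$n, x$n_cases))
  if (x$estimator == "duplicated_logistic")
    cat(sprintf("  duplicated rows: %d original -> %d analysed\n",
                x$n_original, x$n_after_duplication))
  if (!x$converged)
    cat("  ** did not converge:", paste(x$notes, collapse = "; "), "\n")
  est <- x$estimates
  cat(sprintf("  %-12s %s (%.0f%% CI), %s variance\n", "term", x$measure,
              100 * x$ci_level, x$variance))
  for (i in seq_len(nrow(est)))
    cat(sprintf("  %-12s %.*f (%.*f - %.*f)  SE(log) %.4f\n",
                est$term[i], digits, est$effect[i], digits, est$ci_low[i],
                digits, est$ci_high[i], est$se[i]))
  invisible(x)
}

#' @export
coef.rr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$term)
}
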