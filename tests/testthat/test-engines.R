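test_that("engines agree with the closed-form oracle on 2x2 data", {
  set.seed(202)
  for (i in 1:25) {
    cc <- sample(1:40, 4, replace = TRUE)
    t <- two_by_two(cc[1], cc[2], cc[3], cc[4])
    d <- expand_two_by_two(t)
    spec <- model_spec("y", "x")

    or <- odds_ratio(t)
    f <- fit_logistic(d, spec)
    expect_equal(f$estimates$beta, or$log_effect, tolerance = 1e-8)
    expect_equal(f$estimates$se, or$se, tolerance = 1e-8)

    rr <- risk_ratio(t)
    f <- fit_log_binomial(d, spec)
    expect_equal(f$estimates$beta, rr$log_effect, tolerance = 1e-8)
    expect_equal(f$estimates$se, rr$se, tolerance = 1e-8)

    dup <- duplicated_rr(t)
    f <- estimate_rr_duplicated(d, spec)
    expect_equal(f$estimates$beta, dup$log_effect, tolerance = 1e-8)
    expect_equal(f$estimates$se, dup$se, tolerance = 1e-8)
  }
})

test_that("logistic fit reproduces published odds ratios", {
  cc <- paper_counts()
  f <- fit_logistic(counts_to_cohort(cc$y50_A), model_spec("y", "x"))
  expect_true(matches_printed(f$estimates$effect, "7.27"))
  expect_true(matches_printed(f$estimates$ci_low, "5.44"))
  expect_true(matches_printed(f$estimates$ci_high, "9.72"))
  expect_equal(f$measure, "OR")
  f5 <- fit_logistic(counts_to_cohort(cc$y5_A), model_spec("y", "x"))
  expect_true(matches_printed(f5$estimates$effect, "6.41"))
})

test_that("log-binomial fit reproduces published relative risks", {
  cc <- paper_counts()
  f <- fit_log_binomial(counts_to_cohort(cc$y50_B), model_spec("y", "x"))
  expect_true(matches_printed(f$estimates$effect, "3.9"))
  expect_true(matches_printed(f$estimates$ci_low, "3.26"))
  expect_true(matches_printed(f$estimates$ci_high, "4.67"))
  expect_equal(f$measure, "RR")
  f20 <- fit_log_binomial(counts_to_cohort(cc$y20_A), model_spec("y", "x"))
  expect_true(matches_printed(f20$estimates$effect, "2.75"))
})

test_that("duplicated-logistic estimator reproduces published cells and n", {
  cc <- paper_counts()
  f <- estimate_rr_duplicated(counts_to_cohort(cc$y50_A),
                              model_spec("y", "x"))
  expect_true(matches_printed(f$estimates$effect, "3"))
  expect_true(matches_printed(f$estimates$ci_low, "2.31"))
  expect_true(matches_printed(f$estimates$ci_high, "3.89"))
  expect_equal(f$n_original, 1000L)
  expect_equal(f$n_after_duplication, 1500L)
  expect_equal(f$measure, "RR")
  expect_equal(f$variance, "model_based")

  fC <- estimate_rr_duplicated(counts_to_cohort(cc$y50_C),
                               model_spec("y", "x"))
  expect_true(matches_printed(fC$estimates$effect, "1.25"))
  expect_true(matches_printed(fC$estimates$ci_low, "1"))
  expect_true(matches_printed(fC$estimates$ci_high, "1.55"))

  expect_error(
    estimate_rr_duplicated(duplicate_cases(counts_to_cohort(cc$y50_A), "y"),
                           model_spec("y", "x")),
    "already duplicated")
})

test_that("duplicated SE exceeds log-binomial SE by exactly 2/n per arm", {
  t <- two_by_two(30, 20, 12, 38)
  d <- expand_two_by_two(t)
  fd <- estimate_rr_duplicated(d, model_spec("y", "x"))
  fb <- fit_log_binomial(d, model_spec("y", "x"))
  expect_equal(fd$estimates$se^2 - fb$estimates$se^2,
               2 / t$n1 + 2 / t$n0, tolerance = 1e-8)
  expect_gt(fd$estimates$se, fb$estimates$se)
})

test_that("a covariate independent of the outcome gives a null effect", {
  set.seed(9)
  d <- data.frame(y = rep(c(0, 1), each = 200), x = rep(c(0, 1), 200))
  f <- fit_logistic(d, model_spec("y", "x"))
  expect_equal(f$estimates$effect, 1, tolerance = 1e-6)
  ci <- c(f$estimates$ci_low, f$estimates$ci_high)
  expect_true(ci[1] < 1 && 1 < ci[2])
})

test_that("separation is reported as non-convergence, not huge estimates", {
  d <- data.frame(y = rep(c(0, 1), each = 20), x = rep(c(0, 1), each = 20))
  f <- fit_logistic(d, model_spec("y", "x"))
  expect_false(f$converged)
  expect_match(paste(f$notes, collapse = " "), "separation|numerically")
})

test_that("log-binomial boundary fits are flagged, carrying the iterate", {
  # all exposed subjects are cases: the ML solution sits on the boundary
  d <- expand_two_by_two(two_by_two(15, 0, 6, 24))
  f <- fit_log_binomial(d, model_spec("y", "x"))
  expect_false(f$converged)
  expect_true(f$boundary || length(f$notes) > 0)
  expect_true(is.finite(f$estimates$beta) || is.na(f$estimates$beta))
})

test_that("rank-deficient designs raise an input error", {
  d <- counts_to_cohort(two_by_two(20, 30, 10, 40))
  d$x2 <- d$x
  expect_error(fit_logistic(d, model_spec("y", c("x", "x2"))),
               "rank deficient")
})

test_that("sandwich variance matches a hand-computed HC0 oracle", {
  set.seed(31)
  tab <- simulate_cohort(cohort_design(n = 300), seed = 31)
  spec <- model_spec("y", c("A", "B", "C"))
  f <- fit_logistic(tab, spec)
  X <- cbind(1, as.matrix(tab[, c("A", "B", "C")]))
  p <- 1 / (1 + exp(-drop(X %*% c(f$intercept, f$estimates$beta))))
  bread <- solve(t(X) %*% (X * (p * (1 - p))))
  score <- X * (tab$y - p)
  meat <- t(score) %*% score
  expect_equal(unname(sandwich_vcov(f)), unname(bread %*% meat %*% bread),
               tolerance = 1e-8)
  # HC1 scales HC0 by n/(n-p)
  expect_equal(unname(sandwich_vcov(f, df_correction = TRUE)),
               unname(sandwich_vcov(f)) * 300 / (300 - 4),
               tolerance = 1e-10)
})

test_that("robust and model-based SEs nearly coincide on saturated 2x2", {
  d <- counts_to_cohort(two_by_two(40, 60, 25, 75))
  spec_r <- model_spec("y", "x", variance = "robust")
  f_r <- fit_logistic(d, spec_r)
  f_m <- fit_logistic(d, model_spec("y", "x"))
  expect_equal(f_r$estimates$se, f_m$estimates$se, tolerance = 0.05)
  # robust variance computes on a duplicated table without complaint
  dup <- duplicate_cases(d, "y")
  f_d <- fit_logistic(dup, spec_r)
  expect_true(is.finite(f_d$estimates$se))
})

test_that("model_spec validates its arguments", {
  expect_error(model_spec("y", character(0)), "at least one")
  expect_error(model_spec("y", c("A", "A")), "duplicated")
  expect_error(model_spec("y", "A", ci_level = 1), "strictly between")
  expect_error(model_spec("y", "A", estimator = "poisson"), "arg")
})
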