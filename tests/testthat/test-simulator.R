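test_that("benchmark reconstruction reproduces every published margin", {
  ref <- build_reference_cohort()
  expect_equal(nrow(ref), 1000L)
  expect_equal(colSums(ref[, c("A", "B", "C")]), c(A = 600, B = 500, C = 400))
  expect_equal(colSums(ref[, c("y50", "y20", "y5")]),
               c(y50 = 500, y20 = 200, y5 = 50))
  cc <- paper_counts()
  for (key in names(cc)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1L]]
    t <- cross_tabulate(ref, parts[2L], parts[1L])
    expect_equal(with(t, c(a1, b1, a0, b0)), cc[[key]], label = key)
  }
})

test_that("benchmark outcomes are nested case subsets", {
  ref <- build_reference_cohort()
  expect_true(all(ref$y5 <= ref$y20))
  expect_true(all(ref$y20 <= ref$y50))
})

test_that("the reconstruction is deterministic", {
  expect_identical(build_reference_cohort(), build_reference_cohort())
})

test_that("benchmark narrative structure holds", {
  ref <- build_reference_cohort()
  # A and B positively associated (the confounding), C enriched under A
  ab <- cross_tabulate(ref, "A", "B")
  expect_gt(odds_ratio(ab)$effect, 1)
  expect_gt(mean(ref$C[ref$A == 1]), mean(ref$C[ref$A == 0]))
  # C associated with the outcome crudely but explained by A: the adjusted
  # duplicated-logistic RR for C is near 1 while the crude one is not
  crude <- estimate_rr_duplicated(ref, model_spec("y50", "C"))
  adj <- estimate_rr_duplicated(ref, model_spec("y50", c("A", "B", "C")))
  expect_gt(crude$estimates$effect, 1.2)
  expect_lt(abs(log(adj$estimates$effect[3])), abs(log(1.2)))
})

test_that("simulated cohorts are reproducible and near design margins", {
  design <- cohort_design()
  s1 <- simulate_cohort(design, seed = 123)
  s2 <- simulate_cohort(design, seed = 123)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 1000L)
  # empirical prevalences within 3 binomial SDs of the design values
  expect_lt(abs(mean(s1$A) - 0.6), 3 * sqrt(0.6 * 0.4 / 1000))
  expect_lt(abs(mean(s1$B) - 0.5), 3 * sqrt(0.25 / 1000))
  expect_lt(abs(mean(s1$C) - 0.4), 3 * sqrt(0.4 * 0.6 / 1000))
  expect_lt(abs(mean(s1$y) - design$expected_incidence),
            3 * sqrt(0.25 / 1000))
  expect_equal(sum(s1$y20), 200L)
  expect_equal(sum(s1$y5), 50L)
})

test_that("invalid designs are refused", {
  expect_error(cohort_design(baseline_risk = 0.4, rr_a = 2, rr_b = 2),
               "> 1")
  expect_error(cohort_design(prevalence_b = 0.9, p_b_given_a1 = 0.2),
               "outside")
  expect_error(cohort_design(target_incidences = 0.9), "exceed")
})

test_that("a null design recovers effects near 1 with every estimator", {
  design <- cohort_design(baseline_risk = 0.4, rr_a = 1, rr_b = 1,
                          target_incidences = numeric(0))
  tab <- simulate_cohort(design, seed = 55)
  spec <- model_spec("y", c("A", "B", "C"))
  for (f in list(fit_logistic(tab, spec), fit_log_binomial(tab, spec),
                 fit_cox_constant(tab, spec),
                 estimate_rr_duplicated(tab, spec))) {
    expect_true(all(abs(log(f$estimates$effect)) < 3 * f$estimates$se + 0.1))
  }
})

test_that("thinning keeps a uniform subset of cases, reproducibly", {
  tab <- simulate_cohort(cohort_design(target_incidences = numeric(0)),
                         seed = 8)
  n_cases <- sum(tab$y)
  th <- thin_outcome(tab, "y", 100, seed = 4)
  expect_equal(sum(th$y), 100L)
  expect_equal(nrow(th), 1000L)
  expect_true(all(tab$y[th$y == 1] == 1))            # subset property
  expect_identical(th, thin_outcome(tab, "y", 100, seed = 4))
  expect_identical(thin_outcome(tab, "y", n_cases, seed = 1)$y, tab$y)
  expect_error(thin_outcome(tab, "y", n_cases + 1, seed = 1), "exceeds")
  expect_equal(th[, c("A", "B", "C")], tab[, c("A", "B", "C")])
})
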