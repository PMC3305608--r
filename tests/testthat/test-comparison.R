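test_that("full benchmark grid has 72 cells and 9 inflation rows", {
  ref <- build_reference_cohort()
  cmp <- compare_methods(ref, c("A", "B", "C"), c("y5", "y20", "y50"))
  expect_equal(nrow(cmp$cells), 72L)   # 3 outcomes x 3 predictors x 2 x 4
  expect_equal(nrow(cmp$inflation), 9L)
  expect_true(all(cmp$inflation$inflation > 0))
  expect_true(all(cmp$cells$converged))
  pf <- inflation_profile(cmp)
  expect_equal(nrow(pf), 9L)
  expect_equal(pf$incidence[pf$predictor == "A"], c(0.05, 0.2, 0.5))
})

test_that("unadjusted RR estimators agree pairwise to numerical precision", {
  ref <- build_reference_cohort()
  cmp <- compare_methods(ref, c("A", "B", "C"), c("y5", "y50"))
  un <- cmp$cells[cmp$cells$adjustment == "unadjusted", ]
  for (oc in unique(un$outcome)) for (pr in unique(un$predictor)) {
    g <- un[un$outcome == oc & un$predictor == pr, ]
    eff <- g$effect[g$estimator != "logistic"]
    expect_equal(max(eff) - min(eff), 0, tolerance = 1e-8)
  }
})

test_that("OR exceeds RR, and exceeds it more as incidence grows", {
  ref <- build_reference_cohort()
  cmp <- compare_methods(ref, "B", c("y5", "y20", "y50"))
  un <- cmp$cells[cmp$cells$adjustment == "unadjusted", ]
  ratio <- sapply(c("y5", "y20", "y50"), function(oc) {
    g <- un[un$outcome == oc, ]
    g$effect[g$estimator == "logistic"] /
      g$effect[g$estimator == "log_binomial"]
  })
  expect_true(all(ratio >= 1))
  expect_true(all(diff(ratio) > 0))
})

test_that("duplicated-method CIs are the widest in every cell", {
  ref <- build_reference_cohort()
  cmp <- compare_methods(ref, c("A", "B", "C"), "y50")
  for (pr in c("A", "B", "C")) for (adj in c("unadjusted", "adjusted")) {
    g <- cmp$cells[cmp$cells$predictor == pr & cmp$cells$adjustment == adj, ]
    width <- log(g$ci_high) - log(g$ci_low)
    dup_w <- width[g$estimator == "duplicated_logistic"]
    lb_w <- width[g$estimator == "log_binomial"]
    expect_gte(dup_w, lb_w)
  }
})

test_that("single predictor and outcome give a degenerate 4+1-row report", {
  ref <- build_reference_cohort()
  cmp <- compare_methods(ref, "A", "y50")
  expect_equal(nrow(cmp$cells), 8L)  # 4 estimators x {unadjusted, adjusted}
  expect_equal(nrow(cmp$inflation), 1L)
  un <- cmp$cells[cmp$cells$adjustment == "unadjusted", ]
  ad <- cmp$cells[cmp$cells$adjustment == "adjusted", ]
  expect_equal(un$effect, ad$effect, tolerance = 1e-10)
})

test_that("a failing cell is recorded without aborting the grid", {
  ref <- build_reference_cohort()
  ref$A2 <- ref$A  # collinear with A: every adjusted fit must fail
  cmp <- compare_methods(ref, c("A", "A2"), "y50")
  adj <- cmp$cells[cmp$cells$adjustment == "adjusted", ]
  expect_true(all(!adj$converged))
  expect_true(all(nzchar(adj$note)))
  un <- cmp$cells[cmp$cells$adjustment == "unadjusted", ]
  expect_true(all(un$converged))
})

test_that("csv rendering round-trips the numeric content", {
  ref <- build_reference_cohort()
  cmp <- compare_methods(ref, c("A", "B"), "y20")
  lines <- render_report(cmp, "csv")
  blank <- which(lines == "")[1L]
  cells <- utils::read.csv(textConnection(lines[seq_len(blank - 1L)]))
  expect_equal(nrow(cells), nrow(cmp$cells))
  expect_equal(cells$effect, cmp$cells$effect, tolerance = 1e-12)
  f <- tempfile(fileext = ".csv")
  render_report(cmp, "csv", path = f)
  expect_true(file.exists(f))
})

test_that("text rendering rounds to two decimals and shows inflation", {
  ref <- build_reference_cohort()
  cmp <- compare_methods(ref, "A", "y50")
  txt <- render_report(cmp, "text")
  expect_true(any(grepl("3.00 (2.31 - 3.89)", txt, fixed = TRUE)))
  expect_true(any(grepl("7.27 (5.44 - 9.72)", txt, fixed = TRUE)))
  expect_true(any(grepl("SE inflation", txt)))
  expect_error(render_report(cmp, "yaml"))
})
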