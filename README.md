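# rrlogit

Relative risks and prevalence ratios by **case-duplication logistic
regression** — with the standard comparator estimators, exact 2×2
oracles, a cohort simulator, and standard-error inflation diagnostics.

## The problem

Logistic regression estimates odds ratios (OR). For a rare outcome the OR
approximates the relative risk (RR), but for common outcomes
(incidence ≳ 10%) it overstates it, sometimes severely: an exposure that
doubles a 50% risk has OR ≫ 2. The direct alternatives — log-binomial
regression, or Cox regression with a constant time variable and robust
variance — are not available in every statistics program, and log-binomial
fits frequently fail to converge because fitted probabilities must stay
below 1.

The case-duplication method needs nothing but ordinary logistic
regression. Every case is copied once into a provisional dataset and
relabelled as a non-case. In any covariate stratum with `a` cases and `b`
non-cases, the transformed data contain `a` cases and `a + b` non-cases,
so the fitted odds equal the original risk:

```
log-binomial:          log a/(a+b) = β0 + β1·X1 + … + βk·Xk
ordinary logistic:     log a/b     = β0 + β1·X1 + … + βk·Xk
duplicated logistic:   log a/y     = β0 + β1·X1 + … + βk·Xk,  y = a + b
```

so `exp(βi)` from the duplicated fit is a direct RR (or PR) estimate. The
price is precision: each case is counted twice, inflating the model-based
standard error (for a single 2×2 table, `SE²_dup − SE²_binomial = 2/n₁ +
2/n₀`), so confidence intervals are wider and the inflation grows with
outcome incidence.

## What the package provides

* `estimate_rr_duplicated()` — the duplication RR/PR estimator
  (`duplicate_cases()` + `fit_logistic()`).
* `fit_log_binomial()`, `fit_cox_constant()` (Breslow ties, constant
  time, robust Lin–Wei variance), `fit_logistic()` — the comparators.
* `risk_ratio()`, `odds_ratio()`, `duplicated_rr()`,
  `inflation_factor()` — exact closed-form 2×2 estimators used as the
  oracle layer in the tests.
* `build_reference_cohort()` — a deterministic 1000-subject benchmark
  cohort (three binary predictors, outcomes at 50/20/5% incidence) whose
  published one-way margins reproduce cell for cell;
  `simulate_cohort()` / `cohort_design()` — stochastic cohorts with the
  same confounding structure.
* `compare_methods()` / `inflation_profile()` / `render_report()` — the
  estimator × predictor × adjustment grid and SE-inflation table.
* A command-line interface: `rrlogit_cli()` and the installed launcher
  `system.file("cli", "rrlogit", package = "rrlogit")`, with
  `duplicate`, `fit`, `compare` and `simulate` subcommands.

## Worked example

Adjusted relative risks for the benchmark cohort's common (50%) outcome:

```r
library(rrlogit)
ref <- build_reference_cohort()
estimate_rr_duplicated(ref, model_spec("y50", c("A", "B", "C")))
#> Case-duplication logistic regression (n = 1500, cases = 500)
#>   duplicated rows: 1000 original -> 1500 analysed
#>   term         RR (95% CI), model_based variance
#>   A            2.09 (1.58 - 2.75)  SE(log) 0.1419
#>   B            3.17 (2.44 - 4.11)  SE(log) 0.1331
#>   C            1.05 (0.84 - 1.33)  SE(log) 0.1176
```

The analysis runs on 1500 rows: the 1000 subjects plus one relabelled
copy of each of the 500 cases. A and B remain strong risk factors after
mutual adjustment; C — associated with the outcome only through A — is
correctly pushed to the null. Compare the ordinary logistic ORs for the
same data (4.8, 11.8, 1.17): with a 50% outcome they are far from the
risk ratios.

The precision cost of the duplication, by predictor and incidence:

```r
cmp <- compare_methods(ref, c("A", "B", "C"), c("y5", "y20", "y50"))
inflation_profile(cmp)
#>   predictor outcome incidence inflation
#> 1         A      y5      0.05  1.018929
#> 4         A     y20      0.20  1.140614
#> 7         A     y50      0.50  1.378120
#> 2         B      y5      0.05  1.041167
#> 5         B     y20      0.20  1.140112
#> 8         B     y50      0.50  1.400694
#> 3         C      y5      0.05  1.053161
#> 6         C     y20      0.20  1.228581
#> 9         C     y50      0.50  1.770837
```

Each entry is the ratio of the duplicated-method SE to the log-binomial
SE for the same unadjusted coefficient: a 2–5% penalty for the rare
outcome, rising to 38–77% for the common one. When an association is
borderline with the duplicated method, ordinary logistic regression can
still be used for the null-hypothesis test (RR = 1 iff OR = 1).

From the shell:

```sh
rrlogit simulate --reference --out cohort.csv
rrlogit fit --in cohort.csv --outcome y50 --predictors A,B,C \
        --estimator duplicated_logistic
rrlogit compare --in cohort.csv --outcome y5,y20,y50 \
        --predictors A,B,C --format text
```

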