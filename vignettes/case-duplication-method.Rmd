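---
title: "Estimating relative risks by case-duplication logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating relative risks by case-duplication logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrlogit)
```

## The model and why it works

For a binary outcome observed in a cohort (or a cross-sectional sample),
the estimand of interest is usually the relative risk RR (prevalence
ratio PR) — the ratio of outcome probabilities between exposed and
unexposed — not the odds ratio. A log-binomial model targets it directly:
within a covariate stratum holding $a$ cases and $b$ non-cases,

$$\log \frac{a}{a+b} = \beta_0 + \beta_1 X_1 + \dots + \beta_k X_k,$$

and $e^{\beta_i}$ is the RR for $X_i$. Ordinary logistic regression
replaces the proportion by the odds, $\log a/b$, and $e^{\beta_i}$
becomes an OR, which exceeds the RR whenever RR > 1 and the outcome is
not rare.

The case-duplication device maps one problem onto the other. Copy every
case into the dataset once more, relabelled as a non-case. The stratum
then holds $a$ cases and $y = a + b$ non-cases, so the *odds* fitted by
logistic regression on the transformed data,

$$\log \frac{a}{y} = \beta_0 + \beta_1 X_1 + \dots + \beta_k X_k,$$

equal the original *risk*: the duplicated-data logistic model is exactly
the log-risk model. Equivalently, each original subject contributes
$1 + p(x)$ expected rows of which $p(x)$ are case rows, so the
duplicated-population case fraction is $p/(1+p)$ and
$\mathrm{logit}^{-1}(\beta'x) = p/(1+p) \iff e^{\beta'x} = p$. The
estimator is therefore consistent exactly when the log-linear risk model
is correctly specified — the same condition log-binomial regression
needs. It is the same idea as a case-cohort analysis in which the
comparison group is the *entire* cohort: cases are over-represented,
which biases nothing but costs precision.

## Precision cost and the inflation factor

Because every case appears twice, the model-based variance from the
duplicated fit exceeds the log-binomial one. For a single 2×2 table with
arm totals $n_1, n_0$ the closed forms are

$$\mathrm{SE}^2_{\text{dup}} = \frac1{a_1} + \frac1{n_1} + \frac1{a_0} +
  \frac1{n_0}, \qquad
  \mathrm{SE}^2_{\text{bin}} = \frac{b_1}{n_1 a_1} + \frac{b_0}{n_0 a_0},$$

whose difference is $2/n_1 + 2/n_0 > 0$ (using $n - b = a$). The package
reports the ratio $\mathrm{SE}_{\text{dup}}/\mathrm{SE}_{\text{bin}}$ as
the *inflation factor*; it grows with outcome incidence (about 1.02–1.05
at 5% incidence versus 1.38–1.77 at 50% on the benchmark cohort, as
`inflation_profile()` shows) because the duplicated case mass grows with
the case fraction. Consequently confidence intervals are wider and the
type II error risk is higher; when a duplicated-method interval is
borderline, the null hypothesis RR = 1 can still be tested with ordinary
logistic regression, since OR = 1 iff RR = 1. No general correction
factor exists: in a multivariable model each coefficient's SE depends on
the correlation structure of all covariates, so the package reports the
factor rather than attempting to undo it.

No cluster correction ties a duplicate to its source case: the method as
specified uses plain model-based logistic SEs, and that is what
`estimate_rr_duplicated()` reports. The transform is materialised as a
real "provisional" table (`duplicate_cases()`, with a `.provenance`
flag) rather than implemented as frequency weights, so any external
logistic-regression program can consume the written CSV; the flag also
lets the transform refuse an already-duplicated input, since applying it
twice would duplicate cases again and destroy the odds-equals-risk
identity.

## The comparator estimators

* **Log-binomial** (`fit_log_binomial()`): binomial family, log link,
  fitted by iteratively reweighted least squares with starting values
  intercept = log(overall risk), slopes = 0. The likelihood maximum can
  sit on the boundary of the parameter space (fitted probability → 1);
  boundary or non-converged fits are returned flagged, with the last
  iterate, never silently repaired.
* **Cox with constant time** (`fit_cox_constant()`): every subject gets
  the same follow-up time and the outcome is the event. Ties are handled
  with the Breslow approximation — with all events tied, every risk set
  is the full cohort and the partial-likelihood score solves exactly to
  the risk ratio for a single binary covariate; the Efron approximation
  would reweight risk sets and break this identity, so the ties method is
  fixed. Reported intervals use the Lin–Wei robust variance with the
  $n/(n-1)$ finite-sample multiplier that the major commercial
  implementations of this estimator apply; the naive partial-likelihood
  variance (too wide here — it treats the binary outcome like event
  counts) is kept alongside for comparison.
* **Ordinary logistic** (`fit_logistic()`): the OR benchmark. Apparent
  separation is reported as non-convergence with a diagnostic rather
  than returning numerically divergent estimates.

All effect-scale intervals are large-sample Wald intervals,
$\exp(\beta \mp z\,\mathrm{SE})$ with $z = 1.959964$ at the default 95%
level; the benchmark tables reproduce under exactly this choice, and no
small-sample $t$ quantile is used.

## Numerical choices

* GLM convergence: deviance tolerance $10^{-14}$, at most 100
  iterations. The tight tolerance matters for a subtle reason: `glm`'s
  own covariance is evaluated with the weights of the penultimate
  iterate, which lags the coefficients by one Newton step. The package
  recomputes the expected information at the final coefficients, so on
  saturated (single binary predictor) data the engines agree with the
  closed-form SEs to ~1e-10 rather than ~1e-7.
* Log-link step-halving is delegated to the IRLS implementation; a fit
  whose final probabilities reach $1 - 10^{-8}$ is flagged as a boundary
  fit and marked non-converged.
* Robust GLM variance is the HC0 information sandwich (bread = inverse
  observed information, meat = outer products of per-subject scores),
  with an optional HC1 degrees-of-freedom correction that is off by
  default. Only the Cox estimator applies a finite-sample multiplier,
  because that is the convention its reference implementations use.
* Zero cells in 2×2 tables are refused rather than continuity-corrected;
  rank-deficient designs are an input error, not a silent column drop.
* Rounding to 2 decimals (the benchmark tables' precision) happens only
  when a report is rendered; all comparisons and inflation factors use
  full precision.

## The benchmark cohort and its canonical completion

`build_reference_cohort()` reconstructs, deterministically, a
1000-subject cohort with binary predictors A (prevalence 60%), B (50%)
and C (40%) and three nested outcomes with incidence 50%, 20% and 5%
(the rarer outcomes are case subsets of the 50% outcome). Its published
description fixes only the *one-way* margins — each predictor
cross-tabulated against each outcome — plus narrative structure: A and B
are both strong risk factors and mutually associated (confounding), and
C is associated with the outcome only through A.

The joint distribution over (A, B, C) is not published, so the function
fixes one canonical completion:

1. Within the 50%-outcome cases and non-cases separately, cell counts
   over the $2^3$ (A, B, C) grid are obtained by iterative proportional
   fitting of a log-linear seed with A–B and A–C log odds ratios of
   $\log 2$ (a moderate association, matching the narrative) to the
   published margins. IPF preserves the seed's interaction structure
   while matching the margins.
2. Real-valued cells are rounded to integers by largest-remainder
   rounding, then repaired by paired one-unit transfers between cells
   differing in a single variable — fixing the total, then the A, B and
   C margins in that order, each transfer preserving the margins already
   fixed.
3. The 20%- and 5%-incidence case sets are allocated the same way,
   seeded with the parent case cells and capped by them, so the case
   sets nest.

All published margins reproduce exactly, and the suite asserts every
one. Adjusted (multivariable) estimates computed on the completion are
close to, but cannot be guaranteed identical to, values computed on the
unpublished original — only the unadjusted cells are desk-checkable, and
only those are held to exact reproduction.

## The simulator: what it emulates and what it does not

`cohort_design()` encodes the generative structure the benchmark cohort
narrates, with these defaults:

| parameter | default | why |
|---|---|---|
| n | 1000 | the benchmark cohort size |
| P(A), P(B), P(C) | .6, .5, .4 | the stated prevalences |
| P(B \| A=1) | .6 (⇒ P(B \| A=0) = .35) | moderate A–B association, preserving the marginal |
| P(C \| A=1) | .5 (⇒ P(C \| A=0) = .25) | C enriched under A, preserving the marginal |
| baseline risk | .153 | overall incidence ≈ 50% under the covariate mix |
| RR_A, RR_B | 1.9, 3.1 | conditional effects of the magnitude the benchmark's adjusted common-outcome analyses display |
| thinned incidences | .2, .05 | the benchmark's derived outcomes (200 and 50 cases) |

Risk is multiplicative, $p = p_0\,\mathrm{RR}_A^{A}\,\mathrm{RR}_B^{B}$,
with C carrying no effect given A and B — so C's crude association with
the outcome is pure confounding through A, and the log-linear risk model
fitted by all RR estimators is correctly specified. Lower-incidence
outcomes keep a uniformly random subset of the drawn cases
(`thin_outcome()`), which preserves every RR because all risks scale by
the same factor. A fixed seed reproduces a cohort exactly.

What the simulator does *not* emulate: continuous or multi-level
covariates, interactions or non-multiplicative risk, missing data,
sampling designs other than a simple cohort, and model misspecification
generally. Passing parameter-recovery tests on these cohorts therefore
shows the estimators are consistent and mutually consistent *under a
correctly specified multiplicative risk model* — not that the
duplication method is robust to misspecification on arbitrary real data.

## Problem sizes used by the test harness

The suite's Monte-Carlo evidence uses 200 simulated cohorts of n = 1000
under the default design, each analysed at incidences 5/20/50% — enough
replicates that the Monte-Carlo SE of a mean log-RR is ≈ 0.007–0.03,
making the 3-MC-SE recovery bands meaningful. Engine-vs-oracle
equivalence is asserted at 1e-8 on a deterministic 5⁴-point grid of 2×2
tables spanning cell counts 1–30, while the closed-form identities
(duplication point = RR, SE inflation > 1, |log OR| ≥ |log RR|) are
swept exhaustively over all 30⁴ such tables in vectorised form.
Adjusted-estimate agreement between the duplicated, Cox and log-binomial
fits is asserted as a mean relative difference below 5% per incidence ×
predictor × estimator cell: single-cohort differences on a near-null
coefficient can exceed that even between two consistent estimators of
the same quantity, so the aggregate is the scientifically meaningful
statement.

## Known limitations

* The duplication method pays for its simplicity in precision; with
  common outcomes its intervals are materially wider than log-binomial
  or robust-Cox intervals. It is the right tool when logistic regression
  is the only estimator available.
* Covariates must be numeric; categorical predictors with more than two
  levels must be encoded as indicator columns upstream.
* The estimator hierarchy is documentation, not automation: a
  non-convergent log-binomial cell in `compare_methods()` is reported as
  such, with no silent fallback to another estimator.
* Model-based duplicated-method SEs ignore the case/duplicate pairing by
  design (that is the method as formulated); a clustered-robust variant
  is deliberately not offered.
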