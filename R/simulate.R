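## Cohort construction: a deterministic reconstruction of the 1000-subject
## benchmark cohort, and a stochastic generator with the same structure
## (two causal binary predictors with confounding between them, plus a
## third predictor associated with the outcome only through the first).

## --- iterative proportional fitting over the 2x2x2 (A,B,C) cell grid ----

ipf_cell_grid <- function() expand.grid(a = 0:1, b = 0:1, c = 0:1)

## Scale a seed table so each one-way margin (A, B, C and the total) is
## met; IPF preserves the seed's interaction structure.
ipf_fit_margins <- function(seed, total, mA, mB, mC,
                            tol = 1e-12, maxit = 1000L) {
  g <- ipf_cell_grid()
  x <- seed / sum(seed) * total
  for (it in seq_len(maxit)) {
    old <- x
    x[g$a == 1] <- x[g$a == 1] * mA / sum(x[g$a == 1])
    x[g$a == 0] <- x[g$a == 0] * (total - mA) / sum(x[g$a == 0])
    x[g$b == 1] <- x[g$b == 1] * mB / sum(x[g$b == 1])
    x[g$b == 0] <- x[g$b == 0] * (total - mB) / sum(x[g$b == 0])
    x[g$c == 1] <- x[g$c == 1] * mC / sum(x[g$c == 1])
    x[g$c == 0] <- x[g$c == 0] * (total - mC) / sum(x[g$c == 0])
    if (max(abs(x - old)) < tol) break
  }
  x
}

## Round real-valued cells to integers while reproducing the total and all
## three one-way margins exactly.  Largest-remainder rounding fixes the
## total; then paired +-1 transfers between cells differing only in one
## variable fix that variable's margin without disturbing the margins fixed
## before it (order: A, then B, then C).  `cap` bounds cells from above
## (used when thinned case counts must stay within the parent cell).
round_to_margins <- function(x, total, mA, mB, mC, cap = NULL) {
  g <- ipf_cell_grid()
  k <- round(x)
  if (!is.null(cap)) k <- pmin(k, cap)
  d <- total - sum(k)
  while (d != 0) {
    r <- x - k
    if (d > 0) {
      blocked <- if (is.null(cap)) rep(FALSE, 8L) else k >= cap
      i <- which.max(r - 1e9 * blocked)
      k[i] <- k[i] + 1; d <- d - 1
    } else {
      i <- which.max(-r - 1e9 * (k <= 0))
      k[i] <- k[i] - 1; d <- d + 1
    }
  }
  fix_margin <- function(k, var, target) {
    others <- setdiff(c("a", "b", "c"), var)
    repeat {
      d <- target - sum(k[g[[var]] == 1])
      if (d == 0) return(k)
      from <- if (d > 0) 0 else 1
      donors <- which(g[[var]] == from & k > 0)
      best <- NULL; best_score <- -Inf
      for (i in donors) {
        j <- which(g[[var]] == 1 - from &
                     g[[others[1L]]] == g[[others[1L]]][i] &
                     g[[others[2L]]] == g[[others[2L]]][i])
        if (!is.null(cap) && k[j] >= cap[j]) next
        score <- (x[j] - k[j]) - (x[i] - k[i])
        if (score > best_score) { best_score <- score; best <- c(i, j) }
      }
      if (is.null(best))
        stop_validation("margins infeasible under cell caps")
      k[best[1L]] <- k[best[1L]] - 1
      k[best[2L]] <- k[best[2L]] + 1
    }
  }
  k <- fix_margin(k, "a", mA)
  k <- fix_margin(k, "b", mB)
  k <- fix_margin(k, "c", mC)
  stopifnot(sum(k) == total, sum(k[g$a == 1]) == mA,
            sum(k[g$b == 1]) == mB, sum(k[g$c == 1]) == mC,
            all(k >= 0), is.null(cap) || all(k <= cap))
  k
}

## Printed one-way margins of the benchmark cohort: cases among
## A/B/C-positive subjects at each outcome incidence, and predictor totals.
reference_margins <- function() {
  list(totals = c(A = 600, B = 500, C = 400),
       cases = c("y50" = 500, "y20" = 200, "y5" = 50),
       cases_pos = rbind("y50" = c(A = 409, B = 398, C = 227),
                         "y20" = c(A = 161, B = 159, C = 84),
                         "y5" = c(A = 45, B = 36, C = 23)))
}

#' Deterministic reconstruction of the 1000-subject benchmark cohort
#'
#' Rebuilds, without any random draw, a cohort of 1000 subjects with three
#' binary predictors (A, prevalence 60%; B, 50%; C, 40%) and three nested
#' binary outcomes of incidence 50%, 20% and 5%, whose one-way
#' cross-tabulations of each predictor against each outcome reproduce the
#' published benchmark table cell for cell.
#'
#' Only those one-way margins are published; the joint distribution of
#' (A, B, C) is not, so this function fixes a canonical completion:
#' \enumerate{
#'   \item Within cases and non-cases of the 50% outcome separately, cell
#'     counts over the 2x2x2 (A, B, C) grid are obtained by iterative
#'     proportional fitting of a log-linear seed with A-B and A-C log odds
#'     ratios of log 2 (the narrative structure: A and B mutually
#'     associated, C more frequent when A is present and conditionally
#'     unrelated to the outcome) to the published margins.
#'   \item Real-valued cells are rounded to integers by largest-remainder
#'     rounding followed by paired one-unit transfers that restore the
#'     total and the A, B, C margins exactly, in that order.
#'   \item The 20%- and 5%-incidence case sets are nested subsets of the
#'     50% cases (y5 within y20 within y50), allocated across cells by the
#'     same fit-then-round procedure seeded with the parent case cells and
#'     capped by them.
#' }
#' Margins are exact by construction; adjusted (multivariable) estimates on
#' this completion are close to, but cannot be guaranteed identical to,
#' those computed on the unpublished original.
#'
#' @return data.frame with 1000 rows and columns `A`, `B`, `C`, `y50`,
#'   `y20`, `y5`.
#' @export
#' @examples
#' ref <- build_reference_cohort()
#' cross_tabulate(ref, "A", "y50")  # 409 / 191 / 91 / 309
build_reference_cohort <- function() {
  m <- reference_margins()
  g <- ipf_cell_grid()
  theta <- log(2)  # moderate A-B and A-C association
  seed <- exp(theta * g$a * g$b + theta * g$a * g$c)
  mk <- function(total, mv) round_to_margins(
    ipf_fit_margins(seed, total, mv[["A"]], mv[["B"]], mv[["C"]]),
    total, mv[["A"]], mv[["B"]], mv[["C"]])
  cases50 <- mk(500, m$cases_pos["y50", ])
  noncases <- mk(500, m$totals - m$cases_pos["y50", ])
  nest <- function(parent, total, mv) round_to_margins(
    ipf_fit_margins(pmax(parent, 1e-9), total,
                    mv[["A"]], mv[["B"]], mv[["C"]]),
    total, mv[["A"]], mv[["B"]], mv[["C"]], cap = parent)
  cases20 <- nest(cases50, 200, m$cases_pos["y20", ])
  cases5 <- nest(cases20, 50, m$cases_pos["y5", ])
  rows <- vector("list", 16L)
  for (i in seq_len(8L)) {
    cell <- data.frame(A = g$a[i], B = g$b[i], C = g$c[i])
    k50 <- cases50[i]; k20 <- cases20[i]; k5 <- cases5[i]
    case_rows <- cell[rep(1L, k50), , drop = FALSE]
    case_rows$y50 <- 1L
    case_rows$y20 <- rep(c(1L, 0L), c(k20, k50 - k20))
    case_rows$y5 <- rep(c(1L, 0L), c(k5, k50 - k5))
    non_rows <- cell[rep(1L, noncases[i]), , drop = FALSE]
    if (nrow(non_rows)) non_rows[c("y50", "y20", "y5")] <- 0L
    rows[[2L * i - 1L]] <- case_rows
    rows[[2L * i]] <- non_rows
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## --- stochastic generator --------------------------------------------

#' Describe a cohort-generating design
#'
#' Specifies the generative model behind [simulate_cohort()]: predictor A
#' is Bernoulli with prevalence `prevalence_a`; B and C are Bernoulli given
#' A, with the A-positive conditional probabilities given explicitly and
#' the A-negative ones derived so the stated marginal prevalences hold;
#' the outcome risk is multiplicative, `baseline_risk * rr_a^A * rr_b^B`
#' (C carries no effect given A and B, so its crude association with the
#' outcome is pure confounding through A).  Lower-incidence outcomes are
#' obtained by randomly thinning the case set to `round(n * incidence)`
#' cases.
#'
#' The defaults emulate the benchmark cohort: n = 1000, prevalences
#' 60/50/40%, conditional RRs 1.9 for A and 3.1 for B, baseline risk 0.153
#' (overall incidence close to 50%), and thinned outcomes at 20% and 5%.
#'
#' @param n cohort size.
#' @param prevalence_a,prevalence_b,prevalence_c marginal prevalences of
#'   the three predictors.
#' @param p_b_given_a1,p_c_given_a1 conditional probabilities of B and C
#'   when A = 1; the A = 0 values are derived from the marginals.
#' @param baseline_risk outcome risk when A = B = 0.
#' @param rr_a,rr_b multiplicative risk ratios for A and B.
#' @param target_incidences incidences of the thinned outcome columns;
#'   must not exceed the primary incidence implied by the risk model.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n = 1000L, prevalence_a = 0.6,
                          prevalence_b = 0.5, prevalence_c = 0.4,
                          p_b_given_a1 = 0.6, p_c_given_a1 = 0.5,
                          baseline_risk = 0.153, rr_a = 1.9, rr_b = 3.1,
                          target_incidences = c(0.2, 0.05)) {
  if (n < 1L) stop_validation("'n' must be at least 1")
  probs <- c(prevalence_a, prevalence_b, prevalence_c,
             p_b_given_a1, p_c_given_a1, baseline_risk)
  if (any(probs < 0 | probs > 1))
    stop_validation("all probabilities must lie in [0, 1]")
  if (rr_a <= 0 || rr_b <= 0)
    stop_validation("risk ratios must be positive")
  p_b_given_a0 <- (prevalence_b - prevalence_a * p_b_given_a1) /
    (1 - prevalence_a)
  p_c_given_a0 <- (prevalence_c - prevalence_a * p_c_given_a1) /
    (1 - prevalence_a)
  if (p_b_given_a0 < 0 || p_b_given_a0 > 1 ||
      p_c_given_a0 < 0 || p_c_given_a0 > 1)
    stop_validation("conditional probabilities implied by the marginals ",
                    "fall outside [0, 1]")
  max_risk <- baseline_risk * max(1, rr_a) * max(1, rr_b)
  if (max_risk > 1)
    stop_validation("risk model yields probability ", signif(max_risk, 4),
                    " > 1 for the doubly exposed pattern")
  mean_mult <- local({
    pa <- prevalence_a
    p11 <- pa * p_b_given_a1; p10 <- pa * (1 - p_b_given_a1)
    p01 <- (1 - pa) * p_b_given_a0; p00 <- (1 - pa) * (1 - p_b_given_a0)
    p11 * rr_a * rr_b + p10 * rr_a + p01 * rr_b + p00
  })
  incidence <- baseline_risk * mean_mult
  if (any(target_incidences > incidence))
    stop_validation("target incidences must not exceed the primary ",
                    "incidence (", signif(incidence, 3), ")")
  structure(list(n = as.integer(n), prevalence_a = prevalence_a,
                 prevalence_b = prevalence_b, prevalence_c = prevalence_c,
                 p_b_given_a1 = p_b_given_a1, p_b_given_a0 = p_b_given_a0,
                 p_c_given_a1 = p_c_given_a1, p_c_given_a0 = p_c_given_a0,
                 baseline_risk = baseline_risk, rr_a = rr_a, rr_b = rr_b,
                 expected_incidence = incidence,
                 target_incidences = target_incidences),
            class = "cohort_design")
}

#' Simulate a cohort from a design
#'
#' Draws a cohort under the generative model of a [cohort_design()].  The
#' primary outcome column is `y`; each requested thinned incidence adds a
#' column `y<percent>` (e.g. `y20`, `y5`) obtained by keeping a uniformly
#' random subset of `round(n * incidence)` cases.  All draws come from R's
#' default generator seeded once with `seed`, so a fixed seed reproduces
#' the table exactly.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return data.frame with columns `A`, `B`, `C`, `y` and one column per
#'   thinned incidence.
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  n <- design$n
  A <- rbinom(n, 1L, design$prevalence_a)
  B <- rbinom(n, 1L, ifelse(A == 1, design$p_b_given_a1,
                            design$p_b_given_a0))
  C <- rbinom(n, 1L, ifelse(A == 1, design$p_c_given_a1,
                            design$p_c_given_a0))
  risk <- design$baseline_risk * design$rr_a^A * design$rr_b^B
  y <- rbinom(n, 1L, risk)
  out <- data.frame(A = A, B = B, C = C, y = y)
  for (inc in design$target_incidences) {
    target <- round(n * inc)
    if (target > sum(y))
      stop_validation("cannot thin to ", target, " cases: only ", sum(y),
                      " cases were drawn")
    col <- paste0("y", format(100 * inc, trim = TRUE))
    out[[col]] <- thin_cases(y, target)
  }
  out
}

## Keep a uniformly random subset of the current cases (sampled from the
## sorted case indices without replacement); everyone else becomes a
## non-case.  Uses the current RNG stream.
thin_cases <- function(y, target_cases) {
  idx <- which(y == 1)
  keep <- sort(sample(idx, target_cases))
  out <- integer(length(y))
  out[keep] <- 1L
  out
}

#' Thin an outcome to a target number of cases
#'
#' Keeps a uniformly random subset of the current cases and relabels every
#' other subject a non-case; covariates are untouched.  This is how
#' lower-incidence outcome variables are derived from a common-outcome
#' cohort.
#'
#' @param table cohort data.frame.
#' @param outcome outcome column to thin.
#' @param target_cases number of cases to retain; must not exceed the
#'   current case count.
#' @param seed optional integer seed (set once before sampling); leave
#'   `NULL` to use the current RNG state.
#' @param new_outcome optional name for a new column holding the thinned
#'   outcome; by default the outcome column is replaced.
#' @return the modified cohort data.frame.
#' @export
thin_outcome <- function(table, outcome, target_cases, seed = NULL,
                         new_outcome = NULL) {
  validate_cohort(table, outcome)
  n_cases <- sum(table[[outcome]] == 1)
  if (target_cases > n_cases)
    stop_validation("target_cases (", target_cases, ") exceeds current ",
                    "case count (", n_cases, ")")
  if (!is.null(seed)) set.seed(seed)
  thinned <- thin_cases(table[[outcome]], target_cases)
  table[[if (is.null(new_outcome)) outcome else new_outcome]] <- thinned
  table
}
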