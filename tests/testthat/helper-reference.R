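# Frozen published benchmark values used across the suite.
#
# paper_counts(): exposed-case / exposed-noncase / unexposed-case /
# unexposed-noncase counts for each predictor at each outcome incidence
# (the benchmark cohort's one-way margins).
#
# paper_unadjusted(): the published unadjusted effect and 95% CI of every
# estimator, stored as printed strings so tests can compare at printed
# precision ("6", "2.4", "14.98" have different rounding).

paper_counts <- function() {
  list(
    y50_A = c(409, 191, 91, 309), y50_B = c(398, 102, 102, 398),
    y50_C = c(227, 173, 273, 327),
    y20_A = c(161, 439, 39, 361), y20_B = c(159, 341, 41, 459),
    y20_C = c(84, 316, 116, 484),
    y5_A = c(45, 555, 5, 395), y5_B = c(36, 464, 14, 486),
    y5_C = c(23, 377, 27, 573))
}

paper_unadjusted <- function() {
  rows <- list(
    c("y5", "A", "log_binomial", "6", "2.4", "14.98"),
    c("y5", "A", "logistic", "6.41", "2.52", "16.28"),
    c("y5", "A", "cox_constant_robust", "6", "2.4", "14.99"),
    c("y5", "A", "duplicated_logistic", "6", "2.36", "15.25"),
    c("y5", "B", "log_binomial", "2.57", "1.4", "4.71"),
    c("y5", "B", "logistic", "2.69", "1.43", "5.06"),
    c("y5", "B", "cox_constant_robust", "2.57", "1.4", "4.71"),
    c("y5", "B", "duplicated_logistic", "2.57", "1.37", "4.83"),
    c("y5", "C", "log_binomial", "1.28", "0.74", "2.2"),
    c("y5", "C", "logistic", "1.29", "0.73", "2.29"),
    c("y5", "C", "cox_constant_robust", "1.28", "0.74", "2.2"),
    c("y5", "C", "duplicated_logistic", "1.28", "0.72", "2.26"),
    c("y20", "A", "log_binomial", "2.75", "1.99", "3.81"),
    c("y20", "A", "logistic", "3.39", "2.33", "4.95"),
    c("y20", "A", "cox_constant_robust", "2.75", "1.99", "3.81"),
    c("y20", "A", "duplicated_logistic", "2.75", "1.9", "3.99"),
    c("y20", "B", "log_binomial", "3.88", "2.82", "5.34"),
    c("y20", "B", "logistic", "5.22", "3.6", "7.56"),
    c("y20", "B", "cox_constant_robust", "3.88", "2.82", "5.34"),
    c("y20", "B", "duplicated_logistic", "3.88", "2.69", "5.59"),
    c("y20", "C", "log_binomial", "1.09", "0.85", "1.4"),
    c("y20", "C", "logistic", "1.11", "0.81", "1.52"),
    c("y20", "C", "cox_constant_robust", "1.09", "0.85", "1.4"),
    c("y20", "C", "duplicated_logistic", "1.09", "0.8", "1.48"),
    c("y50", "A", "log_binomial", "3", "2.48", "3.62"),
    c("y50", "A", "logistic", "7.27", "5.44", "9.72"),
    c("y50", "A", "cox_constant_robust", "3", "2.48", "3.62"),
    c("y50", "A", "duplicated_logistic", "3", "2.31", "3.89"),
    c("y50", "B", "log_binomial", "3.9", "3.26", "4.67"),
    c("y50", "B", "logistic", "15.23", "11.19", "20.71"),
    c("y50", "B", "cox_constant_robust", "3.9", "3.26", "4.67"),
    c("y50", "B", "duplicated_logistic", "3.9", "3.04", "5.01"),
    c("y50", "C", "log_binomial", "1.25", "1.1", "1.41"),
    c("y50", "C", "logistic", "1.57", "1.22", "2.03"),
    c("y50", "C", "cox_constant_robust", "1.25", "1.1", "1.41"),
    c("y50", "C", "duplicated_logistic", "1.25", "1", "1.55"))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("outcome", "predictor", "estimator", "est", "lo", "hi")
  out
}

# decimals of a printed token ("2.4" -> 1, "6" -> 0)
printed_decimals <- function(s) {
  ifelse(grepl(".", s, fixed = TRUE),
         nchar(sub("^[^.]*\\.", "", s)), 0L)
}

# does `value` round to the printed token?
matches_printed <- function(value, printed) {
  round(value, printed_decimals(printed)) == as.numeric(printed)
}

counts_to_cohort <- function(cc) {
  if (!inherits(cc, "two_by_two"))
    cc <- two_by_two(cc[1], cc[2], cc[3], cc[4])
  expand_two_by_two(cc)
}
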