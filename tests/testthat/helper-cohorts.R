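# Shared fixtures: compact cohort specs used across test files. All
# fixtures are generated in code at test time; no covariate missingness
# unless a test asks for it.

hinge_spec <- function(n, seed, K = 3.3, or_below = 0.60, or_above = 1.28,
                       ...) {
  cohort_spec(n_patients = n, seed = seed, turning_point_K = K,
              slope_below = log(or_below), slope_above = log(or_above),
              missing_rates = c(), ...)
}

linear_spec <- function(n, seed, or_unit = 1.1, prev = 0.0594) {
  # equal slopes on both sides of K: a strictly linear logit
  cohort_spec(n_patients = n, seed = seed,
              slope_below = log(or_unit), slope_above = log(or_unit),
              target_prev = prev, missing_rates = c())
}

flat_spec <- function(n, seed, prev = 0.06) {
  cohort_spec(n_patients = n, seed = seed, slope_below = 0, slope_above = 0,
              intercept = qlogis(prev), missing_rates = c())
}

# 12-row toy cohort with values chosen for hand computation
toy_cohort <- function() {
  data.frame(
    id = 1:12,
    death28 = c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 1),
    ratio = c(0.5, 0.8, 1.1, 1.4, 2.6, 2.9, 3.2, 3.5, 4.4, 5.0, 6.1, 8.0),
    age = c(60, 62, 64, 66, 68, 70, 72, 74, 50, 52, 54, 56),
    sex = factor(rep(c("male", "female"), 6), levels = c("male", "female")),
    stringsAsFactors = FALSE)
}
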