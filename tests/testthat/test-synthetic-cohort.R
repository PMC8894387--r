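test_that("flat-risk cohorts reproduce the intercept-implied prevalence", {
  co <- generate_cohort(flat_spec(50000, seed = 101, prev = 0.06))
  se <- sqrt(0.06 * 0.94 / 50000)
  expect_lt(abs(mean(co$death28) - 0.06), 3 * se)
})

test_that("identical specs give byte-identical cohorts", {
  s <- cohort_spec(n_patients = 500, seed = 7)
  expect_identical(generate_cohort(s), generate_cohort(s))
})

test_that("refitting the hinge model at the true K recovers the slopes", {
  co <- generate_cohort(hinge_spec(20000, seed = 31))
  fit <- fit_two_piecewise(co, "death28", "ratio", K = 3.3)
  b1 <- fit$fit$coefficients[["ratio"]]
  b2 <- fit$fit$coefficients[["hinge"]]
  se1 <- sqrt(fit$fit$vcov["ratio", "ratio"])
  se2 <- sqrt(fit$fit$vcov["hinge", "hinge"])
  expect_lt(abs(b1 - log(0.60)), 2 * se1)
  expect_lt(abs((b1 + b2) - log(1.28)), 2 * sqrt(se1^2 + se2^2 +
                                                   2 * fit$fit$vcov["ratio", "hinge"]))
})

test_that("raising the above-K slope raises mortality above K at fixed seed", {
  lo <- generate_cohort(hinge_spec(20000, seed = 55, or_above = 1.1))
  hi <- generate_cohort(hinge_spec(20000, seed = 55, or_above = 1.8))
  expect_identical(lo$ratio, hi$ratio)  # same exposure stream
  expect_gt(mean(hi$death28[hi$ratio > 3.3]), mean(lo$death28[lo$ratio > 3.3]))
})

test_that("exposure distribution matches its calibrated moments and range", {
  co <- generate_cohort(hinge_spec(50000, seed = 77))
  expect_true(all(co$ratio >= 0.28 & co$ratio <= 10))
  expect_lt(abs(mean(co$ratio) - 3.43), 0.05)
  expect_lt(abs(sd(co$ratio) - 2.01), 0.05)
})

test_that("14-day deaths are a thinning of 28-day deaths", {
  co <- generate_cohort(cohort_spec(n_patients = 5000, seed = 13))
  expect_true(all(co$death14 <= co$death28))
  p14 <- mean(co$death14[co$death28 == 1])
  expect_lt(abs(p14 - 0.7), 3 * sqrt(0.7 * 0.3 / sum(co$death28)))
})

test_that("MCAR injection hits the requested rate within binomial noise", {
  co <- generate_cohort(hinge_spec(724, seed = 9))
  co2 <- inject_missingness(co, c(lactate = 0.283), seed = 42)
  n_miss <- sum(is.na(co2$lactate))
  expect_lt(abs(n_miss - 724 * 0.283), 3 * sqrt(724 * 0.283 * 0.717))
  expect_false(anyNA(co2$ratio))
  expect_false(anyNA(co2$death28))
})

test_that("missingness rates are validated and exposure/outcome protected", {
  co <- generate_cohort(hinge_spec(100, seed = 1))
  expect_identical(inject_missingness(co, c(), seed = 1), co)
  expect_error(inject_missingness(co, c(lactate = 1.0), seed = 1), "\\[0, 1\\)")
  expect_error(inject_missingness(co, c(ratio = 0.1), seed = 1),
               "exposure/outcome")
  expect_error(inject_missingness(co, c(death28 = 0.1), seed = 1),
               "exposure/outcome")
  expect_error(cohort_spec(missing_rates = c(ratio = 0.2)), "missing_rates")
})

test_that("MAR tilt preserves the mean rate but tracks the driver", {
  co <- generate_cohort(hinge_spec(20000, seed = 3))
  co2 <- inject_missingness(co, c(lactate = 0.3), seed = 8, mar_by = "age")
  miss <- is.na(co2$lactate)
  expect_lt(abs(mean(miss) - 0.3), 0.02)
  old <- co$age > median(co$age)
  expect_gt(mean(miss[old]), mean(miss[!old]))
})

test_that("invalid specs fail naming the offending field", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(turning_point_K = 11), "turning_point_K")
  expect_error(cohort_spec(turning_point_K = 0.1), "turning_point_K")
  expect_error(cohort_spec(death14_given_death28 = 1.5), "death14")
  expect_error(cohort_spec(seed = NULL), "seed")
})

test_that("intercept calibration hits the target marginal prevalence", {
  b0 <- calibrate_intercept(target_prev = 0.0594)
  co <- generate_cohort(hinge_spec(100000, seed = 19, intercept = b0))
  expect_lt(abs(mean(co$death28) - 0.0594), 3 * sqrt(0.0594 * 0.9406 / 1e5))
})

test_that("cohort CSV round-trips exactly, missing values as empty fields", {
  co <- generate_cohort(cohort_spec(n_patients = 300, seed = 23))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  raw <- readLines(path, n = 5)
  expect_false(any(grepl("NA", raw, fixed = TRUE)))
  back <- read_cohort(path)
  attr(co, "true_logit") <- NULL
  expect_equal(back, co, tolerance = 0)
  expect_identical(back$ratio, co$ratio)  # bit-exact doubles
})

test_that("cohort spec YAML round-trips and demands a seed", {
  s <- hinge_spec(250, seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(s, path)
  s2 <- read_cohort_spec(path)
  expect_identical(generate_cohort(s2)$death28, generate_cohort(s)$death28)
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_patients = 10), bad)
  expect_error(read_cohort_spec(bad), "seed")
})
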