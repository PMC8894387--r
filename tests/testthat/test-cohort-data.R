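# brute-force tertile oracle: enumerate all cut-value pairs under the
# ties-to-lower labelling rule and pick the most balanced partition
brute_tertiles <- function(values) {
  n <- length(values)
  uv <- sort(unique(values))
  best <- NULL
  best_dev <- Inf
  for (c1 in uv) for (c2 in uv[uv >= c1]) {
    counts <- c(sum(values <= c1), sum(values > c1 & values <= c2),
                sum(values > c2))
    dev <- max(abs(counts - n / 3))
    if (dev < best_dev) {
      best_dev <- dev
      best <- counts
    }
  }
  best
}

test_that("exact thirds split 1..9 into 3/3/3 in order", {
  t <- assign_tertiles(1:9)
  expect_equal(t$counts, c(3, 3, 3))
  expect_equal(as.character(t$labels), rep(c("T1", "T2", "T3"), each = 3))
  expect_equal(t$boundaries, c(3, 6))
})

test_that("724 distinct values split 241/241/242 (remainder to top group)", {
  x <- qlnorm(seq(0.001, 0.999, length.out = 724), 1, 0.5)
  expect_equal(assign_tertiles(x)$counts, c(241, 241, 242))
})

test_that("tied values match the brute-force balanced partition", {
  vals <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  expect_equal(assign_tertiles(vals)$counts, brute_tertiles(vals))
  expect_equal(assign_tertiles(vals)$counts, c(3, 3, 4))
  # with distinct values the nearest-rank rule is as balanced as the best
  # achievable cut-value partition (sizes differ by at most 1)
  for (seed in 1:5) {
    set.seed(seed)
    v <- sample(seq(0.1, 50, by = 0.1), 31)
    got <- assign_tertiles(v)$counts
    expect_equal(sum(got), 31)
    expect_lte(diff(range(got)), 1)
    expect_equal(max(abs(got - 31 / 3)), max(abs(brute_tertiles(v) - 31 / 3)),
                 info = paste("seed", seed))
  }
})

test_that("tertile labels are permutation-equivariant", {
  set.seed(2)
  x <- rlnorm(101)
  perm <- sample(101)
  t1 <- assign_tertiles(x)
  t2 <- assign_tertiles(x[perm])
  expect_identical(t2$labels, t1$labels[perm])
})

test_that("degenerate tertile inputs are rejected", {
  expect_error(assign_tertiles(c(1, 2)), "at least 3")
  expect_error(assign_tertiles(rep(5, 10)), "constant")
  expect_error(assign_tertiles(c(1, NA, 3, 4)), "missing")
})

test_that("missing-indicator method: indicator above 1%, mean fill, exact mean preservation", {
  set.seed(4)
  co <- data.frame(death28 = rbinom(200, 1, 0.1), ratio = rlnorm(200),
                   lactate = rlnorm(200), sofa = rpois(200, 3))
  co$lactate[sample(200, 57)] <- NA  # 28.5% missing
  obs_mean <- mean(co$lactate, na.rm = TRUE)
  out <- add_missing_dummies(co)
  expect_true("lactate_missing" %in% names(out))
  expect_false(anyNA(out$lactate))
  expect_equal(sum(out$lactate_missing), 57)
  expect_identical(mean(out$lactate[out$lactate_missing == 0]), obs_mean)
  expect_identical(out$sofa, co$sofa)  # untouched, no indicator
  expect_false("sofa_missing" %in% names(out))
})

test_that("exactly-1% missingness is mean-filled without an indicator", {
  co <- data.frame(death28 = rep(0:1, 50), ratio = 1:100, hr = as.numeric(1:100))
  co$hr[10] <- NA
  # independent count oracle for the strictly-greater rule
  expect_identical(sum(is.na(co$hr)) / nrow(co), 0.01)
  out <- add_missing_dummies(co, covariates = "hr")
  expect_false("hr_missing" %in% names(out))
  expect_false(anyNA(out$hr))
  expect_equal(out$hr[10], mean(co$hr, na.rm = TRUE))
})

test_that("missing-dummy guard rails hold", {
  co <- data.frame(death28 = 0:1, ratio = c(1, 2), z = c(NA_real_, NA_real_))
  expect_error(add_missing_dummies(co, covariates = "z"), "100% missing")
  expect_error(add_missing_dummies(co, covariates = "ratio"), "protected")
  expect_error(add_missing_dummies(co, threshold_fraction = 0), "threshold")
})

test_that("design matrices expand categoricals to k-1 indicators with declared reference", {
  set.seed(6)
  n <- 30
  co <- data.frame(
    death28 = rbinom(n, 1, 0.4), ratio = rlnorm(n), age = rnorm(n, 60, 10),
    site = factor(sample(c("pulmonary", "renal/UTI", "GI", "unknown",
                           "cutaneous/soft tissue", "other"), n, TRUE)))
  d <- build_design(co, outcome = "death28", continuous = c("ratio", "age"),
                    categorical = list(site = "pulmonary"),
                    hinge_terms = c(ratio = 3.3))
  # intercept + 2 continuous + 5 site indicators + 1 hinge
  expect_equal(ncol(d$X), 1 + 2 + 5 + 1)
  expect_equal(d$reference_levels$site, "pulmonary")
  expect_false(any(grepl("pulmonary", colnames(d$X))))
  expect_equal(d$X[, "ratio_hinge"], pmax(co$ratio - 3.3, 0))
  expect_true(all(d$X[, grepl("^site:", colnames(d$X))] %in% 0:1))
  expect_false(anyNA(d$X))
  expect_equal(nrow(d$X), n)  # no silent row dropping
})

test_that("unknown columns and levels are errors naming the offender", {
  co <- data.frame(death28 = 0:1, ratio = c(1, 2),
                   sex = factor(c("male", "female")))
  expect_error(build_design(co, "death28", continuous = "bmi"), "bmi")
  expect_error(build_design(co, "death28", categorical = list(sex = "other")),
               "other")
})

test_that("exposure missingness is an exclusion with a logged count", {
  co <- data.frame(death28 = rep(0, 5), ratio = c(1, NA, 3, NA, 5))
  expect_message(out <- exclude_missing_exposure(co), "2 row")
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_excluded"), 2)
})
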