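test_that("hinge transform makes the piecewise logit continuous at K", {
  expect_equal(hinge(3.3, 3.3), 0)
  expect_equal(hinge(c(1, 3.3, 5), 3.3), c(0, 0, 1.7))
  # left/right limits of the fitted logit at K agree
  co <- generate_cohort(hinge_spec(3000, seed = 71))
  fit <- fit_two_piecewise(co, "death28", "ratio", K = 3.3)
  b <- fit$fit$coefficients
  lp <- function(x) b[["intercept"]] + b[["ratio"]] * x + b[["hinge"]] * hinge(x, 3.3)
  eps <- 1e-9
  expect_lt(abs(lp(3.3 - eps) - lp(3.3 + eps)), 1e-7)
})

test_that("no-threshold data give matching segment ORs and a null hinge", {
  co <- generate_cohort(linear_spec(20000, seed = 73, or_unit = 1.1))
  fit <- fit_two_piecewise(co, "death28", "ratio", K = 3.3)
  b2 <- fit$fit$coefficients[["hinge"]]
  se2 <- sqrt(fit$fit$vcov["hinge", "hinge"])
  expect_lt(abs(b2), 2 * se2)
})

test_that("delta-method above-segment CI matches a reparameterized refit", {
  co <- generate_cohort(hinge_spec(5000, seed = 79))
  K <- 3.3
  fit <- fit_two_piecewise(co, "death28", "ratio", K = K)
  # reparameterize: logit = a + g1*min(x,K) + g2*(x-K)+ ; g2 is the above
  # slope directly, so its Wald SE must equal the delta-method SE
  X <- cbind(intercept = 1, below = pmin(co$ratio, K),
             above = hinge(co$ratio, K))
  refit <- fit_logistic(X, co$death28)
  se_above_direct <- sqrt(refit$vcov["above", "above"])
  v <- fit$fit$vcov
  se_above_delta <- sqrt(v["ratio", "ratio"] + v["hinge", "hinge"] +
                           2 * v["ratio", "hinge"])
  expect_equal(se_above_delta, se_above_direct, tolerance = 1e-6)
  expect_equal(fit$or_above[["or"]],
               exp(refit$coefficients[["above"]]), tolerance = 1e-6)
})

test_that("turning-point search equals an exhaustive glm-based profile", {
  co <- generate_cohort(hinge_spec(2000, seed = 83))
  res <- search_turning_point(co, "death28", "ratio")
  # independent code path: glm at every candidate
  prof <- vapply(res$profile$K, function(k) {
    as.numeric(logLik(glm(death28 ~ ratio + pmax(ratio - k, 0),
                          family = binomial, data = co)))
  }, numeric(1))
  expect_equal(res$profile$loglik, prof, tolerance = 1e-6)
  expect_equal(res$K_hat, res$profile$K[which.max(prof)])
  expect_equal(max(res$profile$loglik, na.rm = TRUE),
               res$profile$loglik[res$profile$K == res$K_hat])
})

test_that("segment preconditions are enforced", {
  co <- generate_cohort(hinge_spec(500, seed = 87))
  expect_error(fit_two_piecewise(co, "death28", "ratio", K = 12), "range")
  k_small <- sort(co$ratio)[10]  # only 9 observations strictly below
  expect_error(fit_two_piecewise(co, "death28", "ratio", K = k_small,
                                 min_seg = 20), "observations")
  expect_error(search_turning_point(co, "death28", "ratio",
                                    grid = c(5.0, 5.1)), "candidates")
})

test_that("LRT follows the chi-squared reference distribution", {
  f <- list(log_likelihood = -100)
  expect_equal(unname(lrt_one_vs_two(f, f)[c("statistic", "p")]), c(0, 1))
  g <- list(log_likelihood = -100 + 3.841 / 2)
  expect_equal(round(lrt_one_vs_two(f, g)[["p"]], 3), 0.050)
  h <- list(log_likelihood = -100 + 5.170 / 2)
  expect_equal(round(lrt_one_vs_two(f, h)[["p"]], 3), 0.023)
  worse <- list(log_likelihood = -101)
  expect_error(lrt_one_vs_two(f, worse), "negative")
})

test_that("two-piecewise likelihood is never below the nested one-line model", {
  for (seed in c(91, 92, 93)) {
    co <- generate_cohort(hinge_spec(1500, seed = seed))
    one <- fit_one_line(co, "death28", "ratio")
    srch <- search_turning_point(co, "death28", "ratio")
    expect_gte(srch$fit$fit$log_likelihood, one$fit$log_likelihood - 1e-8)
    lrt <- lrt_one_vs_two(one$fit, srch$fit$fit)
    expect_gte(lrt[["statistic"]], 0)
  }
})

test_that("per-SD rescaling and standardization are the stated closed forms", {
  expect_equal(round(per_sd_or(0.60, 2.01), 2), 0.36)
  expect_equal(round(per_sd_or(1.28, 2.01), 2), 1.64)
  expect_equal(round(per_sd_or(1.04, 2.01), 2), 1.08)
  expect_equal(per_sd_or(1.00, 5), 1.00)
  v <- c(or = 0.60, lower = 0.37, upper = 0.99, p = 0.043)
  out <- per_sd_or(v, 2.01)
  expect_equal(round(unname(out["or"]), 2), 0.36)
  expect_equal(out[["p"]], 0.043)  # p carried through untouched
  expect_error(per_sd_or(-1, 2), "positive")
  expect_equal(round(standardize_value(2.9, 3.43, 2.01), 2), -0.26)
  expect_equal(round(standardize_value(3.9, 3.43, 2.01), 2), 0.23)
  expect_equal(standardize_value(3.43, 3.43, 2.01), 0)
  expect_error(standardize_value(1, 0, -1), "positive")
})

test_that("bootstrap contract: minimum size, mandatory seed, determinism", {
  co <- generate_cohort(hinge_spec(600, seed = 97))
  expect_error(bootstrap_turning_point_ci(co, "death28", "ratio", n_boot = 2,
                                          seed = 1), "at least 100")
  expect_error(bootstrap_turning_point_ci(co, "death28", "ratio",
                                          n_boot = 100), "seed")
  b1 <- bootstrap_turning_point_ci(co, "death28", "ratio", n_boot = 100,
                                   seed = 5)
  b2 <- bootstrap_turning_point_ci(co, "death28", "ratio", n_boot = 100,
                                   seed = 5)
  expect_identical(b1, b2)
  expect_true(b1$lower <= b1$upper)
})

test_that("full threshold analysis is internally consistent", {
  co <- generate_cohort(hinge_spec(2000, seed = 99))
  res <- threshold_effect(co, "death28", "ratio", n_boot = 0)
  expect_s3_class(res, "threshold_result")
  expect_true(res$K_hat %in% res$grid)
  expect_equal(res$profile_loglik[res$grid == res$K_hat],
               max(res$profile_loglik, na.rm = TRUE))
  expect_equal(res$lrt_statistic,
               2 * (res$fit_two$log_likelihood - res$fit_one$log_likelihood),
               tolerance = 1e-10)
  expect_equal(res$sd_used, sd(co$ratio))
  expect_equal(res$K_hat_sd,
               (res$K_hat - mean(co$ratio)) / sd(co$ratio))
  # per-SD one-line OR is the per-unit OR to the power of the SD
  expect_equal(res$one_line_or_sd[["or"]],
               res$one_line_or[["or"]]^res$sd_used)
  expect_error(threshold_effect(co, "death28", "ratio", n_boot = 100),
               "seed")
  out <- capture.output(print(res))
  expect_true(any(grepl("Turning point", out)))
  js <- threshold_result_json(res)
  expect_equal(js$K_hat, res$K_hat)
})
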