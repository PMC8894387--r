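test_that("intercept-only MLE equals the closed-form log-odds and likelihood", {
  y <- c(rep(1, 43), rep(0, 681))
  X <- cbind(intercept = rep(1, 724))
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coefficients), log(43 / 681), tolerance = 1e-9)
  p <- 43 / 724
  expect_equal(fit$log_likelihood, 43 * log(p) + 681 * log(1 - p),
               tolerance = 1e-9)
  expect_true(fit$converged)
  expect_lte(fit$log_likelihood, 0)
})

test_that("logistic slope on a binary contrast equals the 2x2 log odds ratio", {
  # middle-vs-low tertile contrast from published counts
  y <- c(rep(1, 8), rep(0, 233), rep(1, 17), rep(0, 224))
  x <- c(rep(1, 241), rep(0, 241))
  fit <- fit_logistic(cbind(intercept = 1, middle = x), y)
  ors <- odds_ratios(fit)
  mid <- ors[ors$term == "middle", ]
  expect_equal(round(c(mid$or, mid$lower, mid$upper), 2), c(0.45, 0.19, 1.07))
  direct <- odds_ratio_2x2(8, 233, 17, 224)
  expect_equal(mid$or, unname(direct["or"]), tolerance = 1e-8)
  expect_equal(mid$lower, unname(direct["lower"]), tolerance = 1e-8)
})

test_that("slope equals ln(ad/bc) on random all-positive 2x2 data", {
  set.seed(31)
  for (i in 1:20) {
    cts <- sample(5:80, 4)  # a, b, c, d all positive
    y <- rep(c(1, 0, 1, 0), cts)
    x <- rep(c(1, 1, 0, 0), cts)
    fit <- fit_logistic(cbind(intercept = 1, x = x), y)
    expect_equal(unname(fit$coefficients["x"]),
                 log(cts[1] * cts[4] / (cts[2] * cts[3])), tolerance = 1e-8)
  }
})

test_that("estimates and covariance agree with glm as an independent oracle", {
  set.seed(41)
  n <- 800
  d <- data.frame(x = rnorm(n), z = rlnorm(n))
  d$y <- rbinom(n, 1, plogis(-1.5 + 0.8 * d$x - 0.2 * d$z))
  X <- cbind(intercept = 1, x = d$x, z = d$z)
  fit <- fit_logistic(X, d$y)
  ref <- glm(y ~ x + z, family = binomial, data = d,
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("final score is below tolerance and vcov is symmetric PSD", {
  set.seed(43)
  X <- cbind(intercept = 1, x = rnorm(300))
  y <- rbinom(300, 1, plogis(X[, 2]))
  fit <- fit_logistic(X, y)
  mu <- plogis(drop(X %*% fit$coefficients))
  expect_lt(max(abs(crossprod(X, y - mu))), 1e-8)
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > 0))
})

test_that("affine rescaling of a predictor rescales its coefficient inversely", {
  set.seed(47)
  x <- rlnorm(500)
  y <- rbinom(500, 1, plogis(-1 + 0.5 * x))
  f1 <- fit_logistic(cbind(intercept = 1, x = x), y)
  f2 <- fit_logistic(cbind(intercept = 1, x = x / 10), y)
  expect_equal(unname(f1$coefficients["x"]) * 10,
               unname(f2$coefficients["x"]), tolerance = 1e-8)
})

test_that("separation and rank deficiency are explicit errors", {
  x <- rep(0:1, each = 25)
  expect_error(fit_logistic(cbind(intercept = 1, x = x), x), "separation")
  X <- cbind(intercept = 1, a = rnorm(50), b = NA)
  X[, "b"] <- 2 * X[, "a"]
  y <- rbinom(50, 1, 0.5)
  expect_error(fit_logistic(X, y), "b")
  expect_error(fit_logistic(cbind(intercept = 1, x = rnorm(20)), rep(0, 20)),
               "single class")
})

test_that("odds_ratios transforms coefficients as the Wald formula dictates", {
  set.seed(53)
  X <- cbind(intercept = 1, x = rnorm(400))
  y <- rbinom(400, 1, 0.3)
  fit <- fit_logistic(X, y)
  ors <- odds_ratios(fit)
  i <- which(ors$term == "x")
  se <- sqrt(fit$vcov["x", "x"])
  est <- fit$coefficients[["x"]]
  z <- qnorm(0.975)
  expect_equal(ors$or[i], exp(est))
  expect_equal(ors$lower[i], exp(est - z * se), tolerance = 1e-10)
  expect_equal(ors$upper[i], exp(est + z * se), tolerance = 1e-10)
  expect_equal(ors$p[i], 2 * pnorm(-abs(est / se)), tolerance = 1e-12)
  # null coefficient: OR 1, CI symmetric about 1 on the log scale
  expect_equal(log(ors$lower[i]) + log(ors$upper[i]), 2 * est,
               tolerance = 1e-10)
})

test_that("confounder screen selects by the 10% change-in-estimate rule", {
  set.seed(61)
  n <- 10000
  z <- rnorm(n)                      # confounder: drives exposure and outcome
  x <- 1.2 * z + rnorm(n)
  noise <- rnorm(n)                  # independent of everything
  y <- rbinom(n, 1, plogis(-2.5 + 1.0 * z))
  d <- data.frame(y = y, x = x, z = z, noise = noise)
  scr <- screen_confounders(d, "y", "x", candidates = c("z", "noise"))
  expect_true(scr$selected[scr$candidate == "z"])
  expect_false(scr$selected[scr$candidate == "noise"])
  expect_lt(scr$rel_change[scr$candidate == "noise"], 0.02)
  expect_identical(attr(scr, "selected"), "z")
  empty <- screen_confounders(d, "y", "x", candidates = character())
  expect_equal(nrow(empty), 0)
  expect_length(attr(empty, "selected"), 0)
})
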