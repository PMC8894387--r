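# Threshold-effect analysis: one-line vs two-piecewise logistic models,
# profile-likelihood turning-point search, likelihood-ratio test for
# non-linearity, bootstrap percentile CI for the turning point, per-SD
# rescaling.
#
# The two-piecewise model parameterizes the exposure as
#   logit p = b0 + b1 * x + b2 * (x - K)+ + covariates
# so the logit is continuous at K; the per-unit OR below K is exp(b1) and
# above K is exp(b1 + b2), with the above-segment CI from the delta method
# (var = V11 + V22 + 2 V12).

default_grid <- function(x, step = 0.1, probs = c(0.05, 0.95)) {
  q <- stats::quantile(x, probs, type = 7, names = FALSE)
  lo <- ceiling(q[1] / step) * step
  hi <- floor(q[2] / step) * step
  seq(lo, hi, by = step)
}

term_or <- function(est, se, conf) {
  z <- z_crit(conf)
  c(or = exp(est), lower = exp(est - z * se), upper = exp(est + z * se),
    p = 2 * stats::pnorm(-abs(est / se)))
}

prepare_threshold_design <- function(data, outcome, exposure, covariates) {
  is_cat <- vapply(covariates, function(nm)
    is.factor(data[[nm]]) || is.character(data[[nm]]), logical(1))
  build_design(data, outcome = outcome,
               continuous = c(exposure, covariates[!is_cat]),
               categorical = covariates[is_cat])
}

#' One-line (linear) logistic exposure model
#'
#' Fits the exposure linearly alongside the adjustment covariates and
#' reports the per-unit and per-SD odds ratios.
#'
#' @param data Cohort data frame with missingness already resolved.
#' @param outcome,exposure Column names.
#' @param covariates Adjustment covariate names (categoricals detected
#'   automatically and expanded against their first/declared level).
#' @param sd_used Exposure SD for the per-SD rescaling; default is the
#'   sample SD of the exposure.
#' @param conf Confidence level.
#' @return List with the `fit` (`logistic_fit`), `or_unit`, `or_sd`
#'   (each `c(or, lower, upper, p)`), and `sd_used`.
#' @export
fit_one_line <- function(data, outcome, exposure, covariates = character(),
                         sd_used = NULL, conf = 0.95) {
  design <- prepare_threshold_design(data, outcome, exposure, covariates)
  fit <- fit_logistic(design)
  est <- fit$coefficients[[exposure]]
  se <- sqrt(fit$vcov[exposure, exposure])
  sd_used <- sd_used %||% stats::sd(data[[exposure]])
  or_unit <- term_or(est, se, conf)
  list(fit = fit, or_unit = or_unit,
       or_sd = per_sd_or(or_unit, sd_used), sd_used = sd_used)
}

#' Two-piecewise (hinge) logistic exposure model at a fixed turning point
#'
#' @param data,outcome,exposure,covariates,sd_used,conf As [fit_one_line()].
#' @param K Turning point, strictly inside the observed exposure range.
#' @param min_seg Minimum observations required on each side of `K`
#'   (default 20).
#' @return List with `fit`, `K`, `or_below`, `or_above` (per-unit,
#'   `c(or, lower, upper, p)`), `or_below_sd`, `or_above_sd`, `sd_used`;
#'   the above-segment slope is `b1 + b2` with delta-method variance.
#' @export
fit_two_piecewise <- function(data, outcome, exposure, K,
                              covariates = character(), min_seg = 20L,
                              sd_used = NULL, conf = 0.95) {
  x <- data[[exposure]]
  if (K <= min(x) || K >= max(x)) {
    stop("K = ", K, " lies outside the observed exposure range")
  }
  n_below <- sum(x < K); n_above <- sum(x >= K)
  if (n_below < min_seg || n_above < min_seg) {
    stop("fewer than ", min_seg, " observations on one side of K = ", K)
  }
  design <- prepare_threshold_design(data, outcome, exposure, covariates)
  hcol <- hinge(x, K)
  design$X <- cbind(design$X, hinge = hcol)
  fit <- fit_logistic(design)
  b1 <- fit$coefficients[[exposure]]
  b2 <- fit$coefficients[["hinge"]]
  v <- fit$vcov
  se_below <- sqrt(v[exposure, exposure])
  se_above <- sqrt(v[exposure, exposure] + v["hinge", "hinge"] +
                     2 * v[exposure, "hinge"])
  sd_used <- sd_used %||% stats::sd(x)
  or_below <- term_or(b1, se_below, conf)
  or_above <- term_or(b1 + b2, se_above, conf)
  list(fit = fit, K = K,
       or_below = or_below, or_above = or_above,
       or_below_sd = per_sd_or(or_below, sd_used),
       or_above_sd = per_sd_or(or_above, sd_used),
       sd_used = sd_used)
}

#' Profile-likelihood search for the turning point
#'
#' Fits the two-piecewise model at every candidate K on a grid (default:
#' 5th to 95th exposure percentile in steps of 0.1) and returns the K with
#' maximum log-likelihood together with the full profile. Ties are broken
#' toward the smallest K with a warning. Candidates violating the
#' minimum-segment-size rule are dropped.
#'
#' @inheritParams fit_two_piecewise
#' @param grid Numeric vector of candidate K values; `NULL` uses the
#'   default grid.
#' @param step Grid step when `grid` is `NULL` (default 0.1).
#' @return List `K_hat`, `profile` (data frame `K`, `loglik`), `fit` (the
#'   two-piecewise fit at `K_hat`).
#' @export
search_turning_point <- function(data, outcome, exposure,
                                 covariates = character(), grid = NULL,
                                 step = 0.1, min_seg = 20L, conf = 0.95,
                                 sd_used = NULL, refit = TRUE) {
  x <- data[[exposure]]
  if (is.null(grid)) grid <- default_grid(x, step = step)
  grid <- grid[vapply(grid, function(k)
    sum(x < k) >= min_seg && sum(x >= k) >= min_seg && k > min(x) && k < max(x),
    logical(1))]
  if (length(grid) < 3L) stop("fewer than 3 admissible turning-point candidates")
  design <- prepare_threshold_design(data, outcome, exposure, covariates)
  Xbase <- design$X
  y <- design$response
  p_base <- ncol(Xbase)
  X <- cbind(Xbase, hinge = numeric(nrow(Xbase)))
  loglik <- rep(NA_real_, length(grid))
  start <- NULL
  for (i in seq_along(grid)) {
    X[, p_base + 1L] <- hinge(x, grid[i])
    res <- tryCatch(irls_logit(X, y, start = start),
                    error = function(e) NULL)
    if (!is.null(res) && res$converged) {
      loglik[i] <- res$log_likelihood
      start <- res$coefficients  # warm start: neighbour K differs little
    } else {
      start <- NULL
    }
  }
  if (all(is.na(loglik))) stop("all candidate two-piecewise fits failed")
  best <- max(loglik, na.rm = TRUE)
  idx <- which(loglik == best)
  if (length(idx) > 1L) {
    warning("profile log-likelihood tied at ", length(idx),
            " candidates; taking the smallest K")
  }
  K_hat <- grid[min(idx)]
  list(K_hat = K_hat,
       profile = data.frame(K = grid, loglik = loglik),
       fit = if (refit)
         fit_two_piecewise(data, outcome, exposure, K = K_hat,
                           covariates = covariates, min_seg = min_seg,
                           conf = conf, sd_used = sd_used))
}

#' Likelihood-ratio test of one-line vs two-piecewise model
#'
#' `statistic = 2 * (loglik_twopiece - loglik_oneline)` referred to a
#' chi-squared with `df` degrees of freedom. By convention `df = 1` (the
#' hinge coefficient), which does not account for the searched turning
#' point and is therefore anti-conservative under the linear null; this is
#' measured, documented behaviour, not corrected silently.
#'
#' @param fit_one,fit_two `logistic_fit` objects for the nested pair
#'   (same covariates; `fit_two` adds the hinge term).
#' @param df Degrees of freedom (default 1).
#' @return Named vector `c(statistic, df, p)`.
#' @export
lrt_one_vs_two <- function(fit_one, fit_two, df = 1L) {
  stat <- 2 * (fit_two$log_likelihood - fit_one$log_likelihood)
  if (stat < -1e-6) {
    stop("negative LRT statistic (", fmt_num(stat, 6),
         "): the two-piecewise fit has lower likelihood than the nested ",
         "one-line model, indicating a fitting failure")
  }
  stat <- max(stat, 0)
  c(statistic = stat, df = df,
    p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Bootstrap percentile CI for the turning point
#'
#' Resamples patients with replacement `n_boot` times, reruns the full
#' profile-likelihood grid search on each resample, and returns the 2.5 and
#' 97.5 percentiles of the resampled turning points. Resamples whose search
#' fails (e.g. separation) are dropped and counted; more than 10% failures
#' is an error.
#'
#' @inheritParams search_turning_point
#' @param n_boot Number of resamples (default 500, minimum 100).
#' @param seed Integer seed (mandatory; same seed gives identical CIs).
#' @param conf Confidence level for the percentile interval.
#' @return List `lower`, `upper`, `K_hats` (resample distribution),
#'   `n_failed`.
#' @export
bootstrap_turning_point_ci <- function(data, outcome, exposure,
                                       covariates = character(),
                                       n_boot = 500L, seed,
                                       grid = NULL, step = 0.1,
                                       min_seg = 20L, conf = 0.95) {
  if (n_boot < 100L) stop("n_boot must be at least 100")
  if (missing(seed)) stop("a seed is mandatory for the bootstrap")
  n <- nrow(data)
  data <- data[, unique(c(outcome, exposure, covariates)), drop = FALSE]
  K_hats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(
        search_turning_point(data[idx, , drop = FALSE], outcome, exposure,
                             covariates = covariates, grid = grid,
                             step = step, min_seg = min_seg, refit = FALSE),
        error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$K_hat
    }, numeric(1))
  })
  n_failed <- sum(is.na(K_hats))
  if (n_failed > 0.10 * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap searches failed (> 10%)")
  }
  alpha <- 1 - conf
  qs <- stats::quantile(K_hats, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        type = 7, names = FALSE)
  list(lower = qs[1], upper = qs[2], K_hats = K_hats, n_failed = n_failed)
}

#' Rescale a per-unit odds ratio to per-SD
#'
#' A log-linear effect of `log OR` per unit corresponds to `sd * log OR`
#' per standard deviation, i.e. `OR^sd`; confidence bounds transform
#' identically.
#'
#' @param or_unit Named vector with at least `or`, `lower`, `upper`
#'   (a `p` element is carried through unchanged), or a single OR.
#' @param sd Exposure standard deviation (> 0).
#' @return Same shape as `or_unit`, on the per-SD scale.
#' @examples
#' per_sd_or(0.60, 2.01)  # 0.36
#' @export
per_sd_or <- function(or_unit, sd) {
  if (sd <= 0) stop("sd must be positive")
  if (is.null(names(or_unit))) {
    if (any(or_unit <= 0)) stop("odds ratios must be positive")
    return(or_unit^sd)
  }
  out <- or_unit
  for (nm in intersect(names(out), c("or", "lower", "upper"))) {
    if (out[[nm]] <= 0) stop("odds ratios must be positive")
    out[[nm]] <- out[[nm]]^sd
  }
  out
}

#' Standardize a value to z-score units
#'
#' @param v Value(s) on the raw scale.
#' @param mean,sd Centering and scaling constants (`sd > 0`).
#' @return `(v - mean) / sd`.
#' @examples
#' standardize_value(2.9, 3.43, 2.01)  # -0.26
#' @export
standardize_value <- function(v, mean, sd) {
  if (sd <= 0) stop("sd must be positive")
  (v - mean) / sd
}

#' Full threshold-effect analysis
#'
#' Runs the complete inference: one-line model, profile-likelihood search
#' for the turning point, two-piecewise model at the estimate,
#' likelihood-ratio test of non-linearity, bootstrap percentile CI for the
#' turning point, and per-unit / per-SD reporting (the SD and mean used for
#' standardization are the full-cohort sample statistics of the exposure).
#'
#' @inheritParams search_turning_point
#' @param n_boot Bootstrap resamples for the turning-point CI (default 500);
#'   `0` skips the bootstrap (e.g. for quick exploration).
#' @param seed Seed for the bootstrap (mandatory when `n_boot > 0`).
#' @return An object of class `threshold_result` with fields `K_hat`,
#'   `K_ci`, `K_hat_sd`, `K_ci_sd` (standardized), `or_below`, `or_above`,
#'   `or_below_sd`, `or_above_sd`, `one_line_or`, `one_line_or_sd`,
#'   `lrt_statistic`, `lrt_p`, `grid`, `profile_loglik`, `sd_used`,
#'   `mean_used`, `n_boot`, `seed`, `n_obs`, plus the underlying fits.
#' @export
threshold_effect <- function(data, outcome, exposure,
                             covariates = character(), grid = NULL,
                             step = 0.1, min_seg = 20L, n_boot = 500L,
                             seed = NULL, conf = 0.95) {
  x <- data[[exposure]]
  sd_used <- stats::sd(x)
  mean_used <- mean(x)
  one <- fit_one_line(data, outcome, exposure, covariates,
                      sd_used = sd_used, conf = conf)
  srch <- search_turning_point(data, outcome, exposure, covariates,
                               grid = grid, step = step, min_seg = min_seg,
                               conf = conf, sd_used = sd_used)
  two <- srch$fit
  lrt <- lrt_one_vs_two(one$fit, two$fit)
  K_ci <- c(NA_real_, NA_real_)
  boot <- NULL
  if (n_boot > 0L) {
    if (is.null(seed)) stop("a seed is mandatory when n_boot > 0")
    boot <- bootstrap_turning_point_ci(data, outcome, exposure, covariates,
                                       n_boot = n_boot, seed = seed,
                                       grid = grid, step = step,
                                       min_seg = min_seg, conf = conf)
    K_ci <- c(boot$lower, boot$upper)
    if (!is.na(K_ci[1]) && (K_ci[1] > srch$K_hat || K_ci[2] < srch$K_hat)) {
      warning("percentile CI does not contain the point estimate of the ",
              "turning point; inspect the bootstrap distribution")
    }
  }
  structure(list(
    K_hat = srch$K_hat, K_ci = K_ci,
    K_hat_sd = standardize_value(srch$K_hat, mean_used, sd_used),
    K_ci_sd = standardize_value(K_ci, mean_used, sd_used),
    or_below = two$or_below, or_above = two$or_above,
    or_below_sd = two$or_below_sd, or_above_sd = two$or_above_sd,
    one_line_or = one$or_unit, one_line_or_sd = one$or_sd,
    lrt_statistic = unname(lrt["statistic"]), lrt_p = unname(lrt["p"]),
    grid = srch$profile$K, profile_loglik = srch$profile$loglik,
    sd_used = sd_used, mean_used = mean_used,
    n_boot = if (is.null(boot)) 0L else n_boot,
    n_boot_failed = if (is.null(boot)) 0L else boot$n_failed,
    seed = seed, n_obs = nrow(data),
    fit_one = one$fit, fit_two = two$fit,
    bootstrap_K = if (is.null(boot)) NULL else boot$K_hats),
    class = "threshold_result")
}

or_cell <- function(v, digits = 2) {
  sprintf("%s (%s, %s)", fmt_num(v[["or"]], digits),
          fmt_num(v[["lower"]], digits), fmt_num(v[["upper"]], digits))
}

#' @export
print.threshold_result <- function(x, digits = 2, ...) {
  cat("Threshold effect analysis (n =", x$n_obs, ")\n")
  cat(sprintf("%-34s %-22s %-8s %-22s %s\n", "", "Per-unit OR (95% CI)", "P",
              "Per-SD OR (95% CI)", "P"))
  row <- function(lab, unit, sdv) {
    cat(sprintf("%-34s %-22s %-8s %-22s %s\n", lab, or_cell(unit, digits),
                fmt_num(unit[["p"]], 3), or_cell(sdv, digits),
                fmt_num(sdv[["p"]], 3)))
  }
  cat("Model I\n")
  row("  One line effect", x$one_line_or, x$one_line_or_sd)
  cat("Model II\n")
  cat(sprintf("  Turning point (K): %s (standardized %s)\n",
              fmt_num(x$K_hat, 1), fmt_num(x$K_hat_sd, 2)))
  row("  Exposure < K", x$or_below, x$or_below_sd)
  row("  Exposure >= K", x$or_above, x$or_above_sd)
  cat(sprintf("  P for LRT (one-line vs two-piecewise): %s\n",
              fmt_num(x$lrt_p, 3)))
  if (!is.na(x$K_ci[1])) {
    cat(sprintf("  95%% bootstrap CI for K: %s, %s (standardized %s, %s; B = %d)\n",
                fmt_num(x$K_ci[1], 1), fmt_num(x$K_ci[2], 1),
                fmt_num(x$K_ci_sd[1], 2), fmt_num(x$K_ci_sd[2], 2),
                x$n_boot))
  }
  invisible(x)
}

#' Serialize a threshold result to a plain list (for JSON)
#'
#' @param x A `threshold_result`.
#' @return Nested list of plain numbers suitable for
#'   `jsonlite::write_json`.
#' @export
threshold_result_json <- function(x) {
  orl <- function(v) as.list(v)
  list(K_hat = x$K_hat, K_ci = x$K_ci, K_hat_sd = x$K_hat_sd,
       K_ci_sd = x$K_ci_sd,
       one_line_or = orl(x$one_line_or), one_line_or_sd = orl(x$one_line_or_sd),
       or_below = orl(x$or_below), or_above = orl(x$or_above),
       or_below_sd = orl(x$or_below_sd), or_above_sd = orl(x$or_above_sd),
       lrt_statistic = x$lrt_statistic, lrt_p = x$lrt_p,
       sd_used = x$sd_used, mean_used = x$mean_used,
       n_boot = x$n_boot, n_boot_failed = x$n_boot_failed,
       seed = x$seed, n_obs = x$n_obs)
}
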