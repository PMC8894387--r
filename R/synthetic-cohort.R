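# Synthetic ICU sepsis cohort generator.
#
# The generator produces patient-level tables with the statistical structure
# the downstream analysis assumes: a continuous lipid-ratio exposure
# (non-HDLc/HDLc) on a bounded range, a hinge-shaped (two-piecewise linear)
# logit risk of 28-day death with a turning point K, covariates on the scale
# of a real sepsis cohort, and configurable completely-at-random covariate
# missingness. Everything is driven by a single seed, so identical specs
# give byte-identical cohorts.

.calib_cache <- new.env(parent = emptyenv())

#' Calibrate a truncated lognormal to target moments
#'
#' Finds `(meanlog, sdlog)` such that a lognormal truncated to
#' `[lower, upper]` has the requested mean and standard deviation. Used to
#' give the exposure the moments of a real cohort (mean 3.43, SD 2.01 on
#' 0.28-10) when only moments and range, not a law, are known.
#'
#' @param mean,sd Target moments of the truncated distribution.
#' @param lower,upper Truncation bounds.
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
calibrate_truncated_lognormal <- function(mean = 3.43, sd = 2.01,
                                          lower = 0.28, upper = 10) {
  key <- paste0("ln:", mean, ":", sd, ":", lower, ":", upper)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  moments <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    zmass <- stats::plnorm(upper, mu, sig) - stats::plnorm(lower, mu, sig)
    m1 <- stats::integrate(function(x) x * stats::dlnorm(x, mu, sig),
                           lower, upper, rel.tol = 1e-10)$value / zmass
    m2 <- stats::integrate(function(x) x^2 * stats::dlnorm(x, mu, sig),
                           lower, upper, rel.tol = 1e-10)$value / zmass
    c(m1, sqrt(m2 - m1^2))
  }
  obj <- function(par) {
    m <- moments(par)
    (m[1] - mean)^2 + (m[2] - sd)^2
  }
  # start at the untruncated solution
  s0 <- sqrt(log(1 + (sd / mean)^2))
  fit <- stats::optim(c(log(mean) - s0^2 / 2, log(s0)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  out <- c(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
  .calib_cache[[key]] <- out
  out
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

dtrunc_lnorm <- function(x, meanlog, sdlog, lower, upper) {
  zmass <- stats::plnorm(upper, meanlog, sdlog) - stats::plnorm(lower, meanlog, sdlog)
  ifelse(x >= lower & x <= upper,
         stats::dlnorm(x, meanlog, sdlog) / zmass, 0)
}

#' Calibrate the risk-model intercept to a target prevalence
#'
#' Given the hinge-logit slopes and the exposure distribution, solves for
#' the intercept `b0` such that the marginal outcome probability
#' `E[expit(b0 + f(x))]` equals `target_prev` (default 5.94%, a typical
#' sepsis 28-day mortality).
#'
#' @param target_prev Target marginal prevalence.
#' @param turning_point_K,slope_below,slope_above Hinge-logit parameters
#'   (slopes in log-odds per exposure unit; `slope_above` is the total slope
#'   for x > K).
#' @param ratio_mean,ratio_sd,ratio_min,ratio_max Exposure distribution
#'   targets (truncated lognormal).
#' @return The intercept `b0` (log-odds).
#' @export
calibrate_intercept <- function(target_prev = 0.0594,
                                turning_point_K = 3.3,
                                slope_below = log(0.60),
                                slope_above = log(1.28),
                                ratio_mean = 3.43, ratio_sd = 2.01,
                                ratio_min = 0.28, ratio_max = 10) {
  key <- paste("b0", target_prev, turning_point_K, slope_below, slope_above,
               ratio_mean, ratio_sd, ratio_min, ratio_max, sep = ":")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  par <- calibrate_truncated_lognormal(ratio_mean, ratio_sd, ratio_min, ratio_max)
  marg <- function(b0) {
    stats::integrate(function(x) {
      lp <- b0 + slope_below * x +
        (slope_above - slope_below) * hinge(x, turning_point_K)
      expit(lp) * dtrunc_lnorm(x, par["meanlog"], par["sdlog"],
                               ratio_min, ratio_max)
    }, ratio_min, ratio_max, rel.tol = 1e-10)$value
  }
  b0 <- stats::uniroot(function(b) marg(b) - target_prev,
                       interval = c(-15, 5), tol = 1e-10)$root
  .calib_cache[[key]] <- b0
  b0
}

default_covariate_specs <- function() {
  # scales follow a published sepsis cohort's baseline table; effects on the
  # logit default to zero so the exposure-outcome model is exactly the hinge
  list(
    age = list(dist = list(type = "normal", mean = 66.7, sd = 15.0,
                           min = 18, max = 100), effect = 0),
    weight = list(dist = list(type = "normal", mean = 85.5, sd = 28.0,
                              min = 27, max = 227), effect = 0),
    heart_rate = list(dist = list(type = "normal", mean = 112, sd = 28,
                                  min = 26, max = 201), effect = 0),
    lactate = list(dist = list(type = "lognormal", meanlog = 0.65,
                               sdlog = 0.55, min = 0.4, max = 16.6),
                   effect = 0),
    apache_iv = list(dist = list(type = "normal", mean = 73.2, sd = 23.9,
                                 min = 13, max = 164), effect = 0),
    sofa = list(dist = list(type = "poisson", lambda = 3.1, max = 15),
                effect = 0),
    sex = list(dist = list(type = "categorical",
                           levels = c("male", "female"),
                           probs = c(0.539, 0.461)), effect = 0),
    septic_shock = list(dist = list(type = "bernoulli", p = 0.583),
                        effect = 0),
    infection_site = list(dist = list(
      type = "categorical",
      levels = c("pulmonary", "renal/UTI", "GI", "unknown",
                 "cutaneous/soft tissue", "other"),
      probs = c(0.431, 0.225, 0.098, 0.101, 0.080, 0.065)), effect = 0)
  )
}

#' Specification of a synthetic cohort
#'
#' Collects every generative parameter of [generate_cohort()]: sample size,
#' exposure distribution (truncated lognormal matched to mean 3.43, SD 2.01
#' on 0.28-10 by default), the hinge-logit risk model (turning point K,
#' per-unit slope below K, total per-unit slope above K, intercept),
#' covariate distributions and their effects on the logit, covariate
#' missingness rates, the 14-day-death thinning probability, and the seed.
#'
#' @param n_patients Number of patients (default 724).
#' @param turning_point_K Exposure value where the logit slope changes
#'   (default 3.3).
#' @param slope_below Log-odds per exposure unit below K
#'   (default `log(0.60)`).
#' @param slope_above Total log-odds per exposure unit above K
#'   (default `log(1.28)`); the hinge coefficient is
#'   `slope_above - slope_below`.
#' @param intercept Log-odds intercept; `NULL` (default) calibrates it so
#'   the marginal 28-day mortality is `target_prev`.
#' @param target_prev Marginal mortality used when `intercept` is `NULL`
#'   (default 0.0594).
#' @param ratio_mean,ratio_sd Target moments of the exposure (3.43, 2.01).
#' @param ratio_min,ratio_max Exposure truncation bounds (0.28, 10).
#' @param covariate_specs Named list of covariate distribution/effect specs;
#'   see `default_covariate_specs()` in the package source for the format.
#' @param missing_rates Named vector of MCAR missingness fractions in
#'   `[0, 1)` per covariate (default: lactate 28.3%, apache_iv 10.8%,
#'   weight 1.5%, sofa 1.0%, heart_rate 0.7%, matching a real cohort's
#'   missingness footnote). The exposure and outcome are never missing.
#' @param death14_given_death28 Probability a 28-day death occurred within
#'   14 days (default 0.7); 14-day deaths are a thinning of 28-day deaths
#'   so `death14 <= death28` row-wise.
#' @param mar_by Optional name of a covariate that tilts missingness
#'   probabilities (mean rate preserved); default `NULL` means MCAR.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 724,
                        turning_point_K = 3.3,
                        slope_below = log(0.60),
                        slope_above = log(1.28),
                        intercept = NULL,
                        target_prev = 0.0594,
                        ratio_mean = 3.43, ratio_sd = 2.01,
                        ratio_min = 0.28, ratio_max = 10,
                        covariate_specs = default_covariate_specs(),
                        missing_rates = c(lactate = 0.283, apache_iv = 0.108,
                                          weight = 0.015, sofa = 0.010,
                                          heart_rate = 0.007),
                        death14_given_death28 = 0.7,
                        mar_by = NULL,
                        seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop_field("n_patients", "must be >= 1")
  }
  if (!(ratio_min < turning_point_K && turning_point_K < ratio_max)) {
    stop_field("turning_point_K", "must lie strictly inside (ratio_min, ratio_max)")
  }
  if (ratio_min >= ratio_max) stop_field("ratio_max", "must exceed ratio_min")
  if (length(missing_rates)) {
    if (any(missing_rates < 0 | missing_rates >= 1)) {
      stop_field("missing_rates", "rates must be in [0, 1)")
    }
    bad <- intersect(names(missing_rates),
                     c("ratio", "death28", "death14", "id"))
    if (length(bad)) {
      stop_field("missing_rates",
                 paste("exposure/outcome columns cannot be missing:",
                       paste(bad, collapse = ", ")))
    }
    unknown <- setdiff(names(missing_rates), names(covariate_specs))
    if (length(unknown)) {
      stop_field("missing_rates",
                 paste("not a covariate:", paste(unknown, collapse = ", ")))
    }
  }
  if (death14_given_death28 < 0 || death14_given_death28 > 1) {
    stop_field("death14_given_death28", "must be in [0, 1]")
  }
  if (is.null(seed)) stop_field("seed", "a seed is mandatory")
  if (is.null(intercept)) {
    intercept <- calibrate_intercept(target_prev, turning_point_K,
                                     slope_below, slope_above,
                                     ratio_mean, ratio_sd,
                                     ratio_min, ratio_max)
  }
  structure(list(n_patients = as.integer(n_patients),
                 turning_point_K = turning_point_K,
                 slope_below = slope_below, slope_above = slope_above,
                 intercept = intercept,
                 ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                 ratio_min = ratio_min, ratio_max = ratio_max,
                 covariate_specs = covariate_specs,
                 missing_rates = missing_rates,
                 death14_given_death28 = death14_given_death28,
                 mar_by = mar_by,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_patients, "patients\n")
  cat(sprintf("  exposure: truncated lognormal on [%.2f, %.2f], mean %.2f, SD %.2f\n",
              x$ratio_min, x$ratio_max, x$ratio_mean, x$ratio_sd))
  cat(sprintf("  hinge logit: K = %.2f, OR/unit below = %.3f, above = %.3f, intercept = %.3f\n",
              x$turning_point_K, exp(x$slope_below), exp(x$slope_above),
              x$intercept))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

draw_covariate <- function(n, d) {
  switch(d$type,
    normal = {
      v <- stats::rnorm(n, d$mean, d$sd)
      pmin(pmax(v, d$min %||% -Inf), d$max %||% Inf)
    },
    lognormal = {
      v <- stats::rlnorm(n, d$meanlog, d$sdlog)
      pmin(pmax(v, d$min %||% 0), d$max %||% Inf)
    },
    poisson = pmin(stats::rpois(n, d$lambda), d$max %||% Inf),
    bernoulli = stats::rbinom(n, 1L, d$p),
    categorical = factor(sample(d$levels, n, replace = TRUE, prob = d$probs),
                         levels = d$levels),
    stop("unknown covariate distribution type: ", d$type)
  )
}

covariate_numeric <- function(col) {
  if (is.factor(col)) as.numeric(col) - 1 else as.numeric(col)
}

#' Generate a synthetic cohort
#'
#' Draws a patient table from a [cohort_spec()]: exposure from the
#' truncated lognormal, covariates from their declared distributions,
#' 28-day death from a Bernoulli with
#' `logit p = b0 + b1 * x + (b_above - b1) * max(x - K, 0) + covariate terms`,
#' 14-day death by thinning 28-day deaths, then MCAR covariate missingness
#' at the spec's rates. The same spec (same seed) always yields a
#' byte-identical table.
#'
#' @param spec A `cohort_spec`.
#' @return A data frame (`cohort_table`): `id`, `death28`, `death14`,
#'   `ratio`, plus one column per covariate, with attribute `true_logit`
#'   holding the generating linear predictor.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 200, seed = 42))
#' mean(cohort$death28)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    par <- calibrate_truncated_lognormal(spec$ratio_mean, spec$ratio_sd,
                                         spec$ratio_min, spec$ratio_max)
    ratio <- rtrunc_lnorm(n, par["meanlog"], par["sdlog"],
                          spec$ratio_min, spec$ratio_max)
    covs <- lapply(spec$covariate_specs, function(cs) draw_covariate(n, cs$dist))
    lp <- spec$intercept + spec$slope_below * ratio +
      (spec$slope_above - spec$slope_below) * hinge(ratio, spec$turning_point_K)
    for (nm in names(covs)) {
      eff <- spec$covariate_specs[[nm]]$effect %||% 0
      if (eff != 0) lp <- lp + eff * covariate_numeric(covs[[nm]])
    }
    # fixed uniform stream for the outcome draw: raising the risk at any
    # patient can only turn survivals into deaths, never the reverse
    u_death <- stats::runif(n)
    death28 <- as.integer(u_death < expit(lp))
    death14 <- as.integer(death28 == 1L &
                            stats::runif(n) < spec$death14_given_death28)
    tab <- data.frame(id = seq_len(n), death28 = death28, death14 = death14,
                      ratio = ratio, stringsAsFactors = FALSE)
    for (nm in names(covs)) tab[[nm]] <- covs[[nm]]
    if (length(spec$missing_rates)) {
      tab <- inject_missingness(tab, spec$missing_rates,
                                seed = (spec$seed + 104729L) %% .Machine$integer.max,
                                mar_by = spec$mar_by)
    }
    attr(tab, "true_logit") <- lp
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

#' Inject covariate missingness into a cohort table
#'
#' Sets covariate values missing at the requested rates, completely at
#' random by default. When `mar_by` names a covariate, each rate is tilted
#' by the rank of that covariate (probability proportional to
#' `0.5 + rank/(n+1)`, rescaled to preserve the mean rate) so missingness
#' depends on an observed value - a simple MAR mechanism for sensitivity
#' studies. The exposure and outcome columns are never eligible.
#'
#' @param table A cohort data frame.
#' @param rates Named vector of missingness fractions in `[0, 1)`.
#' @param seed Integer seed.
#' @param mar_by Optional covariate name driving the MAR tilt.
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, rates, seed, mar_by = NULL) {
  if (!length(rates)) return(table)
  forbidden <- intersect(names(rates), c("ratio", "death28", "death14", "id"))
  if (length(forbidden)) {
    stop("cannot inject missingness into exposure/outcome column(s): ",
         paste(forbidden, collapse = ", "))
  }
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0, 1)")
  unknown <- setdiff(names(rates), names(table))
  if (length(unknown)) stop("unknown column(s): ", paste(unknown, collapse = ", "))
  n <- nrow(table)
  with_seed(seed, {
    tilt <- if (!is.null(mar_by)) {
      r <- rank(covariate_numeric(table[[mar_by]]), ties.method = "average")
      w <- 0.5 + r / (n + 1)
      w / mean(w)
    } else rep(1, n)
    for (nm in names(rates)) {
      p <- pmin(rates[[nm]] * tilt, 0.999)
      table[[nm]][stats::runif(n) < p] <- NA
    }
    table
  })
}
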