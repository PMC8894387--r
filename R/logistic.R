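# Maximum-likelihood logistic regression engine.
#
# Every inferential stage of the package (one-line and hinge models, the
# turning-point profile, the bootstrap) funnels through irls_logit(), so it
# is written lean: Newton/IRLS steps on the Bernoulli log-likelihood with
# step-halving, explicit rank and separation diagnostics, and support for
# warm starts (the turning-point grid search refits a model that differs
# from its neighbour in a single column).

irls_logit <- function(X, y, tol = 1e-8, max_iter = 100L, start = NULL) {
  p <- ncol(X)
  beta <- if (is.null(start)) numeric(p) else start
  if (is.null(start) && all(X[, 1L] == 1)) {
    pr <- mean(y)
    if (pr > 0 && pr < 1) beta[1L] <- stats::qlogis(pr)
  }
  eta <- drop(X %*% beta)
  mu <- expit(eta)
  ll <- sum(y * eta - log1p(exp(eta)))
  converged <- FALSE
  it <- 0L
  ll_old <- -Inf
  repeat {
    score <- crossprod(X, y - mu)
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    # deviance-change fallback (as in standard GLM software): when a
    # small event-free subgroup sends its coefficient toward -Inf the
    # score there never vanishes, but the likelihood flattens out
    if (abs(ll - ll_old) < 1e-10 * (abs(ll) + 0.1)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    it <- it + 1L
    ll_old <- ll
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) {
      qrx <- qr(X)
      if (qrx$rank < p) {
        dep <- colnames(X)[qrx$pivot[seq.int(qrx$rank + 1L, p)]]
        stop("rank-deficient design: columns {", paste(dep, collapse = ", "),
             "} are linearly dependent on the others", call. = FALSE)
      }
      stop("weighted information matrix is numerically singular at ",
           "iteration ", it, "; predictors may be near-collinear on this ",
           "scale", call. = FALSE)
    }
    # step-halving guarantees the log-likelihood never decreases
    h <- 1
    repeat {
      beta_new <- beta + h * drop(step)
      eta_new <- drop(X %*% beta_new)
      ll_new <- sum(y * eta_new - log1p(exp(eta_new)))
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      h <- h / 2
      if (h < 1e-10) { ll_new <- ll; beta_new <- beta; eta_new <- eta; break }
    }
    beta <- beta_new; eta <- eta_new; mu <- expit(eta); ll <- ll_new
  }
  # a perfect fit (all fitted probabilities at the data) is unreachable at
  # any finite coefficient vector: the likelihood has no interior maximum.
  # A converged fit with an absurd coefficient magnitude signals quasi-
  # separation on a subset (e.g. an event-free segment): the score can fall
  # under tolerance while the slope runs away.
  if (all(abs(y - mu) < 1e-6) || max(abs(beta)) > 100 ||
      (!converged && max(abs(beta)) > 15)) {
    j <- which.max(abs(beta))
    stop("perfect or quasi-perfect separation detected (coefficient for `",
         colnames(X)[j] %||% paste0("x", j),
         "` is diverging); the likelihood has no finite maximum",
         call. = FALSE)
  }
  w <- mu * (1 - mu)
  XtWX <- crossprod(X, X * w)
  vcov <- tryCatch(solve(XtWX), error = function(e) {
    stop("observed information is singular at the optimum", call. = FALSE)
  })
  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       vcov = vcov, log_likelihood = ll, converged = converged,
       iterations = it, fitted = mu)
}

#' Fit a logistic regression by maximum likelihood
#'
#' Fits a Bernoulli GLM with logit link by iteratively reweighted least
#' squares (Newton scoring with step-halving), converging when the maximum
#' absolute score falls below `tol`. The covariance matrix is the inverse
#' observed information at the optimum and confidence intervals downstream
#' are Wald intervals, matching standard epidemiological software output.
#'
#' @param design A `design_matrix` (see [build_design()]), or a numeric
#'   matrix of predictors (an intercept column is not added automatically).
#' @param y Binary response vector; required when `design` is a bare matrix.
#' @param tol Convergence tolerance on the score (default `1e-8`).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param start Optional starting coefficient vector (warm start).
#' @return An object of class `logistic_fit`: coefficients, `vcov`,
#'   `log_likelihood`, `n_obs`, `converged`, `iterations`.
#' @details Perfect separation and rank deficiency are errors naming the
#'   offending column(s); no penalization is applied silently.
#' @examples
#' X <- cbind(intercept = 1, x = rnorm(200))
#' y <- rbinom(200, 1, plogis(-1 + X[, "x"]))
#' fit <- fit_logistic(X, y)
#' odds_ratios(fit)
#' @export
fit_logistic <- function(design, y = NULL, tol = 1e-8, max_iter = 100L,
                         start = NULL) {
  if (inherits(design, "design_matrix")) {
    X <- design$X
    y <- design$response
  } else {
    X <- as.matrix(design)
    if (is.null(y)) stop("`y` is required when `design` is a bare matrix")
  }
  if (anyNA(X) || anyNA(y)) {
    stop("design matrix or response contains missing values; resolve ",
         "missingness (see add_missing_dummies) before fitting", call. = FALSE)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("response has a single class; logistic MLE undefined", call. = FALSE)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(X))]]
    stop("rank-deficient design: columns {", paste(dep, collapse = ", "),
         "} are linearly dependent on the others", call. = FALSE)
  }
  res <- irls_logit(X, y, tol = tol, max_iter = max_iter, start = start)
  structure(list(coefficients = res$coefficients, vcov = res$vcov,
                 log_likelihood = res$log_likelihood, n_obs = length(y),
                 converged = res$converged, iterations = res$iterations),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (ML):", x$n_obs, "observations, log-likelihood",
      fmt_num(x$log_likelihood, 3), "\n")
  print(odds_ratios(x), digits = 4)
  invisible(x)
}

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            class = "logLik")
}

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' Odds ratios with Wald confidence intervals
#'
#' Exponentiates the coefficients of a [fit_logistic()] fit and attaches
#' Wald confidence intervals `exp(coef +/- z * SE)` and two-sided Wald
#' p-values.
#'
#' @param fit A `logistic_fit`.
#' @param conf Confidence level (default 0.95).
#' @return A data frame with columns `term`, `or`, `lower`, `upper`, `p`,
#'   plus `coef` and `se` on the log-odds scale.
#' @export
odds_ratios <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("fit did not converge; odds ratios unreliable")
  z <- z_crit(conf)
  co <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  data.frame(term = names(co), or = exp(co),
             lower = exp(co - z * se), upper = exp(co + z * se),
             p = 2 * stats::pnorm(-abs(co / se)),
             coef = unname(co), se = unname(se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Change-in-estimate confounder screening
#'
#' Screens candidate covariates by the 10% change-in-estimate rule: a
#' candidate is selected when adding it to the base exposure model changes
#' the exposure odds ratio by more than `threshold` in relative terms,
#' i.e. `|OR_with / OR_without - 1| > threshold`.
#'
#' @param data Data frame containing outcome, exposure and candidates.
#' @param outcome Name of the binary outcome column.
#' @param exposure Name of the continuous exposure column.
#' @param candidates Character vector of candidate covariate names.
#' @param base_covariates Covariates always kept in both models.
#' @param threshold Relative change triggering selection (default 0.10).
#' @return A data frame logging, per candidate, the exposure OR without and
#'   with the candidate, the relative change, whether it was selected, and
#'   whether its model converged; selected names in
#'   `attr(, "selected")`.
#' @export
screen_confounders <- function(data, outcome, exposure, candidates,
                               base_covariates = character(),
                               threshold = 0.10) {
  split_types <- function(nms) {
    is_cat <- vapply(nms, function(nm)
      is.factor(data[[nm]]) || is.character(data[[nm]]), logical(1))
    list(cont = nms[!is_cat], cat = nms[is_cat])
  }
  base <- split_types(base_covariates)
  base_fit <- fit_logistic(build_design(
    data, outcome = outcome, continuous = c(exposure, base$cont),
    categorical = base$cat))
  or_base <- exp(base_fit$coefficients[[exposure]])
  rows <- lapply(candidates, function(cand) {
    with_cand <- split_types(c(base_covariates, cand))
    fit <- tryCatch(
      fit_logistic(build_design(data, outcome = outcome,
                                continuous = c(exposure, with_cand$cont),
                                categorical = with_cand$cat)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(candidate = cand, or_without = or_base,
                        or_with = NA_real_, rel_change = NA_real_,
                        selected = NA, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    or_with <- exp(fit$coefficients[[exposure]])
    chg <- abs(or_with / or_base - 1)
    data.frame(candidate = cand, or_without = or_base, or_with = or_with,
               rel_change = chg, selected = chg > threshold, converged = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(candidate = character(), or_without = numeric(),
               or_with = numeric(), rel_change = numeric(),
               selected = logical(), converged = logical(),
               stringsAsFactors = FALSE)
  attr(out, "selected") <- out$candidate[which(out$selected)]
  out
}
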