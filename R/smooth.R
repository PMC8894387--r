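# Smooth dose-response layer: penalized-spline logistic fit of the
# exposure with a pointwise confidence band, plus a U-shape diagnostic.
#
# Construction: cubic B-spline basis on equally spaced knots,
# second-order difference penalty on the basis coefficients (a P-spline),
# smoothing parameter chosen by AIC over a log-spaced grid. The penalty
# null space is the linear functions, so as lambda -> Inf the smooth
# collapses to the one-line logistic fit.

# Equally spaced cubic B-spline basis (Eilers-Marx P-spline). Equal
# spacing is essential: it makes the null space of the second-order
# difference penalty exactly the functions linear in x, so the smooth
# collapses to the one-line model as lambda -> Inf.
pspline_basis <- function(x, n_basis = 20L, xr = range(x)) {
  degree <- 3L
  h <- diff(xr) / (n_basis - degree)
  knots <- xr[1] + seq.int(-degree, n_basis, by = 1L) * h
  list(knots = knots, degree = degree,
       eval = function(v) {
    v <- pmin(pmax(v, xr[1]), xr[2])
    splines::splineDesign(knots, v, ord = degree + 1L, outer.ok = TRUE)
  })
}

# damped Newton on the penalized Bernoulli log-likelihood
# pll(beta) = loglik(beta) - beta' Pen beta / 2
penalized_irls <- function(X, y, Pen, tol = 1e-12, max_iter = 200L) {
  beta <- numeric(ncol(X))
  eta <- drop(X %*% beta)
  mu <- expit(eta)
  pll <- sum(y * eta - log1p(exp(eta)))
  for (it in seq_len(max_iter)) {
    grad <- drop(crossprod(X, y - mu)) - drop(Pen %*% beta)
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + Pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      stop("penalized information matrix is singular (iteration ", it, ")")
    }
    # Newton decrement: scale-free convergence criterion (the raw gradient
    # has the scale of the penalty, which can be enormous)
    if (sum(grad * step) < tol) break
    h <- 1
    repeat {
      beta_new <- beta + h * step
      eta_new <- drop(X %*% beta_new)
      pll_new <- sum(y * eta_new - log1p(exp(eta_new))) -
        drop(crossprod(beta_new, Pen %*% beta_new)) / 2
      if (is.finite(pll_new) && pll_new >= pll - 1e-12) break
      h <- h / 2
      if (h < 1e-10) { beta_new <- beta; eta_new <- eta; pll_new <- pll; break }
    }
    # likelihood-stall fallback: an event-free subgroup in the unpenalized
    # block sends its coefficient toward -Inf with vanishing gains; stop
    # before its weights underflow the information matrix
    stalled <- abs(pll_new - pll) < 1e-11 * (abs(pll) + 0.1)
    beta <- beta_new; eta <- eta_new; mu <- expit(eta); pll <- pll_new
    if (stalled) break
  }
  w <- mu * (1 - mu)
  XtWX <- crossprod(X, X * w)
  A <- solve(XtWX + Pen)
  list(beta = beta, cov = A, edf = sum(diag(A %*% XtWX)),
       deviance = -2 * sum(y * eta - log1p(exp(eta))), iterations = it)
}

#' Penalized-spline smooth logistic dose-response curve
#'
#' Fits `logit p = f(exposure) + linear covariate terms` where `f` lives in
#' a cubic B-spline basis (default 20 basis functions, equally spaced
#' knots) with a second-order difference penalty; the smoothing
#' parameter is selected by AIC (`deviance + 2 * edf`) over a log-spaced
#' grid. The curve is reported as a centered partial effect (mean zero over
#' the observed exposure) with a pointwise Wald band from the
#' penalized-information covariance.
#'
#' @param data Cohort data frame with missingness resolved.
#' @param outcome,exposure Column names.
#' @param covariates Linear adjustment covariates.
#' @param n_basis Number of B-spline basis functions (default 20).
#' @param lambda Smoothing parameter; `NULL` (default) selects by AIC.
#' @param lambda_grid Candidate lambdas for the AIC search.
#' @param basis Optional custom basis: a function mapping the exposure
#'   vector to a basis matrix (no separate intercept is added). With
#'   `lambda = 0` and the hinge basis `cbind(1, x, pmax(x - K, 0))` this
#'   reproduces the two-piecewise model exactly.
#' @param grid_n Number of evaluation points for the reported curve.
#' @param conf Confidence level for the band.
#' @return An object of class `smooth_curve`: `x_grid`, `partial_logit`,
#'   `ci_lower`, `ci_upper`, `effective_df`, `smoothing_parameter`,
#'   `coefficients`, `aic_path`.
#' @export
fit_smooth_logistic <- function(data, outcome, exposure,
                                covariates = character(),
                                n_basis = 20L, lambda = NULL,
                                lambda_grid = 10^seq(-2, 8, length.out = 30),
                                basis = NULL, grid_n = 200L, conf = 0.95) {
  x <- data[[exposure]]
  y <- as.numeric(data[[outcome]])
  if (is.null(basis) && length(unique(x)) < 20L) {
    stop("exposure has fewer than 20 distinct values; a smooth fit is ",
         "not identifiable")
  }
  if (is.null(basis)) {
    bs <- pspline_basis(x, n_basis = n_basis)
    B <- bs$eval(x)
    eval_basis <- bs$eval
    D <- diff(diag(ncol(B)), differences = 2L)
    P <- crossprod(D)
  } else {
    B <- basis(x)
    eval_basis <- basis
    P <- diag(0, ncol(B))
    lambda <- lambda %||% 0
  }
  Z <- NULL
  if (length(covariates)) {
    is_cat <- vapply(covariates, function(nm)
      is.factor(data[[nm]]) || is.character(data[[nm]]), logical(1))
    des <- build_design(data, outcome = outcome,
                        continuous = covariates[!is_cat],
                        categorical = covariates[is_cat],
                        intercept = FALSE)
    # centered, no intercept: the spline basis spans constants
    Z <- scale(des$X, center = TRUE, scale = FALSE)
  }
  X <- if (is.null(Z)) B else cbind(B, Z)
  pad <- function(lam) {
    Pen <- matrix(0, ncol(X), ncol(X))
    Pen[seq_len(ncol(B)), seq_len(ncol(B))] <- lam * P
    Pen
  }
  aic_path <- NULL
  if (is.null(lambda)) {
    aics <- vapply(lambda_grid, function(lam) {
      f <- tryCatch(penalized_irls(X, y, pad(lam)), error = function(e) NULL)
      if (is.null(f)) Inf else f$deviance + 2 * f$edf
    }, numeric(1))
    aic_path <- data.frame(lambda = lambda_grid, aic = aics)
    if (all(!is.finite(aics))) {
      stop("smooth fit failed at every candidate smoothing parameter ",
           "(basis dim ", ncol(B), "); the data may be quasi-separated")
    }
    lambda <- lambda_grid[which.min(aics)]
  }
  fit <- penalized_irls(X, y, pad(lambda))
  if (!all(is.finite(fit$beta))) {
    stop("smooth fit failed to converge (lambda = ", lambda, ", basis dim ",
         ncol(B), "); inspect the penalty/basis configuration")
  }
  xg <- seq(min(x), max(x), length.out = grid_n)
  Bg <- eval_basis(xg)
  Bobs_mean <- colMeans(eval_basis(x))
  Cc <- sweep(Bg, 2L, Bobs_mean)  # centered partial-effect contrast
  theta <- fit$beta[seq_len(ncol(B))]
  Vtheta <- fit$cov[seq_len(ncol(B)), seq_len(ncol(B))]
  f_hat <- drop(Cc %*% theta)
  se <- sqrt(pmax(rowSums((Cc %*% Vtheta) * Cc), 0))
  z <- z_crit(conf)
  structure(list(x_grid = xg, partial_logit = f_hat,
                 ci_lower = f_hat - z * se, ci_upper = f_hat + z * se,
                 effective_df = fit$edf, smoothing_parameter = lambda,
                 coefficients = fit$beta, basis_dim = ncol(B),
                 aic_path = aic_path, n_obs = length(y)),
            class = "smooth_curve")
}

#' @export
print.smooth_curve <- function(x, ...) {
  cat("Smooth logistic dose-response curve\n")
  cat(sprintf("  basis dim %d, lambda = %.4g, effective df = %.2f\n",
              x$basis_dim, x$smoothing_parameter, x$effective_df))
  tr <- detect_turning_region(x)
  cat(sprintf("  minimum of the smooth at %.2f (slope pattern %s)\n",
              tr$argmin_x, tr$pattern))
  invisible(x)
}

#' Locate the turning region of a fitted smooth
#'
#' Returns the grid location of the minimum of the smooth partial effect
#' and the sign pattern of its numerical derivative: `"-,+"` indicates a
#' U-shape, `"-"` or `"+"` a monotone curve (argmin then at a boundary).
#'
#' @param curve A `smooth_curve`.
#' @param tol Derivative magnitudes below `tol` times the largest are
#'   treated as flat (default 0.05), so small estimation wiggle does not
#'   register as extra sign changes.
#' @return List `argmin_x`, `pattern`, `argmin_index`.
#' @export
detect_turning_region <- function(curve, tol = 0.05) {
  f <- curve$partial_logit
  xg <- curve$x_grid
  i <- which.min(f)
  d <- diff(f) / diff(xg)
  keep <- abs(d) > tol * max(abs(d))
  signs <- ifelse(d[keep] > 0, "+", "-")
  pattern <- paste(rle(signs)$values, collapse = ",")
  list(argmin_x = xg[i], pattern = pattern, argmin_index = i)
}

#' Export a smooth curve as a data frame
#'
#' @param x A `smooth_curve`.
#' @param ... Unused.
#' @return Data frame `x`, `fit`, `lower`, `upper`.
#' @export
as.data.frame.smooth_curve <- function(x, ...) {
  data.frame(x = x$x_grid, fit = x$partial_logit,
             lower = x$ci_lower, upper = x$ci_upper)
}

#' Plot a smooth dose-response curve
#'
#' Base-graphics plot of the centered partial logit with its pointwise
#' confidence band.
#'
#' @param x A `smooth_curve`.
#' @param xlab,ylab,main Plot labels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.smooth_curve <- function(x, xlab = "exposure",
                              ylab = "partial logit (centered)",
                              main = "Smooth dose-response", ...) {
  graphics::plot(x$x_grid, x$partial_logit, type = "n",
                 ylim = range(x$ci_lower, x$ci_upper),
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::polygon(c(x$x_grid, rev(x$x_grid)),
                    c(x$ci_lower, rev(x$ci_upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$x_grid, x$partial_logit, col = "red3", lwd = 2)
  invisible(x)
}
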