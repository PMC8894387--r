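# Internal helpers shared across modules.

# 95% normal quantile used throughout; kept at full precision internally,
# rounding happens only at report time.
z_crit <- function(conf = 0.95) stats::qnorm(1 - (1 - conf) / 2)

expit <- function(x) stats::plogis(x)

#' Hinge (positive-part) transform
#'
#' `hinge(x, k)` returns `max(x - k, 0)` elementwise. Added to a linear term
#' it produces a continuous piecewise-linear predictor with a slope change
#' at `k`.
#'
#' @param x Numeric vector.
#' @param k Knot (turning point) on the scale of `x`.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' hinge(c(1, 3, 5), 3.3)
#' @export
hinge <- function(x, k) pmax(x - k, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# deterministic RNG sandbox: runs `expr` under `seed` and restores the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_field("seed", "must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)
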