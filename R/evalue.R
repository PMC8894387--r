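# E-value sensitivity analysis for unmeasured confounding.
#
# The E-value is the minimum strength of association, on the risk-ratio
# scale, that an unmeasured confounder would need with both the exposure
# and the outcome to fully explain an observed association. For a risk
# ratio RR > 1: E = RR + sqrt(RR * (RR - 1)); protective estimates are
# inverted first. With a rare outcome the odds ratio approximates the risk
# ratio directly; otherwise OR -> sqrt(OR) is the usual approximation.

or_to_rr <- function(or_value, rare_outcome) {
  if (or_value <= 0) stop("odds ratio must be positive")
  rr <- if (rare_outcome) or_value else sqrt(or_value)
  if (rr < 1) rr <- 1 / rr
  rr
}

#' E-value for a point estimate
#'
#' @param or_value Odds ratio (> 0).
#' @param rare_outcome If `TRUE` (default, appropriate when outcome
#'   prevalence is a few percent) the OR is treated as an approximate risk
#'   ratio; otherwise the square-root approximation `OR -> sqrt(OR)` is
#'   applied first.
#' @return The E-value (>= 1).
#' @examples
#' evalue_point(1.28)  # 1.88
#' evalue_point(0.60)  # 2.72 (protective estimates are inverted)
#' @export
evalue_point <- function(or_value, rare_outcome = TRUE) {
  rr <- or_to_rr(or_value, rare_outcome)
  rr + sqrt(rr * (rr - 1))
}

#' E-value for a confidence-interval limit
#'
#' Applies [evalue_point()] to the CI limit closer to the null; when the
#' interval contains 1 the E-value is exactly 1 (no confounding is needed
#' to render the interval compatible with no effect).
#'
#' @param ci Length-2 vector `(lower, upper)` on the OR scale.
#' @param rare_outcome As in [evalue_point()].
#' @return The E-value for the CI (>= 1).
#' @export
evalue_ci <- function(ci, rare_outcome = TRUE) {
  lower <- ci[[1]]; upper <- ci[[2]]
  if (lower > upper) stop("lower CI bound exceeds upper bound")
  if (lower <= 1 && upper >= 1) return(1)
  limit <- if (lower > 1) lower else upper
  evalue_point(limit, rare_outcome = rare_outcome)
}

#' E-value report for an estimate with CI
#'
#' @param or_value Point odds ratio.
#' @param ci Optional `(lower, upper)`.
#' @param rare_outcome As in [evalue_point()].
#' @param label Free-text label for the estimate.
#' @return An `evalue_result`: `input_or`, `input_ci`, `rare_outcome`,
#'   `evalue_point`, `evalue_ci`.
#' @export
evalue_report <- function(or_value, ci = NULL, rare_outcome = TRUE,
                          label = "") {
  structure(list(label = label, input_or = or_value, input_ci = ci,
                 rare_outcome = rare_outcome,
                 evalue_point = evalue_point(or_value, rare_outcome),
                 evalue_ci = if (is.null(ci)) NA_real_
                             else evalue_ci(ci, rare_outcome)),
            class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, ...) {
  ci_txt <- if (is.null(x$input_ci)) "" else
    sprintf(" (95%% CI %s, %s)", fmt_num(x$input_ci[[1]]), fmt_num(x$input_ci[[2]]))
  cat(sprintf("E-value%s: OR %s%s -> E = %s point",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              fmt_num(x$input_or), ci_txt, fmt_num(x$evalue_point)))
  if (!is.na(x$evalue_ci)) cat(",", fmt_num(x$evalue_ci), "for the CI limit")
  cat("\n")
  invisible(x)
}
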