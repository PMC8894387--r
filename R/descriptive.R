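# Descriptive layer: baseline tables by exposure tertile, group-comparison
# tests, proportion CIs, unadjusted 2x2 odds ratios.

#' Wald confidence interval for a proportion
#'
#' Normal-approximation (Wald) interval `p +/- z * sqrt(p(1-p)/n)`, clipped
#' to `[0, 1]`. This is the interval conventional epidemiological reports
#' print for a mortality rate; Wilson is available via `method = "wilson"`.
#'
#' @param k Number of events.
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95, z = 1.959964).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return Named vector `c(estimate, lower, upper)` as proportions.
#' @examples
#' round(100 * proportion_ci(43, 724), 2)  # 5.94 (4.22, 7.66)
#' @export
proportion_ci <- function(k, n, conf = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  p <- k / n
  z <- z_crit(conf)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half); hi <- min(1, p + half)
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, centre - half); hi <- min(1, centre + half)
  }
  c(estimate = p, lower = lo, upper = hi)
}

#' Odds ratio of a 2x2 table with Wald CI
#'
#' `OR = ad / (bc)` with log-scale Wald interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Zero cells are an
#' error: a continuity correction is never applied silently; collapse
#' categories or use exact methods instead.
#'
#' @param a,b,c,d Counts: exposed-case, exposed-noncase, unexposed-case,
#'   unexposed-noncase.
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(or, lower, upper, p)` (two-sided Wald p).
#' @examples
#' round(odds_ratio_2x2(8, 233, 17, 224)[1:3], 2)  # 0.45 (0.19, 1.07)
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf = 0.95) {
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("counts must be non-negative")
  if (any(cells == 0)) {
    stop("zero cell in 2x2 table: the Wald odds ratio is undefined; ",
         "no continuity correction is applied silently - collapse ",
         "categories or use an exact method")
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- z_crit(conf)
  c(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
    p = 2 * stats::pnorm(-abs(log(or) / se)))
}

#' Pearson chi-squared test of independence
#'
#' Classical Pearson statistic `sum (O - E)^2 / E` on an r x c count table,
#' `df = (r-1)(c-1)`, without continuity correction (the convention used
#' in baseline-characteristics tables). Delegates to
#' [stats::chisq.test()] with `correct = FALSE`.
#'
#' @param counts Matrix of counts.
#' @return Named vector `c(statistic, df, p)`.
#' @examples
#' m <- rbind(deaths = c(17, 8, 18), survivors = c(224, 233, 224))
#' round(chi_square_test(m)["p"], 3)  # 0.107
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("zero expected cell count: test undefined")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  c(statistic = unname(ct$statistic), df = unname(ct$parameter),
    p = unname(ct$p.value))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA F test of equal group means, via
#' [stats::oneway.test()] with `var.equal = TRUE`. A Kruskal-Wallis rank
#' test is available with `method = "kruskal"` for skewed variables.
#'
#' @param groups List of numeric vectors, >= 2 groups with >= 2 values each.
#' @param method `"anova"` (default) or `"kruskal"`.
#' @return Named vector `c(statistic, df1, df2, p)` (`df2 = NA` for
#'   Kruskal-Wallis, where `statistic` is the H chi-squared).
#' @export
one_way_anova <- function(groups, method = c("anova", "kruskal")) {
  method <- match.arg(method)
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (method == "kruskal") {
    kt <- stats::kruskal.test(y, g)
    return(c(statistic = unname(kt$statistic), df1 = unname(kt$parameter),
             df2 = NA_real_, p = unname(kt$p.value)))
  }
  within_var <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (within_var == 0 && stats::var(y) == 0) {
    stop("degenerate input: zero variance within and across groups")
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  c(statistic = unname(ft$statistic), df1 = unname(ft$parameter[1]),
    df2 = unname(ft$parameter[2]), p = unname(ft$p.value))
}

summary_cell <- function(values, type) {
  v <- values[!is.na(values)]
  switch(type,
    mean_sd = sprintf("%s ± %s", fmt_num(mean(v), 1), fmt_num(stats::sd(v), 1)),
    median_iqr = {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
      sprintf("%s (%s–%s)", fmt_num(q[2], 1), fmt_num(q[1], 1), fmt_num(q[3], 1))
    },
    stop("unknown summary type: ", type))
}

#' Baseline characteristics table by tertile
#'
#' Builds a baseline ("Table 1") analogue: one block per variable with
#' per-tertile summaries and a group-comparison p-value - ANOVA for
#' continuous variables (on raw values; rank tests are a deliberate
#' non-default), chi-squared for categoricals. Continuous variables listed
#' in `median_iqr` are displayed as median (IQR) but still tested by ANOVA.
#'
#' @param table Cohort data frame.
#' @param groups A [assign_tertiles()] result for the exposure.
#' @param variables Character vector of columns to summarize (default: all
#'   covariates present among the standard set).
#' @param median_iqr Variables displayed as median (IQR) rather than
#'   mean +/- SD (default `c("lactate", "sofa")`).
#' @return Data frame with columns `variable`, `level`, one column per
#'   tertile, `test`, `p`; class `baseline_table`.
#' @export
build_baseline_table <- function(table, groups,
                                 variables = NULL,
                                 median_iqr = c("lactate", "sofa")) {
  stopifnot(inherits(groups, "tertile_assignment"))
  if (is.null(variables)) {
    standard <- c("age", "sex", "weight", "heart_rate", "lactate",
                  "apache_iv", "sofa", "septic_shock", "infection_site",
                  "death28")
    variables <- intersect(standard, names(table))
  }
  lab <- groups$labels
  rows <- list()
  for (nm in variables) {
    col <- table[[nm]]
    if (is.numeric(col) && length(unique(stats::na.omit(col))) > 2L) {
      type <- if (nm %in% median_iqr) "median_iqr" else "mean_sd"
      cells <- vapply(levels(lab), function(g)
        summary_cell(col[lab == g], type), "")
      grp_vals <- lapply(levels(lab), function(g) {
        v <- col[lab == g]
        v[!is.na(v)]
      })
      p <- tryCatch(one_way_anova(grp_vals)[["p"]], error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = "", T1 = cells[[1]], T2 = cells[[2]],
        T3 = cells[[3]], test = "ANOVA", p = p, stringsAsFactors = FALSE)
    } else {
      f <- if (is.factor(col)) col else factor(col)
      tab <- table(f, lab)
      p <- tryCatch(chi_square_test(tab)[["p"]], error = function(e) NA_real_)
      for (i in seq_len(nrow(tab))) {
        cells <- vapply(seq_len(ncol(tab)), function(j) {
          sprintf("%d (%s%%)", tab[i, j],
                  fmt_num(100 * tab[i, j] / sum(tab[, j]), 1))
        }, "")
        rows[[length(rows) + 1L]] <- data.frame(
          variable = nm, level = rownames(tab)[i], T1 = cells[[1]],
          T2 = cells[[2]], T3 = cells[[3]],
          test = if (i == 1L) "chi-squared" else "",
          p = if (i == 1L) p else NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Render a baseline table as Markdown
#'
#' @param x A `baseline_table`.
#' @return Character vector of Markdown lines.
#' @export
format_baseline_md <- function(x) {
  header <- c("| Variable | Level | Tertile 1 | Tertile 2 | Tertile 3 | P value |",
              "|---|---|---|---|---|---|")
  body <- vapply(seq_len(nrow(x)), function(i) {
    p <- if (is.na(x$p[i])) "" else fmt_num(x$p[i], 3)
    sprintf("| %s | %s | %s | %s | %s | %s |", x$variable[i], x$level[i],
            x$T1[i], x$T2[i], x$T3[i], p)
  }, "")
  c(header, body)
}

#' Unadjusted tertile odds-ratio table
#'
#' For a binary outcome and a tertile assignment, computes the middle-vs-low
#' and high-vs-low odds ratios from the corresponding 2x2 tables (identical,
#' by MLE equivalence, to a logistic fit on tertile indicators).
#'
#' @param outcome Binary 0/1 vector.
#' @param groups A `tertile_assignment`.
#' @param conf Confidence level.
#' @return Data frame with rows `low` (reference), `middle`, `high`.
#' @export
tertile_or_table <- function(outcome, groups, conf = 0.95) {
  lab <- groups$labels
  cases <- tapply(outcome, lab, sum)
  tot <- tapply(outcome, lab, length)
  non <- tot - cases
  mk <- function(i) odds_ratio_2x2(cases[i], non[i], cases[1], non[1], conf = conf)
  mid <- mk(2); hi <- mk(3)
  data.frame(
    tertile = c("low", "middle", "high"),
    n = as.vector(tot), cases = as.vector(cases),
    or = c(NA, mid["or"], hi["or"]),
    lower = c(NA, mid["lower"], hi["lower"]),
    upper = c(NA, mid["upper"], hi["upper"]),
    p = c(NA, mid["p"], hi["p"]),
    row.names = NULL, stringsAsFactors = FALSE)
}
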