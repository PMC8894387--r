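# Cohort preparation: tertile assignment, missing-indicator adjustment,
# design-matrix construction.

#' Assign tertiles of a continuous variable
#'
#' Splits `values` into three groups as equal in size as ties permit, using
#' nearest-rank cuts: the cut values are the order statistics at ranks
#' `floor(n/3)` and `floor(2n/3)`, values at or below a cut fall in the
#' lower group (ties-to-lower), and any remainder accrues to the top group.
#' With distinct values and n = 724 this yields the 241/241/242 split
#' typical of published tertile tables.
#'
#' @param values Numeric vector without missing values, length >= 3.
#' @return An object of class `tertile_assignment`: `labels` (factor
#'   `T1`/`T2`/`T3` per row), `boundaries` (the two realized cut values),
#'   `counts` (per-group sizes), `ranges` (observed min-max per group).
#' @details The rule is deterministic and permutation-equivariant: the label
#'   of a row depends only on its value, so shuffling rows shuffles labels
#'   identically. A constant vector has no defined tertiles and is an error.
#' @examples
#' assign_tertiles(1:9)$counts
#' @export
assign_tertiles <- function(values) {
  if (anyNA(values)) stop("`values` must not contain missing values")
  n <- length(values)
  if (n < 3L) stop("need at least 3 observations to form tertiles")
  v <- sort(values)
  c1 <- v[floor(n / 3)]
  c2 <- v[floor(2 * n / 3)]
  if (v[1L] == v[n]) stop("constant vector: tertiles undefined")
  labels <- factor(ifelse(values <= c1, "T1", ifelse(values <= c2, "T2", "T3")),
                   levels = c("T1", "T2", "T3"))
  counts <- table(labels)
  rng <- tapply(values, labels, function(g) if (length(g)) range(g) else c(NA, NA))
  structure(list(labels = labels, boundaries = c(c1, c2),
                 counts = as.vector(counts),
                 ranges = rng),
            class = "tertile_assignment")
}

#' @export
print.tertile_assignment <- function(x, ...) {
  cat("Tertile assignment: cuts at", fmt_num(x$boundaries[1]),
      "and", fmt_num(x$boundaries[2]), "\n")
  for (i in 1:3) {
    r <- x$ranges[[i]]
    cat(sprintf("  T%d: n = %d, range %s-%s\n", i, x$counts[i],
                fmt_num(r[1]), fmt_num(r[2])))
  }
  invisible(x)
}

#' Missing-indicator (dummy) adjustment for covariates
#'
#' Implements the missing-indicator method: for each continuous covariate
#' whose missing fraction strictly exceeds `threshold_fraction`, a binary
#' `<name>_missing` column (1 = value was missing) is added and the missing
#' entries are filled with the observed mean; covariates at or below the
#' threshold are mean-filled without an indicator. The outcome and exposure
#' are never touched.
#'
#' @param table Data frame (a cohort table).
#' @param covariates Names of the continuous covariates to process; defaults
#'   to every numeric column with at least one missing value, excluding
#'   `protect`.
#' @param threshold_fraction Missing fraction above which an indicator is
#'   added (default 0.01, i.e. 1%).
#' @param protect Columns that must never be filled (outcome/exposure/id).
#' @return The data frame with missing values resolved, with attributes
#'   `indicator_columns` (names added) and `fill_values` (mean used per
#'   covariate).
#' @export
add_missing_dummies <- function(table, covariates = NULL,
                                threshold_fraction = 0.01,
                                protect = c("id", "ratio", "death28", "death14")) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop_field("threshold_fraction", "must be in (0, 1)")
  }
  if (is.null(covariates)) {
    covariates <- names(table)[vapply(table, function(col)
      is.numeric(col) && anyNA(col), logical(1))]
    covariates <- setdiff(covariates, protect)
  }
  bad <- intersect(covariates, protect)
  if (length(bad)) {
    stop("refusing to fill protected column(s): ", paste(bad, collapse = ", "))
  }
  indicators <- character()
  fills <- numeric()
  for (nm in covariates) {
    col <- table[[nm]]
    miss <- is.na(col)
    frac <- mean(miss)
    if (frac == 1) stop("covariate `", nm, "` is 100% missing; cannot fill")
    if (!any(miss)) next
    fill <- mean(col[!miss])
    if (frac > threshold_fraction) {
      ind <- paste0(nm, "_missing")
      table[[ind]] <- as.integer(miss)
      indicators <- c(indicators, ind)
    }
    col[miss] <- fill
    table[[nm]] <- col
    fills[nm] <- fill
  }
  attr(table, "indicator_columns") <- indicators
  attr(table, "fill_values") <- fills
  table
}

design_matrix <- function(response, X, reference_levels = list()) {
  stopifnot(is.matrix(X), nrow(X) == length(response))
  structure(list(response = response, X = X,
                 reference_levels = reference_levels),
            class = "design_matrix")
}

#' Build a design matrix for logistic fitting
#'
#' Expands a cohort table into a numeric design matrix: an intercept,
#' continuous predictors passed through, categorical predictors expanded to
#' k-1 treatment indicators against declared reference levels, and optional
#' hinge terms `max(x - knot, 0)` for piecewise-linear exposures.
#'
#' @param table Data frame.
#' @param outcome Name of the binary response column.
#' @param continuous Character vector of continuous predictor names.
#' @param categorical Named list or character vector. A character vector
#'   uses the first factor level as reference; a named list maps
#'   `name = reference_level`.
#' @param hinge_terms Named numeric vector mapping column name to knot,
#'   e.g. `c(ratio = 3.3)` adds a `ratio_hinge` column `max(ratio - 3.3, 0)`.
#' @param intercept Include an intercept column (default TRUE).
#' @return A `design_matrix` with `response`, `X`, `reference_levels`.
#' @details Unknown columns or reference levels are errors naming the
#'   offender. The matrix contains no missing values by construction; rows
#'   are never silently dropped (missingness must be resolved first, see
#'   [add_missing_dummies()]).
#' @export
build_design <- function(table, outcome, continuous = character(),
                         categorical = list(), hinge_terms = NULL,
                         intercept = TRUE) {
  all_cols <- c(outcome, continuous,
                if (is.list(categorical)) names(categorical) else categorical,
                names(hinge_terms))
  missing_cols <- setdiff(all_cols, names(table))
  if (length(missing_cols)) {
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  }
  y <- table[[outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  n <- nrow(table)
  parts <- list()
  if (intercept) parts$intercept <- rep(1, n)
  for (nm in continuous) {
    col <- table[[nm]]
    if (!is.numeric(col)) stop("column `", nm, "` is not numeric")
    parts[[nm]] <- col
  }
  if (is.character(categorical)) {
    categorical <- stats::setNames(vector("list", length(categorical)), categorical)
  }
  refs <- list()
  for (nm in names(categorical)) {
    col <- table[[nm]]
    f <- if (is.factor(col)) col else factor(col)
    ref <- categorical[[nm]]
    if (is.null(ref)) ref <- levels(f)[1L]
    if (!ref %in% levels(f)) {
      stop("reference level `", ref, "` not found in column `", nm, "`")
    }
    f <- stats::relevel(f, ref = ref)
    refs[[nm]] <- ref
    for (lv in levels(f)[-1L]) {
      parts[[paste0(nm, ":", lv)]] <- as.numeric(f == lv)
    }
  }
  for (nm in names(hinge_terms)) {
    parts[[paste0(nm, "_hinge")]] <- hinge(table[[nm]], hinge_terms[[nm]])
  }
  X <- do.call(cbind, parts)
  colnames(X) <- names(parts)
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("missing values in predictor column(s): ",
         paste(bad, collapse = ", "),
         "; apply add_missing_dummies() first")
  }
  design_matrix(y, X, refs)
}

#' Drop rows with missing exposure, with a logged count
#'
#' Exposure missingness is handled by exclusion (as when patients without a
#' lipid panel are excluded from a cohort), never by imputation.
#'
#' @param table Data frame.
#' @param exposure Exposure column name.
#' @return The table without exposure-missing rows; the number excluded is
#'   recorded in `attr(, "n_excluded")` and reported via `message()`.
#' @export
exclude_missing_exposure <- function(table, exposure = "ratio") {
  miss <- is.na(table[[exposure]])
  if (any(miss)) {
    message(sum(miss), " row(s) excluded for missing exposure `", exposure, "`")
    table <- table[!miss, , drop = FALSE]
    rownames(table) <- NULL
  }
  attr(table, "n_excluded") <- sum(miss)
  table
}
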