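# End-to-end pipeline: load or simulate a cohort, resolve missingness,
# build the descriptive tables, fit the smooth curve and the
# one-line/two-piecewise models, test non-linearity, bootstrap the turning
# point, rescale per SD, compute E-values, and write every artifact
# (CSV/Markdown tables, curve, consolidated JSON, run log) to an output
# directory. Reruns with the same config are bit-identical.

#' Validate and normalize an analysis configuration
#'
#' A config is a named list (or a YAML file path) with fields:
#' \describe{
#'   \item{input}{Path to a cohort CSV (see [read_cohort()]), or `NULL`
#'     when `synthetic` is given.}
#'   \item{synthetic}{Named list of [cohort_spec()] arguments for a
#'     simulated cohort.}
#'   \item{outcome}{`"death28"` (default) or `"death14"`.}
#'   \item{exposure}{Exposure column (default `"ratio"`).}
#'   \item{covariates}{Adjustment covariates (default: age, sex, weight,
#'     heart_rate, lactate, apache_iv, sofa, septic_shock,
#'     infection_site).}
#'   \item{screen_candidates}{Optional candidates for the 10%
#'     change-in-estimate confounder screen.}
#'   \item{grid_step, n_boot, seed, conf}{Turning-point search and
#'     bootstrap settings; the seed is mandatory when `n_boot > 0` or
#'     `synthetic` is used.}
#'   \item{out_dir}{Output directory.}
#' }
#'
#' @param config Named list or YAML path.
#' @return Normalized config list.
#' @export
analysis_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(outcome = "death28", exposure = "ratio",
                   covariates = c("age", "sex", "weight", "heart_rate",
                                  "lactate", "apache_iv", "sofa",
                                  "septic_shock", "infection_site"),
                   screen_candidates = NULL,
                   grid_step = 0.1, n_boot = 500L, conf = 0.95,
                   seed = NULL, out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (!config$outcome %in% c("death28", "death14")) {
    stop_field("outcome", "must be 'death28' or 'death14'")
  }
  if (is.null(config$input) && is.null(config$synthetic)) {
    stop_field("input", "either `input` (CSV path) or `synthetic` (cohort spec) is required")
  }
  if ((config$n_boot > 0 || !is.null(config$synthetic)) && is.null(config$seed)) {
    stop_field("seed", "mandatory when any stochastic stage is enabled")
  }
  config
}

write_md <- function(lines, path) writeLines(lines, path)

#' Run the full threshold-effect analysis pipeline
#'
#' Executes, in order: load/generate cohort, exposure-missingness
#' exclusion, missing-indicator adjustment, baseline (tertile) table,
#' unadjusted tertile odds ratios, optional confounder screen, smooth
#' dose-response curve, one-line and two-piecewise models with
#' profile-likelihood turning-point search, likelihood-ratio test,
#' bootstrap CI for the turning point, per-SD rescaling, and E-values for
#' the segment estimates. If `config$out_dir` is set, artifacts are
#' written there (`cohort.csv`, `table1.csv/.md`, `table2_tertiles.csv`,
#' `threshold.csv/.md`, `curve.csv`, `curve.png`, `results.json`,
#' `run.log`).
#'
#' @param config See [analysis_config()].
#' @return Invisibly, a list bundle: `cohort`, `table1`, `tertile_or`,
#'   `mortality_ci`, `screen`, `curve`, `threshold`, `evalues`, `log`.
#' @export
run_pipeline <- function(config) {
  config <- analysis_config(config)
  log_lines <- character()
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  stage <- "load"
  bundle <- tryCatch({
    if (!is.null(config$synthetic)) {
      spec_args <- config$synthetic
      if (is.null(spec_args$seed)) spec_args$seed <- config$seed
      spec <- do.call(cohort_spec, spec_args)
      cohort <- generate_cohort(spec)
      note("generated synthetic cohort: n = ", nrow(cohort),
           ", seed = ", spec$seed)
    } else {
      cohort <- read_cohort(config$input)
      note("loaded cohort from ", config$input, ": n = ", nrow(cohort))
    }
    cohort <- exclude_missing_exposure(cohort, config$exposure)
    note(attr(cohort, "n_excluded") %||% 0L,
         " rows excluded for missing exposure")

    stage <- "missing_dummies"
    covs <- intersect(config$covariates, names(cohort))
    num_covs <- covs[vapply(covs, function(nm) is.numeric(cohort[[nm]]), TRUE)]
    prepared <- add_missing_dummies(cohort, covariates = num_covs)
    inds <- attr(prepared, "indicator_columns")
    note("missing-indicator columns added: ",
         if (length(inds)) paste(inds, collapse = ", ") else "none")
    model_covs <- c(covs, inds)

    stage <- "table1"
    tert <- assign_tertiles(prepared[[config$exposure]])
    table1 <- build_baseline_table(cohort, tert)
    k <- sum(cohort[[config$outcome]])
    mort <- proportion_ci(k, nrow(cohort))
    note(sprintf("%s: %d/%d = %.2f%% (95%% CI %.2f-%.2f)", config$outcome,
                 k, nrow(cohort), 100 * mort[1], 100 * mort[2], 100 * mort[3]))

    stage <- "table2"
    tor <- tertile_or_table(prepared[[config$outcome]], tert)

    stage <- "confounder_screen"
    screen <- NULL
    if (!is.null(config$screen_candidates)) {
      screen <- screen_confounders(prepared, config$outcome, config$exposure,
                                   config$screen_candidates)
      note("confounder screen selected: ",
           paste(attr(screen, "selected"), collapse = ", "))
    }

    stage <- "smooth_curve"
    curve <- fit_smooth_logistic(prepared, config$outcome, config$exposure,
                                 covariates = model_covs)
    tr <- detect_turning_region(curve)
    note(sprintf("smooth curve: edf %.2f, minimum at %.2f, pattern %s",
                 curve$effective_df, tr$argmin_x, tr$pattern))

    stage <- "threshold"
    thr <- threshold_effect(prepared, config$outcome, config$exposure,
                            covariates = model_covs, step = config$grid_step,
                            n_boot = config$n_boot, seed = config$seed,
                            conf = config$conf)
    note(sprintf("turning point K = %.1f, LRT p = %.3f", thr$K_hat, thr$lrt_p))

    stage <- "evalue"
    evs <- list(
      below = evalue_report(thr$or_below[["or"]],
                            thr$or_below[c("lower", "upper")],
                            label = "below-threshold per-unit OR"),
      above = evalue_report(thr$or_above[["or"]],
                            thr$or_above[c("lower", "upper")],
                            label = "above-threshold per-unit OR"))
    note(sprintf("E-values: below %.2f, above %.2f",
                 evs$below$evalue_point, evs$above$evalue_point))

    list(cohort = cohort, prepared = prepared, tertiles = tert,
         table1 = table1, tertile_or = tor, mortality_ci = mort,
         screen = screen, curve = curve, threshold = thr, evalues = evs,
         log = log_lines)
  }, error = function(e) {
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    write_cohort(bundle$cohort, out("cohort.csv"))
    utils::write.csv(bundle$table1, out("table1.csv"), row.names = FALSE)
    write_md(format_baseline_md(bundle$table1), out("table1.md"))
    utils::write.csv(bundle$tertile_or, out("table2_tertiles.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(bundle$curve), out("curve.csv"),
                     row.names = FALSE)
    ok <- tryCatch({
      grDevices::png(out("curve.png"), width = 700, height = 500)
      plot(bundle$curve)
      grDevices::dev.off()
      TRUE
    }, error = function(e) FALSE)
    if (!ok) bundle$log <- c(bundle$log, "curve.png skipped (no png device)")
    thr_json <- threshold_result_json(bundle$threshold)
    results <- list(
      outcome = config$outcome,
      n = nrow(bundle$cohort),
      mortality = as.list(bundle$mortality_ci),
      tertile_or = bundle$tertile_or,
      threshold = thr_json,
      evalues = list(below = unclass(bundle$evalues$below)[
                       c("input_or", "evalue_point", "evalue_ci")],
                     above = unclass(bundle$evalues$above)[
                       c("input_or", "evalue_point", "evalue_ci")]),
      smooth = list(effective_df = bundle$curve$effective_df,
                    argmin = detect_turning_region(bundle$curve)$argmin_x))
    jsonlite::write_json(results, out("results.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    write_md(render_threshold_md(bundle$threshold), out("threshold.md"))
    utils::write.csv(threshold_table(bundle$threshold), out("threshold.csv"),
                     row.names = FALSE)
    writeLines(bundle$log, out("run.log"))
  }
  invisible(bundle)
}

threshold_table <- function(x, digits = 2) {
  rows <- list(
    c("Model I: one line effect", or_cell(x$one_line_or, digits),
      fmt_num(x$one_line_or[["p"]], 3), or_cell(x$one_line_or_sd, digits),
      fmt_num(x$one_line_or_sd[["p"]], 3)),
    c("Model II: turning point (K)", fmt_num(x$K_hat, 1),
      "", fmt_num(x$K_hat_sd, 2), ""),
    c("Exposure < K", or_cell(x$or_below, digits),
      fmt_num(x$or_below[["p"]], 3), or_cell(x$or_below_sd, digits),
      fmt_num(x$or_below_sd[["p"]], 3)),
    c("Exposure >= K", or_cell(x$or_above, digits),
      fmt_num(x$or_above[["p"]], 3), or_cell(x$or_above_sd, digits),
      fmt_num(x$or_above_sd[["p"]], 3)),
    c("P for LRT", fmt_num(x$lrt_p, 3), "", fmt_num(x$lrt_p, 3), ""),
    c("95% CI for turning point",
      if (is.na(x$K_ci[1])) "" else
        sprintf("%s, %s", fmt_num(x$K_ci[1], 1), fmt_num(x$K_ci[2], 1)),
      "",
      if (is.na(x$K_ci[1])) "" else
        sprintf("%s, %s", fmt_num(x$K_ci_sd[1], 2), fmt_num(x$K_ci_sd[2], 2)),
      ""))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("model", "per_unit_or", "per_unit_p", "per_sd_or", "per_sd_p")
  out
}

render_threshold_md <- function(x) {
  tab <- threshold_table(x)
  c("| Model | Per-unit OR (95% CI) | P | Per-SD OR (95% CI) | P |",
    "|---|---|---|---|---|",
    vapply(seq_len(nrow(tab)), function(i)
      sprintf("| %s | %s | %s | %s | %s |", tab$model[i], tab$per_unit_or[i],
              tab$per_unit_p[i], tab$per_sd_or[i], tab$per_sd_p[i]), ""))
}
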