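# Cohort CSV round-trip with a JSON schema sidecar.
#
# Numeric columns are written with "%.17g" so doubles survive the text
# round-trip exactly; missing values are empty fields; factor levels are
# declared in the sidecar so categories are restored with their vocabulary
# and ordering intact.

cohort_schema <- function(table) {
  cols <- lapply(names(table), function(nm) {
    col <- table[[nm]]
    entry <- list(name = nm,
                  type = if (is.factor(col)) "categorical"
                         else if (is.integer(col)) "integer"
                         else if (is.numeric(col)) "numeric"
                         else "character")
    if (is.factor(col)) entry$levels <- levels(col)
    entry$units <- switch(nm, ratio = "non-HDLc/HDLc ratio", age = "years",
                          weight = "kg", heart_rate = "bpm",
                          lactate = "mmol/L", NULL)
    entry
  })
  list(columns = cols, n_rows = nrow(table))
}

#' Write a cohort table to CSV with a schema sidecar
#'
#' @param table Cohort data frame.
#' @param path CSV path; the sidecar is written to `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- table
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.double(col)) {
      s <- sprintf("%.17g", col)
      s[is.na(col)] <- NA
      out[[nm]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  jsonlite::write_json(cohort_schema(table), paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' Applies the sidecar schema: numeric columns parsed as doubles, integer
#' columns as integers, categorical columns as factors with the declared
#' levels. Without a sidecar, plain `read.csv` typing is used.
#'
#' @param path CSV path.
#' @return A `cohort_table` data frame.
#' @export
read_cohort <- function(path) {
  schema_path <- paste0(path, ".schema.json")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (file.exists(schema_path)) {
    schema <- jsonlite::read_json(schema_path)
    for (entry in schema$columns) {
      nm <- entry$name
      if (!nm %in% names(tab)) next
      tab[[nm]] <- switch(entry$type,
        numeric = as.numeric(tab[[nm]]),
        integer = as.integer(tab[[nm]]),
        categorical = factor(tab[[nm]], levels = unlist(entry$levels)),
        as.character(tab[[nm]]))
    }
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Serialize / restore a cohort spec as YAML
#'
#' @param spec A [cohort_spec()].
#' @param path YAML file path.
#' @return `write_cohort_spec` returns `path` invisibly; `read_cohort_spec`
#'   returns the restored `cohort_spec` (the seed is mandatory in the file).
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("cohort spec file must declare a seed")
  raw$missing_rates <- unlist(raw$missing_rates) %||% c()
  do.call(cohort_spec, raw[intersect(names(raw), names(formals(cohort_spec)))])
}
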