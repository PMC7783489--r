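#' Construct a validated cohort
#'
#' A cohort is the universal tabular input: one row per subject, with a
#' unique `id`, a 0/1 `treated` indicator, the outcome column, and the
#' covariate columns declared by a [covariate_schema()]. Binary outcomes
#' must be coded 0/1. Missing covariate values are allowed and kept
#' explicit: downstream fitting excludes (and reports) incomplete rows
#' rather than imputing.
#'
#' @param data data.frame with columns `id`, `treated`, the outcome column,
#'   and one column per schema variable. Extra columns are rejected unless
#'   listed in `extra_columns` (used e.g. for the preference bookkeeping of
#'   simulated randomized cohorts).
#' @param schema a [covariate_schema()].
#' @param outcome name of the outcome column (default `"outcome"`).
#' @param outcome_scale `"continuous"` or `"binary"`; never inferred.
#' @param extra_columns character vector of permitted non-schema columns.
#' @return object of class `vc_cohort`: list with elements `data`, `schema`,
#'   `outcome_spec = list(name, scale)`.
#' @export
cohort <- function(data, schema, outcome = "outcome",
                   outcome_scale = c("continuous", "binary"),
                   extra_columns = character(0)) {
  outcome_scale <- match.arg(outcome_scale)
  stopifnot(is.data.frame(data))
  required <- c("id", "treated", outcome, schema_variables(schema))
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(data), c(required, extra_columns))
  if (length(unknown))
    stop("schema error: unexpected column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  data$id <- as.character(data$id)
  if (anyDuplicated(data$id))
    stop("validation error: duplicate subject id(s): ",
         paste(unique(data$id[duplicated(data$id)]), collapse = ", "),
         call. = FALSE)
  tr <- suppressWarnings(as.numeric(data$treated))
  bad <- is.na(tr) | !(tr %in% c(0, 1))
  if (any(bad))
    stop("validation error: 'treated' must be 0/1; offending row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  data$treated <- as.integer(tr)

  y <- suppressWarnings(as.numeric(data[[outcome]]))
  if (any(is.na(y) & !is.na(data[[outcome]])))
    stop("validation error: outcome '", outcome,
         "' is not numeric in row(s) ",
         paste(which(is.na(y) & !is.na(data[[outcome]])), collapse = ", "),
         call. = FALSE)
  if (outcome_scale == "binary") {
    bad <- !is.na(y) & !(y %in% c(0, 1))
    if (any(bad))
      stop("validation error: binary outcome '", outcome,
           "' has value(s) outside {0,1} in row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
  }
  data[[outcome]] <- y

  # type-check covariates (raises row-level diagnostics)
  invisible(expand_design(schema, data))

  structure(list(data = data, schema = schema,
                 outcome_spec = list(name = outcome, scale = outcome_scale)),
            class = "vc_cohort")
}

#' @export
print.vc_cohort <- function(x, ...) {
  n <- nrow(x$data)
  nt <- sum(x$data$treated == 1)
  cat(sprintf("Cohort: %d subjects (%d treated, %d untreated)\n",
              n, nt, n - nt))
  cat(sprintf("Outcome: %s (%s)\n", x$outcome_spec$name, x$outcome_spec$scale))
  cat("Covariates:", paste(schema_variables(x$schema), collapse = ", "), "\n")
  invisible(x)
}

#' @export
nobs.vc_cohort <- function(object, ...) nrow(object$data)

cohort_outcome <- function(ch) ch$data[[ch$outcome_spec$name]]

## rows with complete covariate information
complete_covariate_rows <- function(ch) {
  vars <- schema_variables(ch$schema)
  if (!length(vars)) return(rep(TRUE, nrow(ch$data)))
  stats::complete.cases(ch$data[, vars, drop = FALSE])
}

#' Read a cohort from a delimited text file
#'
#' Reads a comma-delimited, headered, UTF-8 file with "." decimal marks and
#' validates it against a schema and outcome specification. Validation
#' failures name the offending rows; nothing is silently dropped.
#'
#' @param path file path.
#' @inheritParams cohort
#' @return a `vc_cohort`.
#' @export
read_cohort <- function(path, schema, outcome = "outcome",
                        outcome_scale = c("continuous", "binary"),
                        extra_columns = character(0)) {
  if (!file.exists(path))
    stop("file error: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  cohort(df, schema, outcome = outcome, outcome_scale = outcome_scale,
         extra_columns = extra_columns)
}

#' Write a cohort to a delimited text file
#'
#' Writes `id`, `treated`, the outcome, and the schema covariate columns
#' (in schema order) as comma-delimited text. [read_cohort()] of the result
#' reproduces the cohort exactly.
#'
#' @param ch a `vc_cohort`.
#' @param path file path.
#' @export
write_cohort <- function(ch, path) {
  stopifnot(inherits(ch, "vc_cohort"))
  cols <- c("id", "treated", ch$outcome_spec$name, schema_variables(ch$schema))
  utils::write.csv(ch$data[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
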