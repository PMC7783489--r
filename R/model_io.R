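#' Construct a prognostic model
#'
#' A prognostic model is the shareable research product of the framework:
#' a versioned coefficient set (linear or logistic), the covariate schema
#' it expects (including the training-time support intervals used for
#' extrapolation warnings), and training metadata. Models fitted by
#' [fit_prognostic_model()] additionally carry the coefficient covariance
#' matrix (for analytic uncertainty propagation) and, in memory only, the
#' training cohort (for pooling and bootstrap refits); serialization keeps
#' the coefficient set and metadata.
#'
#' @param family `"linear"` or `"logistic"`.
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector over the schema's expanded
#'   (dummy-coded) variable names.
#' @param schema a [covariate_schema()].
#' @param training_meta list with at least `n` (training rows used),
#'   `precision` (R-squared for linear; Brier score for logistic),
#'   `version` (integer >= 1), `provenance` (free text).
#' @param vcov optional covariance matrix of `(intercept, coefficients)`.
#' @return object of class `prognostic_model`.
#' @export
prognostic_model <- function(family = c("linear", "logistic"), intercept,
                             coefficients, schema, training_meta,
                             vcov = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(schema, "covariate_schema"))
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop("model error: intercept must be a finite number", call. = FALSE)
  coefficients <- unlist(coefficients)
  exp_nm <- expanded_names(schema)
  if (length(coefficients)) {
    if (is.null(names(coefficients)) ||
        !all(names(coefficients) %in% exp_nm))
      stop("model error: coefficient names must be a subset of the schema's ",
           "expanded variable names", call. = FALSE)
  }
  tm <- training_meta
  for (f in c("n", "precision", "version", "provenance"))
    if (is.null(tm[[f]])) stop("model error: training_meta missing '", f, "'",
                               call. = FALSE)
  if (tm$version < 1) stop("model error: version must be >= 1", call. = FALSE)
  n_par <- 1L + length(coefficients)
  if (tm$n < n_par + 1L)
    stop("model error: training n (", tm$n, ") must exceed parameter count (",
         n_par, ")", call. = FALSE)
  structure(list(family = family, intercept = intercept,
                 coefficients = coefficients, schema = schema,
                 training_meta = tm, vcov = vcov),
            class = "prognostic_model")
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat(sprintf("Prognostic model (%s), version %d\n", x$family,
              as.integer(x$training_meta$version)))
  cat(sprintf("  trained on n = %d; precision (%s) = %.4f\n",
              as.integer(x$training_meta$n),
              if (x$family == "linear") "R-squared" else "Brier",
              as.numeric(x$training_meta$precision)))
  cat(sprintf("  intercept: %.6g\n", x$intercept))
  for (nm in names(x$coefficients))
    cat(sprintf("  %-16s %.6g\n", nm, x$coefficients[[nm]]))
  invisible(x)
}

schema_to_list <- function(s) {
  list(variables = lapply(names(s$kinds), function(v) {
    out <- list(name = v, kind = s$kinds[[v]])
    if (!is.null(s$support[[v]])) out$support <- as.numeric(s$support[[v]])
    if (!is.null(s$levels[[v]])) out$levels <- as.character(s$levels[[v]])
    out
  }))
}

schema_from_list <- function(l) {
  vars <- l$variables
  kinds <- vapply(vars, function(v) v$kind, character(1))
  names(kinds) <- vapply(vars, function(v) v$name, character(1))
  support <- list(); levels <- list()
  for (v in vars) {
    if (!is.null(v$support)) support[[v$name]] <- as.numeric(v$support)
    if (!is.null(v$levels)) levels[[v$name]] <- as.character(v$levels)
  }
  covariate_schema(kinds, support = support, levels = levels)
}

#' Write a prognostic model to a coefficient-set file
#'
#' Serializes the model (family, intercept, coefficients, schema with
#' support intervals, training metadata, and — when present — the
#' coefficient covariance) as structured JSON text. The serialization is
#' lossless for these fields; [read_model()] of the result reproduces
#' them to full precision. The in-memory training-cohort attachment is
#' deliberately not serialized: the shared research product is the
#' coefficient set.
#'
#' @param model a `prognostic_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "prognostic_model"))
  obj <- list(
    format = "virtualcontrols-model",
    family = model$family,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    schema = schema_to_list(model$schema),
    training_meta = model$training_meta)
  if (!is.null(model$vcov))
    obj$vcov <- list(names = colnames(model$vcov),
                     values = unclass(model$vcov))
  # I(17) significant digits: doubles survive the decimal round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a prognostic model from a coefficient-set file
#'
#' @param path file path written by [write_model()].
#' @return a `prognostic_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path))
    stop("file error: no such file: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("format error: not a readable coefficient-set file: ",
                         conditionMessage(e), call. = FALSE))
  for (f in c("family", "intercept", "coefficients", "schema", "training_meta"))
    if (is.null(obj[[f]]))
      stop("format error: coefficient-set file missing field '", f, "'",
           call. = FALSE)
  vcov <- NULL
  if (!is.null(obj$vcov)) {
    nm <- unlist(obj$vcov$names)
    vcov <- do.call(rbind, lapply(obj$vcov$values, unlist))
    dimnames(vcov) <- list(nm, nm)
  }
  tm <- obj$training_meta
  tm$n <- as.numeric(tm$n); tm$version <- as.integer(tm$version)
  tm$precision <- as.numeric(tm$precision)
  prognostic_model(family = obj$family,
                   intercept = as.numeric(obj$intercept),
                   coefficients = unlist(obj$coefficients),
                   schema = schema_from_list(obj$schema),
                   training_meta = tm, vcov = vcov)
}
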