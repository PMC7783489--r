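#' Covariate schema
#'
#' A `covariate_schema` records, in order, the predictor variables a
#' prognostic model expects: their names, kinds, the observed support
#' interval of each continuous variable at training time, and the levels
#' of each categorical variable. Support intervals record the covariate
#' ranges seen during training, so that later predictions can be flagged
#' when they extrapolate beyond the training experience.
#'
#' @param kinds named character vector mapping variable name to one of
#'   `"continuous"`, `"binary"`, `"categorical"`.
#' @param support named list of length-2 numeric vectors `c(min, max)` for
#'   continuous variables; may be empty (set at fitting time).
#' @param levels named list of character vectors giving the levels of each
#'   categorical variable; the first level is the reference level for
#'   dummy coding.
#' @return object of class `covariate_schema`.
#' @export
covariate_schema <- function(kinds, support = list(), levels = list()) {
  if (length(kinds) &&
      (is.null(names(kinds)) || any(!nzchar(names(kinds)))))
    stop("schema error: every variable must be named", call. = FALSE)
  nm <- names(kinds)
  if (anyDuplicated(nm))
    stop("schema error: duplicate variable names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  kinds <- as.character(kinds)
  ok <- kinds %in% c("continuous", "binary", "categorical")
  if (any(!ok))
    stop("schema error: unknown kind(s): ",
         paste(unique(kinds[!ok]), collapse = ", "), call. = FALSE)
  names(kinds) <- nm
  for (v in names(support)) {
    s <- support[[v]]
    if (!is.numeric(s) || length(s) != 2L || any(!is.finite(s)) || s[1] > s[2])
      stop("schema error: support for '", v,
           "' must be a finite c(min, max) with min <= max", call. = FALSE)
  }
  cat_vars <- nm[kinds == "categorical"]
  for (v in cat_vars) {
    lv <- levels[[v]]
    if (is.null(lv) || length(lv) < 2L)
      stop("schema error: categorical variable '", v,
           "' must list at least two levels", call. = FALSE)
  }
  structure(list(kinds = kinds,
                 support = support[intersect(names(support), nm)],
                 levels = levels[intersect(names(levels), cat_vars)]),
            class = "covariate_schema")
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("Covariate schema (", length(x$kinds), " variables)\n", sep = "")
  for (v in names(x$kinds)) {
    extra <- ""
    if (x$kinds[[v]] == "continuous" && !is.null(x$support[[v]]))
      extra <- sprintf("  support [%g, %g]", x$support[[v]][1], x$support[[v]][2])
    if (x$kinds[[v]] == "categorical")
      extra <- paste0("  levels: ", paste(x$levels[[v]], collapse = "/"))
    cat(sprintf("  %-16s %-12s%s\n", v, x$kinds[[v]], extra))
  }
  invisible(x)
}

schema_variables <- function(schema) names(schema$kinds)

## Names of the expanded (dummy-coded) design columns, in schema order.
## Categorical variables expand to one column per non-reference level,
## named "var=level".
expanded_names <- function(schema) {
  out <- character(0)
  for (v in names(schema$kinds)) {
    if (schema$kinds[[v]] == "categorical") {
      lv <- schema$levels[[v]]
      out <- c(out, paste0(v, "=", lv[-1L]))
    } else {
      out <- c(out, v)
    }
  }
  out
}

## Expand covariate columns of `data` into a numeric design matrix
## (no intercept column) following the schema's dummy coding.
## Rows with missing covariate values propagate NA.
expand_design <- function(schema, data) {
  cols <- list()
  for (v in names(schema$kinds)) {
    kind <- schema$kinds[[v]]
    x <- data[[v]]
    if (kind == "categorical") {
      lv <- schema$levels[[v]]
      bad <- !is.na(x) & !(x %in% lv)
      if (any(bad))
        stop("validation error: variable '", v, "' has value(s) outside its ",
             "declared levels in row(s) ", paste(which(bad), collapse = ", "),
             call. = FALSE)
      for (l in lv[-1L]) cols[[paste0(v, "=", l)]] <- as.numeric(x == l)
    } else {
      xn <- suppressWarnings(as.numeric(x))
      if (any(!is.na(x) & is.na(xn)))
        stop("validation error: variable '", v, "' is not numeric in row(s) ",
             paste(which(!is.na(x) & is.na(xn)), collapse = ", "), call. = FALSE)
      if (kind == "binary") {
        bad <- !is.na(xn) & !(xn %in% c(0, 1))
        if (any(bad))
          stop("validation error: binary variable '", v,
               "' has non-{0,1} value(s) in row(s) ",
               paste(which(bad), collapse = ", "), call. = FALSE)
      }
      cols[[v]] <- xn
    }
  }
  if (!length(cols)) return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  do.call(cbind, cols)
}

## Variables of `data` whose observed values fall outside the schema's
## recorded support (continuous variables only). Used for truncation /
## extrapolation warnings.
support_violations <- function(schema, data) {
  out <- character(0)
  for (v in names(schema$support)) {
    s <- schema$support[[v]]
    x <- suppressWarnings(as.numeric(data[[v]]))
    if (any(!is.na(x) & (x < s[1] | x > s[2]))) out <- c(out, v)
  }
  out
}

## Per-row logical: any continuous covariate outside support.
rows_outside_support <- function(schema, data) {
  flag <- rep(FALSE, nrow(data))
  for (v in names(schema$support)) {
    s <- schema$support[[v]]
    x <- suppressWarnings(as.numeric(data[[v]]))
    flag <- flag | (!is.na(x) & (x < s[1] | x > s[2]))
  }
  flag
}

## Merge two schemas for pooling: shared variables must agree in kind;
## new variables extend the schema. Categorical levels are unioned
## (reference level of the first schema wins).
merge_schemas <- function(a, b) {
  kinds <- a$kinds
  levels <- a$levels
  for (v in names(b$kinds)) {
    if (v %in% names(kinds)) {
      if (kinds[[v]] != b$kinds[[v]])
        stop("schema conflict error: variable '", v, "' is ", kinds[[v]],
             " in one cohort and ", b$kinds[[v]], " in another", call. = FALSE)
      if (kinds[[v]] == "categorical")
        levels[[v]] <- union(levels[[v]], b$levels[[v]])
    } else {
      kinds[v] <- b$kinds[[v]]
      if (b$kinds[[v]] == "categorical") levels[[v]] <- b$levels[[v]]
    }
  }
  covariate_schema(kinds, support = list(), levels = levels)
}
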