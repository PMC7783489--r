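## Core fitting machinery. Linear models are fit by QR least squares and
## logistic models by iteratively reweighted least squares (stats::glm.fit),
## with explicit separation and convergence checks; both return the
## coefficient covariance needed for analytic uncertainty propagation.

fit_linear <- function(X1, y) {
  qr_ <- qr(X1)
  if (qr_$rank < ncol(X1)) {
    bad <- colnames(X1)[qr_$pivot[seq(qr_$rank + 1L, ncol(X1))]]
    stop("singularity error: design is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_, y)
  res <- y - drop(X1 %*% beta)
  dfres <- length(y) - ncol(X1)
  sigma2 <- sum(res^2) / dfres
  XtXinv <- chol2inv(qr.R(qr_))
  dimnames(XtXinv) <- list(colnames(X1), colnames(X1))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  list(beta = beta, vcov = sigma2 * XtXinv, r2 = r2, sigma2 = sigma2)
}

fit_logistic <- function(X1, y, maxit = 100L, epsilon = 1e-8) {
  qr_ <- qr(X1)
  if (qr_$rank < ncol(X1)) {
    bad <- colnames(X1)[qr_$pivot[seq(qr_$rank + 1L, ncol(X1))]]
    stop("singularity error: design is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(
    X1, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)))
  mu <- fit$fitted.values
  if (!fit$converged)
    stop("convergence error: logistic fit did not converge in ", fit$iter,
         " iterations", call. = FALSE)
  sep <- all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6) &&
    any(y == 1) && any(y == 0)
  if (sep)
    stop("convergence error: perfect separation detected after ", fit$iter,
         " iterations; logistic coefficients diverge", call. = FALSE)
  w <- fit$weights
  vcov <- solve(crossprod(X1 * sqrt(w)))
  dimnames(vcov) <- list(colnames(X1), colnames(X1))
  list(beta = stats::coef(fit), vcov = vcov,
       brier = mean((y - mu)^2), iter = fit$iter)
}

#' Fit a prognostic model on an untreated cohort
#'
#' Fits the outcome model that will later generate virtual controls:
#' ordinary least squares for continuous outcomes, maximum-likelihood
#' logistic regression for binary outcomes. The training cohort must be
#' entirely untreated. Rows with missing covariate values are excluded
#' from the fit and counted (never imputed). The fitted model's schema
#' records the observed min/max of each continuous covariate as its
#' support interval, the basis for later extrapolation warnings; its
#' precision (R-squared, or Brier score for logistic models) is stored in
#' `training_meta`.
#'
#' @param training a `vc_cohort` of untreated subjects.
#' @param provenance free-text note stored in the model's metadata.
#' @param version model version (integer >= 1).
#' @return a [prognostic_model()] with coefficient covariance attached and
#'   the training cohort kept in memory for pooling/bootstrap refits.
#' @export
fit_prognostic_model <- function(training, provenance = "", version = 1L) {
  stopifnot(inherits(training, "vc_cohort"))
  if (any(training$data$treated != 0))
    stop("contract error: training cohort contains treated subjects; ",
         "prognostic models are fit on untreated data only", call. = FALSE)
  use <- complete_covariate_rows(training) & !is.na(cohort_outcome(training))
  n_excluded <- sum(!use)
  dat <- training$data[use, , drop = FALSE]
  y <- dat[[training$outcome_spec$name]]
  X <- expand_design(training$schema, dat)
  X1 <- cbind("(Intercept)" = 1, X)
  n_par <- ncol(X1)
  if (nrow(X1) < n_par + 1L)
    stop("contract error: training n (", nrow(X1),
         ") must exceed parameter count (", n_par, ")", call. = FALSE)

  family <- if (training$outcome_spec$scale == "continuous") "linear"
            else "logistic"
  fit <- if (family == "linear") fit_linear(X1, y) else fit_logistic(X1, y)

  schema <- training$schema
  for (v in names(schema$kinds)[schema$kinds == "continuous"]) {
    x <- dat[[v]]
    schema$support[[v]] <- c(min(x, na.rm = TRUE), max(x, na.rm = TRUE))
  }

  precision <- if (family == "linear") fit$r2 else fit$brier
  model <- prognostic_model(
    family = family,
    intercept = unname(fit$beta[1L]),
    coefficients = fit$beta[-1L],
    schema = schema,
    training_meta = list(n = nrow(X1), precision = precision,
                         version = as.integer(version),
                         provenance = provenance,
                         n_excluded_missing = n_excluded),
    vcov = fit$vcov)
  model$training_data <- training
  model
}

## linear predictor for rows of `data` with complete covariates
linear_predictor <- function(model, data) {
  X <- expand_design(model$schema, data)
  co <- rep(0, ncol(X)); names(co) <- colnames(X)
  if (length(model$coefficients))
    co[names(model$coefficients)] <- model$coefficients
  model$intercept + drop(X %*% co)
}

check_schema_compat <- function(model, ch) {
  miss <- setdiff(schema_variables(model$schema), names(ch$data))
  if (length(miss))
    stop("contract error: cohort lacks model covariate(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  scale_needed <- if (model$family == "linear") "continuous" else "binary"
  if (ch$outcome_spec$scale != scale_needed)
    stop("contract error: ", model$family, " model requires a ",
         scale_needed, " outcome; cohort outcome is ",
         ch$outcome_spec$scale, call. = FALSE)
  invisible(TRUE)
}

new_validation_report <- function(x) structure(x, class = "validation_report")

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (%s family), n = %d\n", x$family, x$n))
  if (x$family == "linear") {
    cat(sprintf("  R-squared: %.4f   mean error: %.4g\n", x$r_squared,
                x$mean_error))
  } else {
    cat(sprintf("  Brier: %.4f   mean observed: %.4f   mean predicted: %.4f\n",
                x$brier, x$mean_observed, x$mean_predicted))
  }
  if (is.na(x$calibration_slope)) {
    cat("  calibration slope: undefined (zero-variance predictions)\n")
  } else {
    cat(sprintf("  calibration slope: %.4f   intercept: %.4g\n",
                x$calibration_slope, x$calibration_intercept))
  }
  if (length(x$truncation_warnings))
    cat("  truncation warnings:",
        paste(x$truncation_warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Quantify a model's predictive precision on a cohort
#'
#' For linear models: R-squared (1 - SSE/SST), mean error, and the
#' calibration regression of observed on predicted outcomes. For logistic
#' models: calibration slope/intercept on the linear predictor, mean
#' observed versus mean predicted event rate, and the Brier score.
#' Applied to the model's own training data this reproduces the stored
#' training precision. A zero-variance prediction vector makes the
#' calibration slope undefined; it is reported as `NA` (an explicit
#' sentinel), not an error.
#'
#' @param model a `prognostic_model`.
#' @param ch a `vc_cohort` whose covariates match the model schema.
#' @return object of class `validation_report`.
#' @export
model_precision <- function(model, ch) {
  stopifnot(inherits(model, "prognostic_model"), inherits(ch, "vc_cohort"))
  check_schema_compat(model, ch)
  use <- complete_covariate_rows(ch) & !is.na(cohort_outcome(ch))
  dat <- ch$data[use, , drop = FALSE]
  if (!nrow(dat)) stop("contract error: no complete rows to validate on",
                       call. = FALSE)
  y <- dat[[ch$outcome_spec$name]]
  lp <- linear_predictor(model, dat)

  if (model$family == "linear") {
    pred <- lp
    sse <- sum((y - pred)^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sse / sst else NA_real_
    if (stats::var(pred) > 0) {
      cal <- stats::lm.fit(cbind(1, pred), y)$coefficients
      slope <- cal[2L]; intercept <- cal[1L]
    } else {
      slope <- NA_real_; intercept <- mean(y) - pred[1L]
    }
    new_validation_report(list(
      family = "linear", n = length(y), r_squared = r2,
      mean_error = mean(y - pred),
      calibration_slope = unname(slope),
      calibration_intercept = unname(intercept),
      truncation_warnings = character(0)))
  } else {
    p <- stats::plogis(lp)
    if (stats::var(lp) > 0) {
      cal <- suppressWarnings(stats::glm.fit(cbind(1, lp), y,
                                             family = stats::binomial()))
      slope <- cal$coefficients[2L]; intercept <- cal$coefficients[1L]
    } else {
      slope <- NA_real_; intercept <- NA_real_
    }
    new_validation_report(list(
      family = "logistic", n = length(y),
      brier = mean((y - p)^2),
      mean_observed = mean(y), mean_predicted = mean(p),
      calibration_slope = unname(slope),
      calibration_intercept = unname(intercept),
      truncation_warnings = character(0)))
  }
}

#' Externally validate a model on an independent untreated cohort
#'
#' Out-of-sample counterpart of [model_precision()]. In addition to the
#' precision and calibration summaries, the report lists every covariate
#' whose observed range extends beyond the model's training support — the
#' truncation warning that cautions against generalizing a model fitted
#' on a restricted covariate range. If the model does not transport
#' (calibration slope far from 1, intercept far from 0), the intended
#' remedy is to find the variables accounting for the difference and
#' extend the model via [pool_and_refit()].
#'
#' @param model a `prognostic_model`.
#' @param independent an untreated `vc_cohort`, independently collected
#'   (disjointness from the training data is the caller's assertion).
#' @return object of class `validation_report` with a
#'   `truncation_warnings` field.
#' @export
validate_external <- function(model, independent) {
  if (any(independent$data$treated != 0))
    stop("contract error: external validation cohort must be untreated",
         call. = FALSE)
  rep_ <- model_precision(model, independent)
  rep_$truncation_warnings <- support_violations(model$schema,
                                                 independent$data)
  rep_
}

#' Pool new untreated cohorts into a model and refit
#'
#' Implements the iterative refinement loop: new untreated data sets are
#' pooled with the model's training data, the model is refit from scratch
#' on the concatenation, the version number is incremented, and support
#' intervals widen to the pooled covariate ranges. New variables present
#' only in the newer cohorts extend the schema; rows from cohorts that
#' never measured an extended variable are treated as missing there and
#' excluded from the extended fit ("today's confounder is tomorrow's
#' predictor"). The pooled fit equals a from-scratch fit on the
#' concatenated table.
#'
#' @param model a fitted `prognostic_model` carrying its training data.
#' @param new_cohorts list of untreated `vc_cohort`s (may be empty, in
#'   which case the refit is the identity up to version number).
#' @return a new `prognostic_model` with `version` incremented.
#' @export
pool_and_refit <- function(model, new_cohorts = list()) {
  stopifnot(inherits(model, "prognostic_model"))
  if (is.null(model$training_data))
    stop("contract error: model carries no training data (deserialized ",
         "coefficient sets cannot be pooled); refit from the original ",
         "cohorts instead", call. = FALSE)
  if (inherits(new_cohorts, "vc_cohort")) new_cohorts <- list(new_cohorts)
  for (ch in new_cohorts)
    if (any(ch$data$treated != 0))
      stop("contract error: pooled cohorts must be untreated", call. = FALSE)

  base <- model$training_data
  schema <- base$schema
  for (ch in new_cohorts) schema <- merge_schemas(schema, ch$schema)

  outcome <- base$outcome_spec$name
  all_ch <- c(list(base), new_cohorts)
  vars <- schema_variables(schema)
  frames <- lapply(seq_along(all_ch), function(i) {
    ch <- all_ch[[i]]
    d <- ch$data
    d <- d[, c("id", "treated", ch$outcome_spec$name,
               intersect(vars, names(d))), drop = FALSE]
    names(d)[3L] <- outcome
    for (v in setdiff(vars, names(d))) d[[v]] <- NA
    d$id <- paste0("c", i, ":", d$id)
    d[, c("id", "treated", outcome, vars), drop = FALSE]
  })
  pooled <- do.call(rbind, frames)
  pooled_ch <- cohort(pooled, schema, outcome = outcome,
                      outcome_scale = base$outcome_spec$scale)
  fit_prognostic_model(
    pooled_ch,
    provenance = paste0(model$training_meta$provenance,
                        " | pooled ", length(new_cohorts), " cohort(s)"),
    version = model$training_meta$version + 1L)
}
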