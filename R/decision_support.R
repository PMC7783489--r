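#' Per-patient counterfactual report
#'
#' The clinical end-product of the framework: for one patient's
#' covariates, the predicted outcome without the intervention (from the
#' untreated-cohort model) and with the intervention (from a model fit on
#' accumulated treated subjects by the same machinery), each with a
#' confidence interval and extrapolation warnings. Intervals use the
#' linear-predictor variance when the model carries its coefficient
#' covariance ("analytic"); otherwise, if the model still holds its
#' training data, a bootstrap interval is computed; failing both, the
#' interval is reported as unavailable. For logistic models the interval
#' is formed on the log-odds scale and transformed, so the with/without
#' difference on the probability scale is patient-specific even when the
#' underlying log-odds shift is constant.
#'
#' The report is a pure function of the two models and the covariates.
#' No effect-transport shortcut is applied: if only a pooled effect
#' estimate exists rather than a treated-outcome model, that arithmetic
#' must be done explicitly by the caller and labelled as such.
#'
#' @param model_untreated prognostic model trained on untreated subjects.
#' @param model_treated prognostic model trained on treated subjects;
#'   must share the untreated model's outcome scale.
#' @param covariates named list or one-row data.frame of patient
#'   covariate values; validated against both schemas.
#' @param level confidence level for the intervals.
#' @param boot_B bootstrap replicates for the fallback interval.
#' @return object of class `patient_report`.
#' @export
patient_report <- function(model_untreated, model_treated, covariates,
                           level = 0.95, boot_B = 200L) {
  stopifnot(inherits(model_untreated, "prognostic_model"),
            inherits(model_treated, "prognostic_model"))
  if (model_untreated$family != model_treated$family)
    stop("contract error: with/without models must share an outcome scale (",
         model_untreated$family, " vs ", model_treated$family, ")",
         call. = FALSE)
  cov_df <- as.data.frame(covariates, stringsAsFactors = FALSE)
  stopifnot(nrow(cov_df) == 1L)

  one <- function(model, label) {
    miss <- setdiff(schema_variables(model$schema), names(cov_df))
    if (length(miss))
      stop("contract error: covariates missing for ", label, " model: ",
           paste(miss, collapse = ", "), call. = FALSE)
    lp <- linear_predictor(model, cov_df)
    se <- NA_real_; interval_method <- "unavailable"
    if (!is.null(model$vcov)) {
      X1 <- cbind(1, expand_design(model$schema, cov_df))
      nm <- c("(Intercept)", names(model$coefficients))
      V <- model$vcov[nm, nm, drop = FALSE]
      se <- sqrt(drop(X1 %*% V %*% t(X1)))
      interval_method <- "analytic (linear-predictor variance)"
    } else if (!is.null(model$training_data)) {
      lps <- vapply(seq_len(boot_B), function(b) {
        d <- model$training_data$data
        d <- d[sample.int(nrow(d), replace = TRUE), , drop = FALSE]
        d$id <- as.character(seq_len(nrow(d)))
        chb <- cohort(d, model$training_data$schema,
                      outcome = model$training_data$outcome_spec$name,
                      outcome_scale = model$training_data$outcome_spec$scale)
        linear_predictor(fit_prognostic_model(chb), cov_df)
      }, numeric(1))
      se <- stats::sd(lps)
      interval_method <- "bootstrap-propagated"
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    lp_ci <- if (is.na(se)) c(NA_real_, NA_real_) else c(lp - z * se, lp + z * se)
    if (model$family == "logistic") {
      pred <- stats::plogis(lp); ci <- stats::plogis(lp_ci)
    } else {
      pred <- lp; ci <- lp_ci
    }
    list(prediction = pred, ci = ci, interval_method = interval_method,
         extrapolation = support_violations(model$schema, cov_df),
         version = model$training_meta$version)
  }

  without <- one(model_untreated, "untreated")
  with_ <- one(model_treated, "treated")
  structure(list(covariates = cov_df, level = level,
                 scale = if (model_untreated$family == "linear")
                   "continuous" else "probability",
                 without = without, with_treatment = with_),
            class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  fmt <- function(p) {
    ci <- if (any(is.na(p$ci))) "CI unavailable"
    else sprintf("%g%% CI [%.3g, %.3g], %s", 100 * x$level, p$ci[1],
                 p$ci[2], p$interval_method)
    sprintf("%.3g (%s; model v%d)", p$prediction, ci, p$version)
  }
  cat("Patient counterfactual report (", x$scale, " scale)\n", sep = "")
  cat("  Given your data, the predicted outcome without this intervention is\n")
  cat("    ", fmt(x$without), "\n")
  cat("  and the predicted outcome with this intervention is\n")
  cat("    ", fmt(x$with_treatment), "\n")
  for (side in c("without", "with_treatment")) {
    w <- x[[side]]$extrapolation
    if (length(w))
      cat(sprintf("  warning: covariate(s) outside the %s model's training support: %s\n",
                  if (side == "without") "untreated" else "treated",
                  paste(w, collapse = ", ")))
  }
  invisible(x)
}
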