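#' Predict virtual controls for a treated cohort
#'
#' Plugs each treated subject's covariates into the prognostic model to
#' obtain that subject's predicted counterfactual outcome under no
#' intervention — the virtual control. Linear models return predicted
#' values; logistic models return predicted event probabilities
#' (inverse-logit of the linear predictor). Subjects whose covariates fall
#' outside the model's training support are flagged as extrapolations;
#' subjects with missing covariates are skipped with a warning and listed
#' in the result.
#'
#' @param model a `prognostic_model`.
#' @param treated a `vc_cohort` with `treated == 1` throughout.
#' @return object of class `virtual_control_set`: a data.frame with
#'   columns `id`, `predicted`, `lp` (linear predictor), `extrapolated`;
#'   attributes carry the model family/version, skipped ids, and — when
#'   the model has a coefficient covariance — the variance of the mean
#'   linear predictor used for analytic uncertainty propagation.
#' @export
predict_virtual_controls <- function(model, treated) {
  stopifnot(inherits(model, "prognostic_model"), inherits(treated, "vc_cohort"))
  if (any(treated$data$treated != 1))
    stop("contract error: cohort passed for virtual-control prediction ",
         "must be entirely treated (treated == 1)", call. = FALSE)
  check_schema_compat(model, treated)

  vars <- schema_variables(model$schema)
  cc <- if (length(vars))
    stats::complete.cases(treated$data[, vars, drop = FALSE])
  else rep(TRUE, nrow(treated$data))
  skipped <- treated$data$id[!cc]
  if (length(skipped))
    warning("skipping ", length(skipped),
            " subject(s) with missing covariates: ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "", call. = FALSE)
  dat <- treated$data[cc, , drop = FALSE]

  lp <- linear_predictor(model, dat)
  pred <- if (model$family == "linear") lp else stats::plogis(lp)
  extrap <- rows_outside_support(model$schema, dat)

  out <- data.frame(id = dat$id, predicted = pred, lp = lp,
                    extrapolated = extrap, stringsAsFactors = FALSE)
  mean_lp_var <- NA_real_
  if (!is.null(model$vcov) && nrow(dat) > 0) {
    X1 <- cbind(1, expand_design(model$schema, dat))
    xbar <- colMeans(X1)
    co_nm <- c("(Intercept)", names(model$coefficients))
    V <- model$vcov[co_nm, co_nm, drop = FALSE]
    mean_lp_var <- drop(t(xbar) %*% V %*% xbar)
  }
  structure(out, class = c("virtual_control_set", "data.frame"),
            family = model$family,
            model_version = model$training_meta$version,
            skipped = skipped,
            mean_lp_var = mean_lp_var)
}

#' Added-value scores: observed minus predicted outcomes
#'
#' For a continuous outcome, each treated subject's added-value score is
#' the observed outcome minus the virtual-control prediction; the mean
#' score across the cohort estimates the treatment effect.
#'
#' @param treated a treated `vc_cohort` with continuous outcome.
#' @param vc the matching `virtual_control_set`.
#' @return data.frame with columns `id`, `observed`, `predicted`, `score`,
#'   in the virtual-control set's (id-stable) order.
#' @export
added_value_scores <- function(treated, vc) {
  stopifnot(inherits(vc, "virtual_control_set"))
  if (treated$outcome_spec$scale != "continuous")
    stop("contract error: added-value scores require a continuous outcome",
         call. = FALSE)
  idx <- match(vc$id, treated$data$id)
  if (any(is.na(idx)))
    stop("alignment error: virtual-control id(s) absent from cohort: ",
         paste(vc$id[is.na(idx)], collapse = ", "), call. = FALSE)
  obs <- cohort_outcome(treated)[idx]
  data.frame(id = vc$id, observed = obs, predicted = vc$predicted,
             score = obs - vc$predicted, stringsAsFactors = FALSE)
}

new_effect_estimate <- function(x) structure(x, class = "effect_estimate")

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Effect estimate (%s), n = %d\n", x$measure, x$n))
  cat(sprintf("  point: %.4g   %g%% CI: [%.4g, %.4g]   (%s)\n",
              x$point, 100 * x$level, x$ci[1], x$ci[2], x$uncertainty_mode))
  if (!is.null(x$standardized) && !is.na(x$standardized))
    cat(sprintf("  standardized effect size: %.3f\n", x$standardized))
  if (!is.null(x$risk_ratio))
    cat(sprintf("  risk ratio: %.3f\n", x$risk_ratio))
  if (!is.null(x$test))
    cat(sprintf("  test: %s  statistic = %.4g  p = %.4g\n",
                x$test$method, x$test$statistic, x$test$p.value))
  if (x$n_extrapolated > 0)
    cat(sprintf("  note: %d subject(s) extrapolate beyond model support\n",
                x$n_extrapolated))
  invisible(x)
}

#' Estimate a continuous treatment effect from virtual controls
#'
#' The point estimate is the mean added-value score (observed minus
#' predicted); the confidence interval and test come from the one-sample
#' t construction on the scores. By default the standard error also
#' propagates the prognostic model's coefficient uncertainty analytically
#' (the variance of the mean linear predictor, available whenever the
#' model carries its coefficient covariance); `propagate = "none"` gives
#' the pure plugin analysis that treats predictions as fixed. The
#' standardized effect size mean(score)/sd(score) is reported alongside.
#'
#' @param treated treated `vc_cohort`, continuous outcome.
#' @param vc matching `virtual_control_set`.
#' @param level confidence level in (0, 1); default 0.95, two-sided.
#' @param propagate `"model"` (default) to add the training-coefficient
#'   variance to the standard error, `"none"` for plugin.
#' @return an `effect_estimate` with measure `"mean-added-value"`.
#' @export
estimate_effect_continuous <- function(treated, vc, level = 0.95,
                                       propagate = c("model", "none")) {
  propagate <- match.arg(propagate)
  scores <- added_value_scores(treated, vc)$score
  n <- length(scores)
  if (n < 2L)
    stop("insufficient-data error: need at least 2 subjects, got ", n,
         call. = FALSE)
  m <- mean(scores)
  s <- stats::sd(scores)
  lp_var <- attr(vc, "mean_lp_var")
  extra <- if (propagate == "model" && is.finite(lp_var)) lp_var else 0
  mode <- if (extra > 0) "model-propagated" else "plugin"

  se <- sqrt(s^2 / n + extra)
  degenerate <- se == 0
  df <- n - 1L
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  if (degenerate) {
    ci <- c(m, m)
    stat <- if (m == 0) 0 else Inf * sign(m)
    p <- if (m == 0) 1 else 0
  } else {
    ci <- c(m - tcrit * se, m + tcrit * se)
    stat <- m / se
    p <- 2 * stats::pt(-abs(stat), df)
  }
  new_effect_estimate(list(
    measure = "mean-added-value", point = m, ci = ci, level = level,
    test = list(statistic = stat, p.value = p,
                method = "one-sample t on added-value scores", df = df),
    standardized = if (s > 0) m / s else NA_real_,
    sd_score = s, se = se, n = n,
    uncertainty_mode = mode, degenerate = degenerate,
    n_extrapolated = sum(vc$extrapolated),
    n_skipped = length(attr(vc, "skipped")),
    model_version = attr(vc, "model_version")))
}

## Poisson-binomial pmf over 0..n by direct convolution.
poisson_binomial_pmf <- function(p) {
  f <- 1
  for (pi in p) f <- c(f * (1 - pi), 0) + c(0, f * pi)
  f
}

## Two-sided exact tail probability P(|K - mu| >= |k - mu|) under
## independent Bernoulli(p_i).
poisson_binomial_pvalue <- function(k, p) {
  mu <- sum(p)
  pmf <- poisson_binomial_pmf(p)
  dev <- abs(seq_along(pmf) - 1 - mu)
  sum(pmf[dev >= abs(k - mu) - 1e-12])
}

#' Estimate a binary treatment effect from virtual controls
#'
#' Compares the observed event proportion in the treated cohort with the
#' mean predicted event probability from the virtual controls. The point
#' estimate is the risk difference (observed minus mean predicted); the
#' risk ratio is reported alongside. The test compares the observed event
#' count with the sum of predicted probabilities under the independent-
#' Bernoulli (Poisson-binomial) null: exact two-sided tail evaluation for
#' n <= 20, normal approximation with variance sum p_i(1-p_i) otherwise.
#' The risk-difference CI is computed by normal approximation and, when
#' `B > 0`, also by a subject-level bootstrap (resampling observed/
#' predicted pairs).
#'
#' @param treated treated `vc_cohort`, binary outcome.
#' @param vc matching `virtual_control_set` holding event probabilities.
#' @param level confidence level; default 0.95.
#' @param B bootstrap replicates for the bootstrap CI (0 disables).
#' @param seed optional integer seed for the bootstrap.
#' @return an `effect_estimate` with measure `"risk-difference"` and a
#'   `ci_bootstrap` element when `B > 0`.
#' @export
estimate_effect_binary <- function(treated, vc, level = 0.95, B = 1000L,
                                   seed = NULL) {
  stopifnot(inherits(vc, "virtual_control_set"))
  if (treated$outcome_spec$scale != "binary")
    stop("contract error: binary effect estimation requires a binary outcome",
         call. = FALSE)
  p <- vc$predicted
  if (any(p < 0 | p > 1))
    stop("contract error: predicted probabilities outside [0, 1]",
         call. = FALSE)
  idx <- match(vc$id, treated$data$id)
  if (any(is.na(idx)))
    stop("alignment error: virtual-control id(s) absent from cohort",
         call. = FALSE)
  y <- cohort_outcome(treated)[idx]
  n <- length(y)
  k <- sum(y)
  phat <- k / n
  pbar <- mean(p)
  rd <- phat - pbar
  rr <- if (pbar > 0) phat / pbar else NA_real_

  mu <- sum(p); v <- sum(p * (1 - p))
  if (n <= 20L) {
    pval <- poisson_binomial_pvalue(k, p)
    stat <- if (v > 0) (k - mu) / sqrt(v) else 0
    method <- "exact Poisson-binomial"
  } else {
    stat <- if (v > 0) (k - mu) / sqrt(v) else 0
    pval <- if (v > 0) 2 * stats::pnorm(-abs(stat)) else as.numeric(k != round(mu))
    method <- "Poisson-binomial normal approximation"
  }

  z <- stats::qnorm(1 - (1 - level) / 2)
  se_rd <- sqrt(phat * (1 - phat) / n)
  ci <- c(rd - z * se_rd, rd + z * se_rd)

  ci_boot <- NULL
  if (B > 0) {
    if (!is.null(seed)) set.seed(seed)
    rds <- vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      mean(y[i]) - mean(p[i])
    }, numeric(1))
    ci_boot <- unname(stats::quantile(rds, c((1 - level) / 2,
                                             1 - (1 - level) / 2)))
  }

  new_effect_estimate(list(
    measure = "risk-difference", point = rd, ci = ci, level = level,
    risk_ratio = rr,
    test = list(statistic = stat, p.value = pval, method = method),
    observed_rate = phat, mean_predicted = pbar,
    ci_bootstrap = ci_boot, B = if (B > 0) B else NULL, seed = seed,
    n = n, uncertainty_mode = "plugin",
    n_extrapolated = sum(vc$extrapolated),
    n_skipped = length(attr(vc, "skipped")),
    model_version = attr(vc, "model_version")))
}

#' Propagate training-model uncertainty by the bootstrap
#'
#' Full nonparametric bootstrap of the whole pipeline: each replicate
#' resamples the training cohort with replacement, refits the prognostic
#' model, re-predicts virtual controls for a resampled treated cohort,
#' and re-estimates the effect; the percentile interval over replicates is
#' the reported CI. This propagates both the training-coefficient
#' uncertainty and the treated-cohort sampling variability, so its
#' intervals are on average at least as wide as the plugin intervals.
#' Replicates whose refit fails (e.g. resampled collinearity) are dropped
#' and counted; more than 10% failures aborts.
#'
#' @param training untreated training `vc_cohort`.
#' @param treated treated `vc_cohort`.
#' @param B number of bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed integer seed; the run is reproducible given the seed.
#' @return an `effect_estimate` with `uncertainty_mode =
#'   "bootstrap-propagated"` and elements `B_used`, `B_failed`.
#' @export
bootstrap_propagate <- function(training, treated, B = 500L, level = 0.95,
                                seed = 1L) {
  if (B < 100L)
    stop("contract error: bootstrap needs B >= 100, got ", B, call. = FALSE)
  set.seed(seed)
  model0 <- fit_prognostic_model(training)
  vc0 <- predict_virtual_controls(model0, treated)
  continuous <- treated$outcome_spec$scale == "continuous"
  point0 <- if (continuous)
    mean(added_value_scores(treated, vc0)$score)
  else {
    est0 <- estimate_effect_binary(treated, vc0, level = level, B = 0)
    est0$point
  }

  n_tr <- nrow(training$data)
  n_tx <- nrow(treated$data)
  pts <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pts[b] <- tryCatch({
      itr <- sample.int(n_tr, n_tr, replace = TRUE)
      itx <- sample.int(n_tx, n_tx, replace = TRUE)
      dtr <- training$data[itr, , drop = FALSE]
      dtr$id <- paste0("b", seq_len(n_tr))
      dtx <- treated$data[itx, , drop = FALSE]
      dtx$id <- paste0("b", seq_len(n_tx))
      tr_b <- cohort(dtr, training$schema,
                     outcome = training$outcome_spec$name,
                     outcome_scale = training$outcome_spec$scale)
      tx_b <- cohort(dtx, treated$schema,
                     outcome = treated$outcome_spec$name,
                     outcome_scale = treated$outcome_spec$scale,
                     extra_columns = setdiff(names(dtx),
                       c("id", "treated", treated$outcome_spec$name,
                         schema_variables(treated$schema))))
      m_b <- fit_prognostic_model(tr_b)
      vc_b <- suppressWarnings(predict_virtual_controls(m_b, tx_b))
      if (continuous) mean(added_value_scores(tx_b, vc_b)$score)
      else mean(cohort_outcome(tx_b)) - mean(vc_b$predicted)
    }, error = function(e) NA_real_)
  }
  failed <- sum(is.na(pts))
  if (failed > 0.1 * B)
    stop("bootstrap error: ", failed, " of ", B,
         " replicates failed to refit (> 10%); aborting", call. = FALSE)
  pts <- pts[!is.na(pts)]
  ci <- unname(stats::quantile(pts, c((1 - level) / 2, 1 - (1 - level) / 2)))
  new_effect_estimate(list(
    measure = if (continuous) "mean-added-value" else "risk-difference",
    point = point0, ci = ci, level = level,
    test = list(statistic = NA_real_, p.value = NA_real_,
                method = "bootstrap percentile"),
    standardized = NULL, n = n_tx,
    uncertainty_mode = "bootstrap-propagated",
    B_used = length(pts), B_failed = failed, seed = seed,
    n_extrapolated = sum(vc0$extrapolated),
    n_skipped = length(attr(vc0, "skipped")),
    model_version = model0$training_meta$version))
}
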