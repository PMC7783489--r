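## Monte-Carlo operating characteristics: how often does each design —
## virtual controls vs randomization — reach the correct decision, and
## with what bias, coverage and power, under a stated generative truth?

## Covariate-adjusted analysis of a two-arm randomized cohort: linear
## model outcome ~ arm + covariates (continuous), logistic otherwise.
estimate_rct <- function(ch, level = 0.95, alpha = 0.05) {
  vars <- schema_variables(ch$schema)
  X <- expand_design(ch$schema, ch$data)
  y <- cohort_outcome(ch)
  arm <- ch$data$treated
  X1 <- cbind("(Intercept)" = 1, arm = arm, X)
  if (ch$outcome_spec$scale == "continuous") {
    fit <- fit_linear(X1, y)
    est <- unname(fit$beta["arm"])
    se <- sqrt(fit$vcov["arm", "arm"])
    df <- length(y) - ncol(X1)
    tcrit <- stats::qt(1 - (1 - level) / 2, df)
    ci <- c(est - tcrit * se, est + tcrit * se)
    p <- 2 * stats::pt(-abs(est / se), df)
  } else {
    fit <- fit_logistic(X1, y)
    est <- unname(fit$beta["arm"])
    se <- sqrt(fit$vcov["arm", "arm"])
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- c(est - z * se, est + z * se)
    p <- 2 * stats::pnorm(-abs(est / se))
  }
  list(point = est, ci = ci, p.value = p)
}

## One virtual-control replicate: train -> fit -> single arm -> estimate.
replicate_vc <- function(sc, level, propagate = "model") {
  tr <- generate_training_cohort(sc)
  m <- fit_prognostic_model(tr)
  sa <- generate_single_arm_cohort(sc)
  vcs <- predict_virtual_controls(m, sa)
  if (sc$outcome_scale == "continuous") {
    est <- estimate_effect_continuous(sa, vcs, level = level,
                                      propagate = propagate)
  } else {
    est <- estimate_effect_binary(sa, vcs, level = level, B = 0)
  }
  list(point = est$point, ci = est$ci, p.value = est$test$p.value)
}

#' Run one Monte-Carlo operating-characteristics cell
#'
#' For `n_reps` replicates under a fixed scenario, runs the full design
#' pipeline — virtual-control: generate training cohort, fit prognostic
#' model, generate self-selected single-arm cohort, predict virtual
#' controls, estimate the effect; randomized: generate a two-arm cohort
#' with preference/demoralization mechanics and run a covariate-adjusted
#' two-arm analysis — and aggregates bias, RMSE, empirical CI coverage of
#' the true effect, and the rejection rate of the two-sided alpha-level
#' test against zero effect (type-I error when `tau = 0`, power
#' otherwise), each with its Monte-Carlo standard error. Replicate `i`
#' uses seed `seed + i` (a documented counter scheme), so cells and
#' individual replicates are independently reproducible.
#'
#' Replicates raising an estimator error are recorded and excluded; a
#' cell with more than 5% failures is flagged invalid.
#'
#' @param sc a `simulation_scenario`. For binary scenarios the comparison
#'   is on the scale each design estimates and coverage is not
#'   cross-scale; continuous scenarios (additive `tau`) are the primary
#'   use.
#' @param n_reps replicates (>= 100).
#' @param design `"virtual-control"` or `"randomized"`.
#' @param seed master integer seed.
#' @param alpha decision level for the rejection rate.
#' @param level CI level for coverage.
#' @param propagate uncertainty handling for the continuous
#'   virtual-control estimator (see [estimate_effect_continuous()]).
#' @return object of class `opchar_cell`.
#' @export
run_cell <- function(sc, n_reps, design = c("virtual-control", "randomized"),
                     seed = 1L, alpha = 0.05, level = 0.95,
                     propagate = "model") {
  design <- match.arg(design)
  if (n_reps < 100L)
    stop("contract error: n_reps must be >= 100, got ", n_reps, call. = FALSE)
  gt <- ground_truth(sc)
  truth <- gt$tau
  t0 <- proc.time()[["elapsed"]]
  pts <- rej <- cov <- rep(NA_real_, n_reps)
  n_fail <- 0L
  for (i in seq_len(n_reps)) {
    set.seed(seed + i)
    r <- tryCatch({
      if (design == "virtual-control") replicate_vc(sc, level, propagate)
      else estimate_rct(generate_rct_cohort(sc), level = level)
    }, error = function(e) NULL)
    if (is.null(r)) { n_fail <- n_fail + 1L; next }
    pts[i] <- r$point
    rej[i] <- as.numeric(r$p.value < alpha)
    cov[i] <- as.numeric(r$ci[1] <= truth && truth <= r$ci[2])
  }
  ok <- !is.na(pts)
  n_ok <- sum(ok)
  rate_se <- function(r) sqrt(r * (1 - r) / n_ok)
  bias <- mean(pts[ok]) - truth
  rmse <- sqrt(mean((pts[ok] - truth)^2))
  coverage <- mean(cov[ok])
  reject <- mean(rej[ok])
  structure(list(
    design = design, n_reps = n_reps, n_used = n_ok, n_failed = n_fail,
    valid = n_fail <= 0.05 * n_reps,
    truth = gt,
    bias = bias, bias_mc_se = stats::sd(pts[ok]) / sqrt(n_ok),
    rmse = rmse,
    coverage = coverage, coverage_mc_se = rate_se(coverage),
    reject_rate = reject, reject_mc_se = rate_se(reject),
    alpha = alpha, level = level, seed = seed,
    runtime_s = proc.time()[["elapsed"]] - t0),
    class = "opchar_cell")
}

#' @export
print.opchar_cell <- function(x, ...) {
  cat(sprintf("Operating characteristics [%s design], %d/%d replicates%s\n",
              x$design, x$n_used, x$n_reps,
              if (!x$valid) "  ** INVALID (>5% failures) **" else ""))
  cat(sprintf("  truth: tau = %g, R2 = %.3f, expected bias = %.4g\n",
              x$truth$tau, x$truth$r2, x$truth$expected_bias))
  cat(sprintf("  bias %.4g (MC se %.3g)   RMSE %.4g\n",
              x$bias, x$bias_mc_se, x$rmse))
  cat(sprintf("  coverage %.3f (se %.3g)   reject rate %.3f (se %.3g) at alpha %.3g\n",
              x$coverage, x$coverage_mc_se, x$reject_rate, x$reject_mc_se,
              x$alpha))
  cat(sprintf("  runtime %.1f s\n", x$runtime_s))
  invisible(x)
}

#' Sweep the prognostic R-squared and map it to power
#'
#' Operationalizes the question "how accurate does prediction have to be
#' before the virtual-controls method yields correct decisions?": for
#' each target R-squared in the grid the residual s.d. is back-solved via
#' the closed form, an operating-characteristics cell is run, and the
#' smallest grid R-squared whose power meets the threshold is reported,
#' together with a monotonicity diagnostic (power should be
#' non-decreasing in R-squared up to sampling error).
#'
#' @param sc base `simulation_scenario` (its `tau`, sizes, etc. are kept).
#' @param r2_grid increasing vector of target R-squared values in (0, 1).
#' @param n_reps replicates per cell.
#' @param seed master seed; cell `j` uses `seed + j * 100000`.
#' @param power_threshold power level defining "sufficient accuracy".
#' @param alpha decision level.
#' @return object of class `r2_sweep`: list with a results data.frame
#'   (`r2`, `sigma`, `power`, `power_mc_se`, `bias`, `coverage`),
#'   `minimal_r2`, and `monotone` diagnostic.
#' @export
r2_sweep <- function(sc, r2_grid, n_reps = 500L, seed = 1L,
                     power_threshold = 0.8, alpha = 0.05) {
  stopifnot(all(r2_grid > 0 & r2_grid < 1), !is.unsorted(r2_grid))
  rows <- vector("list", length(r2_grid))
  for (j in seq_along(r2_grid)) {
    scj <- scenario_with_r2(sc, r2_grid[j])
    cell <- run_cell(scj, n_reps, design = "virtual-control",
                     seed = seed + j * 100000L, alpha = alpha)
    rows[[j]] <- data.frame(r2 = r2_grid[j], sigma = scj$sigma,
                            power = cell$reject_rate,
                            power_mc_se = cell$reject_mc_se,
                            bias = cell$bias, coverage = cell$coverage)
  }
  res <- do.call(rbind, rows)
  meets <- res$power >= power_threshold
  minimal_r2 <- if (any(meets)) res$r2[which(meets)[1L]] else NA_real_
  pooled_se <- sqrt(res$power_mc_se[-1L]^2 + res$power_mc_se[-nrow(res)]^2)
  monotone <- all(diff(res$power) >= -3 * pooled_se)
  structure(list(results = res, minimal_r2 = minimal_r2,
                 power_threshold = power_threshold, monotone = monotone,
                 n_reps = n_reps, seed = seed),
            class = "r2_sweep")
}

#' @export
print.r2_sweep <- function(x, ...) {
  cat("R-squared sweep (", x$n_reps, " reps/cell)\n", sep = "")
  print(x$results, row.names = FALSE, digits = 3)
  cat(sprintf("minimal R2 with power >= %.2f: %s   monotone: %s\n",
              x$power_threshold,
              if (is.na(x$minimal_r2)) "none in grid" else
                format(x$minimal_r2), x$monotone))
  invisible(x)
}

## Pooled two-proportion z-test decision on observed counts.
two_prop_reject <- function(x0, x1, n, alpha) {
  pp <- (x0 + x1) / (2 * n)
  if (pp <= 0 || pp >= 1) return(FALSE)
  z <- (x1 / n - x0 / n) / sqrt(pp * (1 - pp) * 2 / n)
  abs(z) > stats::qnorm(1 - alpha / 2)
}

#' Power of a two-sample comparison of proportions
#'
#' Power of the two-sided pooled two-proportion z-test with `n_per_arm`
#' per group. For small expected event counts (or small arms) the power
#' is computed exactly by enumerating both binomial distributions over
#' their effective supports; otherwise the standard normal approximation
#' is used. The rare-event regime is the one behind vaccine
#' safety-signal arguments: an adverse-event rate of 1 in 100,000 is far
#' beyond the detection power of trials with 15,000 per group.
#'
#' @param p0,p1 event probabilities in the two arms.
#' @param n_per_arm subjects per arm.
#' @param alpha two-sided test level.
#' @param method `"auto"` (default), `"exact"`, or `"normal"`.
#' @return list with `power`, `method`, `n_per_arm`, `alpha`.
#' @export
power_two_proportion <- function(p0, p1, n_per_arm, alpha = 0.05,
                                 method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1, n_per_arm >= 1)
  n <- as.integer(n_per_arm)

  supp <- function(p) {
    if (p <= 0) return(0L)
    if (p >= 1) return(n)
    hi <- min(n, stats::qbinom(1e-12, n, p, lower.tail = FALSE) + 1L)
    lo <- max(0L, stats::qbinom(1e-12, n, p))
    lo:hi
  }
  s0 <- supp(p0); s1 <- supp(p1)
  exact_feasible <- length(s0) * length(s1) <= 5e5
  use_exact <- method == "exact" || (method == "auto" && exact_feasible)
  if (method == "exact" && !exact_feasible)
    stop("configuration error: exact enumeration infeasible at this size",
         call. = FALSE)

  if (use_exact) {
    d0 <- stats::dbinom(s0, n, p0)
    d1 <- stats::dbinom(s1, n, p1)
    pw <- 0
    for (i in seq_along(s0)) {
      rejects <- vapply(s1, function(x1) two_prop_reject(s0[i], x1, n, alpha),
                        logical(1))
      pw <- pw + d0[i] * sum(d1[rejects])
    }
    tag <- "exact binomial enumeration"
  } else {
    zc <- stats::qnorm(1 - alpha / 2)
    pbar <- (p0 + p1) / 2
    se0 <- sqrt(2 * pbar * (1 - pbar) / n)
    se1 <- sqrt(p0 * (1 - p0) / n + p1 * (1 - p1) / n)
    d <- p1 - p0
    pw <- stats::pnorm((-zc * se0 - d) / se1) +
      stats::pnorm((d - zc * se0) / se1)
    tag <- "normal approximation"
  }
  list(power = pw, method = tag, n_per_arm = n, alpha = alpha)
}
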