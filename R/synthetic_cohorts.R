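#' Define a simulation scenario
#'
#' A scenario fixes the generative truth behind every synthetic cohort:
#' the covariate law (independent standard-normal covariates, optionally
#' exchangeably correlated, plus optional binary covariates with stated
#' prevalence), the true outcome coefficients, the residual noise (which
#' together with the coefficients fixes the true prognostic R-squared in
#' closed form), the true treatment effect, a hidden standard-normal
#' confounder (the "motivation for improvement" analogue) acting on both
#' outcome and self-selection, and the preference/demoralization
#' mechanics of an unblinded randomized trial.
#'
#' @param p number of continuous standard-normal covariates.
#' @param beta true coefficients of the continuous covariates; default
#'   `rep(1/sqrt(p), p)` so their linear predictor has unit variance.
#' @param intercept true outcome intercept.
#' @param sigma residual standard deviation (> 0); continuous outcomes.
#' @param tau true treatment effect: additive for continuous outcomes,
#'   log-odds shift for binary outcomes.
#' @param gamma effect of the hidden confounder on the outcome.
#' @param selection list `list(mode, strength, offset)`; `mode` one of
#'   `"none"` (everyone opts in), `"observed"` (logistic opt-in in the
#'   first observed covariate), `"hidden"` (logistic opt-in in the hidden
#'   confounder). Opt-in probability is `plogis(offset + strength * z)`;
#'   `offset` (default 0) sets the baseline accrual rate.
#' @param preference fraction of trial volunteers preferring the
#'   treatment arm (randomized-design simulation).
#' @param demoralization non-negative outcome penalty subtracted
#'   (continuous) or log-odds penalty (binary) for subjects randomized
#'   against their preference.
#' @param n_train,n_treated,n_rct_per_arm cohort sizes.
#' @param rho exchangeable correlation among the continuous covariates.
#' @param binary_prev optional named numeric vector of prevalences for
#'   additional binary covariates (independent of the rest).
#' @param beta_binary coefficients of the binary covariates (defaults 0).
#' @param outcome_scale `"continuous"` or `"binary"`.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(p = 3L, beta = NULL, intercept = 0,
                                sigma = 1, tau = 0, gamma = 0,
                                selection = list(mode = "none", strength = 0),
                                preference = 0.5, demoralization = 0,
                                n_train = 500L, n_treated = 100L,
                                n_rct_per_arm = 100L, rho = 0,
                                binary_prev = NULL, beta_binary = NULL,
                                outcome_scale = c("continuous", "binary")) {
  outcome_scale <- match.arg(outcome_scale)
  if (is.null(beta)) beta <- rep(1 / sqrt(p), p)
  stopifnot(length(beta) == p)
  if (sigma <= 0) stop("scenario error: sigma must be > 0", call. = FALSE)
  if (preference < 0 || preference > 1)
    stop("scenario error: preference must lie in [0, 1]", call. = FALSE)
  if (min(n_train, n_treated, n_rct_per_arm) < 1)
    stop("scenario error: cohort sizes must be >= 1", call. = FALSE)
  if (rho < 0 || rho >= 1)
    stop("scenario error: rho must lie in [0, 1)", call. = FALSE)
  if (!selection$mode %in% c("none", "observed", "hidden"))
    stop("scenario error: selection mode must be none/observed/hidden",
         call. = FALSE)
  if (is.null(selection$offset)) selection$offset <- 0
  if (!is.null(binary_prev)) {
    stopifnot(all(binary_prev > 0 & binary_prev < 1))
    if (is.null(names(binary_prev)))
      names(binary_prev) <- paste0("b", seq_along(binary_prev))
    if (is.null(beta_binary)) beta_binary <- rep(0, length(binary_prev))
    stopifnot(length(beta_binary) == length(binary_prev))
  }
  structure(list(p = as.integer(p), beta = beta, intercept = intercept,
                 sigma = sigma, tau = tau, gamma = gamma,
                 selection = selection, preference = preference,
                 demoralization = demoralization,
                 n_train = as.integer(n_train),
                 n_treated = as.integer(n_treated),
                 n_rct_per_arm = as.integer(n_rct_per_arm),
                 rho = rho, binary_prev = binary_prev,
                 beta_binary = beta_binary,
                 outcome_scale = outcome_scale),
            class = "simulation_scenario")
}

scenario_schema <- function(sc) {
  kinds <- rep("continuous", sc$p)
  names(kinds) <- paste0("x", seq_len(sc$p))
  if (!is.null(sc$binary_prev)) {
    kb <- rep("binary", length(sc$binary_prev))
    names(kb) <- names(sc$binary_prev)
    kinds <- c(kinds, kb)
  }
  covariate_schema(kinds)
}

## Variance of the observable linear predictor x'beta under the
## scenario's covariate law.
linear_predictor_variance <- function(sc) {
  b <- sc$beta
  v <- sum(b^2) + sc$rho * (sum(b)^2 - sum(b^2))
  if (!is.null(sc$binary_prev))
    v <- v + sum(sc$beta_binary^2 * sc$binary_prev * (1 - sc$binary_prev))
  v
}

#' Closed-form true prognostic R-squared of a scenario
#'
#' `Var(x'beta) / (Var(x'beta) + gamma^2 + sigma^2)`: the proportion of
#' outcome variance an ideal model of the observed covariates explains in
#' untreated subjects. The hidden-confounder contribution `gamma^2`
#' counts as unexplained noise, as does the residual `sigma^2`.
#'
#' @param sc a `simulation_scenario`.
#' @return the true R-squared in (0, 1).
#' @export
true_r2 <- function(sc) {
  v <- linear_predictor_variance(sc)
  v / (v + sc$gamma^2 + sc$sigma^2)
}

#' Back-solve the residual s.d. for a target prognostic R-squared
#'
#' @param sc a `simulation_scenario` (its beta, rho, gamma are kept).
#' @param r2 target true R-squared in (0, 1).
#' @return a copy of `sc` with `sigma` set so that [true_r2()] equals
#'   `r2`; errors if the target is infeasible given `gamma`.
#' @export
scenario_with_r2 <- function(sc, r2) {
  stopifnot(r2 > 0, r2 < 1)
  v <- linear_predictor_variance(sc)
  s2 <- v * (1 - r2) / r2 - sc$gamma^2
  if (s2 <= 0)
    stop("configuration error: R-squared ", r2, " infeasible: hidden-",
         "confounder variance alone exceeds the implied noise budget",
         call. = FALSE)
  sc$sigma <- sqrt(s2)
  sc
}

#' Ground truth of a scenario
#'
#' Recomputes, from the scenario alone, the quantities a Monte-Carlo cell
#' is judged against: the true effect, the true prognostic R-squared, and
#' the expected bias of the virtual-control estimator under the
#' scenario's selection mechanism. Under hidden selection with logistic
#' opt-in probability `plogis(strength * u)`, the treated group's mean
#' confounder is `E[u | opt-in]` (a deterministic logistic-normal
#' integral, evaluated by quadrature) and the expected bias is `gamma *
#' E[u | opt-in]`; selection on an observed, modelled covariate induces
#' no bias, nor does no selection.
#'
#' @param sc a `simulation_scenario`.
#' @return list with `tau`, `r2`, `expected_bias`, `mean_u_selected`.
#' @export
ground_truth <- function(sc) {
  mean_u <- 0
  if (sc$selection$mode == "hidden" && sc$selection$strength != 0) {
    s <- sc$selection$strength
    a <- sc$selection$offset %||% 0
    num <- stats::integrate(function(u) u * stats::plogis(a + s * u) *
                              stats::dnorm(u), -Inf, Inf)$value
    den <- stats::integrate(function(u) stats::plogis(a + s * u) *
                              stats::dnorm(u), -Inf, Inf)$value
    mean_u <- num / den
  }
  bias <- if (sc$selection$mode == "hidden") sc$gamma * mean_u else 0
  list(tau = sc$tau, r2 = true_r2(sc), expected_bias = bias,
       mean_u_selected = mean_u)
}

## Draw covariates + hidden confounder for n subjects.
draw_covariates <- function(sc, n) {
  if (sc$rho > 0) {
    z0 <- stats::rnorm(n)
    X <- sqrt(sc$rho) * z0 +
      sqrt(1 - sc$rho) * matrix(stats::rnorm(n * sc$p), n, sc$p)
  } else {
    X <- matrix(stats::rnorm(n * sc$p), n, sc$p)
  }
  colnames(X) <- paste0("x", seq_len(sc$p))
  df <- as.data.frame(X)
  if (!is.null(sc$binary_prev))
    for (j in seq_along(sc$binary_prev))
      df[[names(sc$binary_prev)[j]]] <-
        stats::rbinom(n, 1, sc$binary_prev[j])
  df$.u <- stats::rnorm(n)
  df
}

## Observable linear predictor (no hidden term, no treatment).
obs_lp <- function(sc, df) {
  lp <- sc$intercept +
    as.matrix(df[, paste0("x", seq_len(sc$p)), drop = FALSE]) %*% sc$beta
  if (!is.null(sc$binary_prev))
    lp <- lp + as.matrix(df[, names(sc$binary_prev), drop = FALSE]) %*%
      sc$beta_binary
  drop(lp)
}

## Outcome given full linear predictor (including hidden/treatment terms).
draw_outcome <- function(sc, lp_full, n) {
  if (sc$outcome_scale == "continuous")
    lp_full + stats::rnorm(n, 0, sc$sigma)
  else
    stats::rbinom(n, 1, stats::plogis(lp_full))
}

make_cohort <- function(sc, df, y, treated, prefix, extra = NULL) {
  dat <- df[, setdiff(names(df), ".u"), drop = FALSE]
  dat$id <- paste0(prefix, seq_len(nrow(dat)))
  dat$treated <- treated
  dat$outcome <- y
  extra_cols <- character(0)
  if (!is.null(extra)) {
    for (nm in names(extra)) dat[[nm]] <- extra[[nm]]
    extra_cols <- names(extra)
  }
  ch <- cohort(dat, scenario_schema(sc), outcome = "outcome",
               outcome_scale = sc$outcome_scale, extra_columns = extra_cols)
  attr(ch, "hidden_u") <- df$.u
  ch
}

#' Generate an untreated training cohort
#'
#' `n_train` untreated subjects from the scenario's covariate law, with
#' outcome `intercept + x'beta + gamma*u + eps`, `eps ~ N(0, sigma)`,
#' `u` the hidden standard-normal confounder (kept as the cohort
#' attribute `"hidden_u"`, never as a covariate). Binary outcomes use a
#' logistic link on the same linear predictor.
#'
#' @param sc a `simulation_scenario`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a `vc_cohort` of untreated subjects.
#' @export
generate_training_cohort <- function(sc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sc$n_train
  df <- draw_covariates(sc, n)
  lp <- obs_lp(sc, df) + sc$gamma * df$.u
  y <- draw_outcome(sc, lp, n)
  make_cohort(sc, df, y, treated = 0L, prefix = "tr")
}

#' Generate a self-selected single-arm treated cohort
#'
#' Subjects opt into the single-arm study with probability depending on
#' the scenario's selection mode: `"none"` — everyone; `"observed"` —
#' `plogis(strength * x1)` (selection on a modelled covariate, which the
#' prognostic model absorbs); `"hidden"` — `plogis(strength * u)`
#' (selection on the unmeasured confounder, the classic internal-validity
#' threat). Accrual continues until `n_treated` subjects have opted in;
#' if fewer accrue in `100 * n_treated` draws, an accrual error is
#' raised. Outcomes include the true effect `tau`.
#'
#' @inheritParams generate_training_cohort
#' @return a `vc_cohort` of treated subjects (attribute `"hidden_u"`
#'   carries the confounder values).
#' @export
generate_single_arm_cohort <- function(sc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sc$n_treated
  got <- NULL
  drawn <- 0L
  cap <- 100L * n
  while (is.null(got) || nrow(got) < n) {
    batch <- min(cap - drawn, max(n, 1000L))
    if (batch <= 0L)
      stop("accrual error: fewer than ", n, " subjects opted in within ",
           cap, " draws; selection too extreme", call. = FALSE)
    df <- draw_covariates(sc, batch)
    drawn <- drawn + batch
    a <- sc$selection$offset
    p_in <- switch(sc$selection$mode,
                   none = rep(1, batch),
                   observed = stats::plogis(a + sc$selection$strength * df$x1),
                   hidden = stats::plogis(a + sc$selection$strength * df$.u))
    keep <- stats::runif(batch) < p_in
    got <- if (is.null(got)) df[keep, , drop = FALSE]
           else rbind(got, df[keep, , drop = FALSE])
  }
  df <- got[seq_len(n), , drop = FALSE]
  rownames(df) <- NULL
  lp <- obs_lp(sc, df) + sc$gamma * df$.u + sc$tau
  y <- draw_outcome(sc, lp, n)
  make_cohort(sc, df, y, treated = 1L, prefix = "tx")
}

#' Generate a two-arm randomized cohort with preference mechanics
#'
#' Simulates an unblinded randomized trial: `2 * n_rct_per_arm`
#' volunteers, each preferring the treatment arm with probability
#' `preference`, randomized 1:1 (exact split). Subjects assigned against
#' their preference are "demoralized": the demoralization penalty is
#' subtracted from their outcome (continuous) or their log-odds
#' (binary). The returned cohort carries `preferred` (1 = prefers
#' treatment) and `satisfied` (assignment matched preference) columns;
#' `treated` is the randomized arm.
#'
#' @inheritParams generate_training_cohort
#' @return a `vc_cohort` with extra columns `preferred`, `satisfied`.
#' @export
generate_rct_cohort <- function(sc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * sc$n_rct_per_arm
  df <- draw_covariates(sc, n)
  prefer_treat <- stats::rbinom(n, 1, sc$preference)
  arm <- integer(n)
  arm[sample.int(n, sc$n_rct_per_arm)] <- 1L
  satisfied <- as.integer(arm == prefer_treat)
  lp <- obs_lp(sc, df) + sc$gamma * df$.u + sc$tau * arm -
    sc$demoralization * (1L - satisfied)
  y <- draw_outcome(sc, lp, n)
  make_cohort(sc, df, y, treated = arm, prefix = "r",
              extra = list(preferred = prefer_treat, satisfied = satisfied))
}

#' Recruitment burden of a randomized trial
#'
#' Contacts needed per enrolled participant, the bookkeeping behind
#' recruitment-cost arguments (e.g. 18,925 contacts to enroll 140
#' participants is about 135 contacts per enrollee).
#'
#' @param contacts total people contacted.
#' @param enrolled participants enrolled.
#' @return contacts per enrollee.
#' @export
contacts_per_enrollee <- function(contacts, enrolled) {
  stopifnot(contacts >= 0, enrolled > 0)
  contacts / enrolled
}

#' Read/write simulation scenarios as YAML
#'
#' Scenario files are human-editable structured text; every numeric field
#' of [simulation_scenario()] may be set.
#'
#' @param path file path.
#' @return `read_scenario` returns a `simulation_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path))
    stop("file error: no such file: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  obj$beta <- if (!is.null(obj$beta)) as.numeric(obj$beta)
  if (!is.null(obj$selection))
    obj$selection <- list(mode = obj$selection$mode,
                          strength = as.numeric(obj$selection$strength),
                          offset = as.numeric(obj$selection$offset %||% 0))
  do.call(simulation_scenario, obj)
}

#' @rdname read_scenario
#' @param sc a `simulation_scenario`.
#' @export
write_scenario <- function(sc, path) {
  obj <- unclass(sc)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  yaml::write_yaml(obj, path)
  invisible(path)
}
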