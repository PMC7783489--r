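#' Write an effect estimate as machine-readable JSON
#'
#' Fields are emitted in a fixed order so that identical estimates
#' produce byte-identical files.
#'
#' @param est an `effect_estimate`.
#' @param path file path.
#' @export
write_effect <- function(est, path) {
  stopifnot(inherits(est, "effect_estimate"))
  obj <- list(measure = est$measure, point = est$point,
              ci_lower = est$ci[1], ci_upper = est$ci[2],
              level = est$level,
              statistic = est$test$statistic, p_value = est$test$p.value,
              test_method = est$test$method,
              n = est$n, uncertainty_mode = est$uncertainty_mode,
              n_extrapolated = est$n_extrapolated,
              n_skipped = est$n_skipped,
              model_version = est$model_version)
  if (!is.null(est$standardized)) obj$standardized <- est$standardized
  if (!is.null(est$risk_ratio)) obj$risk_ratio <- est$risk_ratio
  if (!is.null(est$ci_bootstrap)) {
    obj$ci_bootstrap_lower <- est$ci_bootstrap[1]
    obj$ci_bootstrap_upper <- est$ci_bootstrap[2]
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end virtual-controls pipeline
#'
#' Fit a prognostic model on an untreated training cohort, optionally
#' validate it externally, predict virtual controls for a treated
#' single-arm cohort, estimate the effect, and write the artifacts
#' (coefficient-set file, virtual-control table, effect-estimate JSON) to
#' an output directory. Errors are labelled with the stage that raised
#' them. Identical configuration and seed produce byte-identical
#' machine-readable outputs.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `training` (cohort CSV path), `treated` (cohort CSV path),
#'   `independent` (optional validation cohort path), `schema` (named
#'   list variable -> kind, plus optional `levels`), `outcome`
#'   (column name, default "outcome"), `outcome_scale`, `out_dir`,
#'   `level` (default 0.95), `bootstrap_B` (0 = plugin only),
#'   `seed` (default 1).
#' @param verbose print progress to stderr.
#' @return invisibly, a list with the fitted model, virtual-control set,
#'   effect estimate, validation report (if any), and artifact paths.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (verbose) message("[virtualcontrols] ", ...)
  level <- config$level %||% 0.95
  seed <- config$seed %||% 1L
  outcome <- config$outcome %||% "outcome"
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  schema <- pipeline_stage("schema", {
    kinds <- unlist(config$schema$kinds %||% config$schema)
    covariate_schema(kinds, levels = config$schema$levels %||% list())
  })
  say("reading cohorts")
  training <- pipeline_stage("read_cohort",
    read_cohort(config$training, schema, outcome = outcome,
                outcome_scale = config$outcome_scale))
  treated <- pipeline_stage("read_cohort",
    read_cohort(config$treated, schema, outcome = outcome,
                outcome_scale = config$outcome_scale))

  say("fitting prognostic model")
  model <- pipeline_stage("fit", fit_prognostic_model(
    training, provenance = config$provenance %||% "run_pipeline"))

  validation <- NULL
  if (!is.null(config$independent)) {
    say("external validation")
    indep <- pipeline_stage("read_cohort",
      read_cohort(config$independent, schema, outcome = outcome,
                  outcome_scale = config$outcome_scale))
    validation <- pipeline_stage("validate", validate_external(model, indep))
  }

  say("predicting virtual controls")
  vcs <- pipeline_stage("predict", predict_virtual_controls(model, treated))

  say("estimating effect")
  est <- pipeline_stage("estimate", {
    B <- config$bootstrap_B %||% 0L
    if (B > 0) {
      bootstrap_propagate(training, treated, B = B, level = level,
                          seed = seed)
    } else if (config$outcome_scale == "continuous") {
      estimate_effect_continuous(treated, vcs, level = level)
    } else {
      estimate_effect_binary(treated, vcs, level = level, seed = seed)
    }
  })

  model_path <- file.path(out_dir, "model.json")
  vc_path <- file.path(out_dir, "virtual_controls.csv")
  effect_path <- file.path(out_dir, "effect.json")
  write_model(model, model_path)
  vc_out <- as.data.frame(vcs)
  vc_out$model_version <- attr(vcs, "model_version")
  utils::write.csv(vc_out, vc_path, row.names = FALSE, quote = FALSE)
  write_effect(est, effect_path)
  say("artifacts written to ", out_dir)

  invisible(list(model = model, virtual_controls = vcs, effect = est,
                 validation = validation,
                 paths = list(model = model_path, virtual_controls = vc_path,
                              effect = effect_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
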