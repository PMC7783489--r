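# Small programmatic fixtures shared across tests.

# simple continuous cohort: outcome = 1 + 2*x1 - x2 + noise
toy_schema <- function() covariate_schema(c(x1 = "continuous",
                                            x2 = "continuous"))

toy_cohort <- function(n = 50, seed = 42, treated = 0L, sigma = 0.5,
                       tau = 0) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1 + 2 * x1 - x2 + tau + rnorm(n, 0, sigma)
  cohort(data.frame(id = paste0("s", seq_len(n)), treated = treated,
                    outcome = y, x1 = x1, x2 = x2),
         toy_schema(), outcome_scale = "continuous")
}

# binary-outcome cohort with logistic truth
toy_binary_cohort <- function(n = 200, seed = 7, treated = 0L, shift = 0) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  p <- plogis(-0.3 + x1 + 0.5 * x2 + shift)
  cohort(data.frame(id = paste0("b", seq_len(n)), treated = treated,
                    outcome = rbinom(n, 1, p), x1 = x1, x2 = x2),
         toy_schema(), outcome_scale = "binary")
}

# hand-built virtual-control set (plugin mode, no model covariance)
manual_vc_set <- function(ids, predicted, family = "linear") {
  structure(data.frame(id = ids, predicted = predicted, lp = predicted,
                       extrapolated = FALSE, stringsAsFactors = FALSE),
            class = c("virtual_control_set", "data.frame"),
            family = family, model_version = 1L,
            skipped = character(0), mean_lp_var = NA_real_)
}
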