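test_that("an exactly linear outcome is recovered perfectly", {
  set.seed(1)
  x <- rnorm(30)
  ch <- cohort(data.frame(id = as.character(1:30), treated = 0,
                          outcome = x, x1 = x, x2 = rnorm(30)),
               toy_schema(), outcome_scale = "continuous")
  m <- fit_prognostic_model(ch)
  expect_equal(unname(m$coefficients["x1"]), 1, tolerance = 1e-10)
  expect_equal(unname(m$coefficients["x2"]), 0, tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
  expect_equal(m$training_meta$precision, 1, tolerance = 1e-10)
})

test_that("three predictor subscales plus a constant give four parameters", {
  set.seed(2)
  sch <- covariate_schema(c(emotional = "continuous", conduct = "continuous",
                            hyperactivity = "continuous"))
  n <- 120
  d <- data.frame(id = as.character(1:n), treated = 0,
                  emotional = rnorm(n), conduct = rnorm(n),
                  hyperactivity = rnorm(n))
  d$outcome <- 2 + 0.5 * d$emotional + 0.3 * d$conduct +
    0.4 * d$hyperactivity + rnorm(n)
  m <- fit_prognostic_model(cohort(d, sch, outcome_scale = "continuous"))
  expect_length(m$coefficients, 3)           # + intercept = 4 parameters
  expect_true(is.numeric(m$intercept))
})

test_that("least-squares coefficients match an independent normal-equations solve", {
  set.seed(3)
  n <- 50
  sch <- covariate_schema(c(x1 = "continuous", x2 = "continuous",
                            x3 = "continuous"))
  d <- data.frame(id = as.character(1:n), treated = 0,
                  x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$outcome <- 1 + d$x1 - 2 * d$x2 + 0.5 * d$x3 + rnorm(n)
  m <- fit_prognostic_model(cohort(d, sch, outcome_scale = "continuous"))
  X1 <- cbind(1, d$x1, d$x2, d$x3)
  beta_oracle <- solve(crossprod(X1), crossprod(X1, d$outcome))
  expect_equal(unname(c(m$intercept, m$coefficients)),
               drop(beta_oracle), tolerance = 1e-8)
})

test_that("fitting contract errors: treated rows, collinearity, too few rows", {
  ch <- toy_cohort(n = 30, treated = 1L)
  expect_error(fit_prognostic_model(ch), "contract error.*treated")

  set.seed(4)
  d <- data.frame(id = as.character(1:30), treated = 0, x1 = rnorm(30))
  d$x2 <- 2 * d$x1
  d$outcome <- d$x1 + rnorm(30)
  expect_error(
    fit_prognostic_model(cohort(d, toy_schema(),
                                outcome_scale = "continuous")),
    "singularity error.*x2")

  tiny <- toy_cohort(n = 3)
  expect_error(fit_prognostic_model(tiny), "contract error.*exceed")
})

test_that("model precision reproduces training R-squared and the definitional oracle", {
  ch <- toy_cohort(n = 80, seed = 11)
  m <- fit_prognostic_model(ch)
  rep_ <- model_precision(m, ch)
  expect_equal(rep_$r_squared, m$training_meta$precision, tolerance = 1e-12)
  # two-pass definitional oracle: R2 = 1 - SSE/SST
  pred <- m$intercept + m$coefficients["x1"] * ch$data$x1 +
    m$coefficients["x2"] * ch$data$x2
  y <- ch$data$outcome
  expect_equal(rep_$r_squared,
               1 - sum((y - pred)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_equal(rep_$calibration_slope, 1, tolerance = 1e-8)
})

test_that("a constant-prediction model reports the calibration slope as undefined", {
  ch <- toy_cohort(n = 40)
  m <- prognostic_model("linear", intercept = 2,
                        coefficients = c(x1 = 0, x2 = 0),
                        schema = toy_schema(),
                        training_meta = list(n = 40, precision = 0,
                                             version = 1, provenance = ""))
  rep_ <- model_precision(m, ch)
  expect_true(is.na(rep_$calibration_slope))
})

test_that("external validation is calibrated on same-law data and shifts with the mean", {
  big <- toy_cohort(n = 2000, seed = 20, sigma = 0.3)
  m <- fit_prognostic_model(toy_cohort(n = 2000, seed = 21, sigma = 0.3))
  rep_ <- validate_external(m, big)
  expect_equal(rep_$calibration_slope, 1, tolerance = 0.05)
  expect_equal(rep_$calibration_intercept, 0, tolerance = 0.05)

  # a uniform +delta outcome shift moves the calibration intercept by delta
  delta <- 0.8
  shifted <- big
  shifted$data$outcome <- shifted$data$outcome + delta
  rep_s <- validate_external(m, shifted)
  expect_equal(rep_s$calibration_intercept - rep_$calibration_intercept,
               delta, tolerance = 0.05)
  expect_equal(rep_s$mean_error, rep_$mean_error + delta, tolerance = 1e-10)
})

test_that("covariates outside training support produce truncation warnings", {
  m <- fit_prognostic_model(toy_cohort(n = 50, seed = 30))
  out <- toy_cohort(n = 20, seed = 31)
  out$data$x1[1] <- max(m$schema$support$x1) + 10
  rep_ <- validate_external(m, out)
  expect_identical(rep_$truncation_warnings, "x1")
  expect_error(validate_external(m, toy_cohort(n = 20, treated = 1L)),
               "contract error.*untreated")
})

test_that("in-sample R-squared never decreases when a predictor is added", {
  set.seed(5)
  n <- 60
  d <- data.frame(id = as.character(1:n), treated = 0,
                  x1 = rnorm(n), x2 = rnorm(n))
  d$outcome <- d$x1 + rnorm(n)
  sch1 <- covariate_schema(c(x1 = "continuous"))
  m1 <- fit_prognostic_model(cohort(d[, c("id", "treated", "outcome", "x1")],
                                    sch1, outcome_scale = "continuous"))
  m2 <- fit_prognostic_model(cohort(d, toy_schema(),
                                    outcome_scale = "continuous"))
  expect_gte(m2$training_meta$precision, m1$training_meta$precision)
})

test_that("fitted coefficients are consistent for the generative truth", {
  sc <- simulation_scenario(p = 3, beta = c(1, -0.5, 0.25), sigma = 1,
                            n_train = 2000)
  reps <- 200
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    m <- fit_prognostic_model(generate_training_cohort(sc, seed = 5000 + r))
    est[r, ] <- m$coefficients[c("x1", "x2", "x3")]
  }
  for (j in 1:3) {
    mc_se <- sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - sc$beta[j]), 3 * mc_se + 1e-3)
  }
})

test_that("pooling: identity on no new data, refit oracle, support widening", {
  tr <- toy_cohort(n = 80, seed = 40)
  m <- fit_prognostic_model(tr)

  m_id <- pool_and_refit(m, list())
  expect_equal(m_id$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(m_id$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(m_id$training_meta$version, m$training_meta$version + 1L)

  extra <- toy_cohort(n = 60, seed = 41)
  m_pool <- pool_and_refit(m, list(extra))
  # from-scratch oracle on the concatenated table
  both <- rbind(cbind(tr$data, src = "a"), cbind(extra$data, src = "b"))
  both$id <- as.character(seq_len(nrow(both)))
  scratch <- fit_prognostic_model(
    cohort(both[, c("id", "treated", "outcome", "x1", "x2")], toy_schema(),
           outcome_scale = "continuous"))
  expect_equal(m_pool$coefficients, scratch$coefficients, tolerance = 1e-10)

  # widened support: add a cohort with larger covariate range (the
  # enlarge-the-smokers move)
  wide <- extra
  wide$data$x1 <- wide$data$x1 * 10
  m_wide <- pool_and_refit(m, list(wide))
  expect_gt(diff(m_wide$schema$support$x1), diff(m$schema$support$x1))
})

test_that("pooling a cohort that adds a new variable extends the schema", {
  tr <- toy_cohort(n = 80, seed = 50)
  m <- fit_prognostic_model(tr)
  set.seed(51)
  n <- 70
  sch3 <- covariate_schema(c(x1 = "continuous", x2 = "continuous",
                             smoker = "binary"))
  d <- data.frame(id = as.character(1:n), treated = 0,
                  x1 = rnorm(n), x2 = rnorm(n),
                  smoker = rbinom(n, 1, 0.4))
  d$outcome <- 1 + 2 * d$x1 - d$x2 + 0.5 * d$smoker + rnorm(n, 0, 0.5)
  new_ch <- cohort(d, sch3, outcome_scale = "continuous")
  m2 <- pool_and_refit(m, list(new_ch))
  expect_true("smoker" %in% names(m2$schema$kinds))
  # old rows lack the new variable -> only the new cohort's rows fit
  expect_equal(m2$training_meta$n, n)
  # incompatible kinds across cohorts are a schema conflict
  sch_bad <- covariate_schema(c(x1 = "binary", x2 = "continuous"))
  d_bad <- data.frame(id = "z1", treated = 0, outcome = 1, x1 = 1, x2 = 0)
  expect_error(pool_and_refit(m, list(cohort(d_bad, sch_bad,
                                             outcome_scale = "continuous"))),
               "schema conflict")
})

test_that("logistic fitting works and flags perfect separation", {
  ch <- toy_binary_cohort(n = 300)
  m <- fit_prognostic_model(ch)
  expect_identical(m$family, "logistic")
  expect_equal(unname(m$coefficients["x1"]), 1, tolerance = 0.35)
  rep_ <- model_precision(m, ch)
  expect_equal(rep_$brier, m$training_meta$precision, tolerance = 1e-12)
  expect_equal(rep_$mean_observed, mean(ch$data$outcome), tolerance = 1e-12)

  # separable toy data must raise a convergence error, not huge coefficients
  set.seed(8)
  x <- c(rnorm(15, -3), rnorm(15, 3))
  d <- data.frame(id = as.character(1:30), treated = 0,
                  outcome = as.integer(x > 0), x1 = x, x2 = rnorm(30))
  expect_error(fit_prognostic_model(cohort(d, toy_schema(),
                                           outcome_scale = "binary")),
               "convergence error")
})

test_that("rows with missing covariates are excluded and counted, never imputed", {
  ch <- toy_cohort(n = 50, seed = 60)
  ch$data$x1[c(3, 7)] <- NA
  m <- fit_prognostic_model(ch)
  expect_equal(m$training_meta$n, 48)
  expect_equal(m$training_meta$n_excluded_missing, 2)
  full <- toy_cohort(n = 50, seed = 60)
  full$data <- full$data[-c(3, 7), ]
  m_oracle <- fit_prognostic_model(full)
  expect_equal(m$coefficients, m_oracle$coefficients, tolerance = 1e-12)
})
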