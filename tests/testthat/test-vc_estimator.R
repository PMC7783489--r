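test_that("virtual-control predictions equal a row-by-row dot-product oracle", {
  tr <- toy_cohort(n = 100, seed = 1)
  m <- fit_prognostic_model(tr)
  tx <- toy_cohort(n = 40, seed = 2, treated = 1L)
  vcs <- predict_virtual_controls(m, tx)
  oracle <- vapply(seq_len(40), function(i)
    m$intercept + sum(m$coefficients * c(tx$data$x1[i], tx$data$x2[i])),
    numeric(1))
  expect_equal(vcs$predicted, oracle, tolerance = 1e-12)
  expect_identical(vcs$id, tx$data$id)
})

test_that("degenerate predictions: intercept-only linear and logistic models", {
  sch <- toy_schema()
  tm <- list(n = 50, precision = 0, version = 1, provenance = "")
  d <- data.frame(id = c("a", "b"), treated = 1L, outcome = c(0, 1),
                  x1 = 0, x2 = 0)
  lin <- prognostic_model("linear", intercept = 3.5,
                          coefficients = c(x1 = 0.7, x2 = -0.2),
                          schema = sch, training_meta = tm)
  ch <- cohort(d, sch, outcome_scale = "continuous")
  expect_equal(predict_virtual_controls(lin, ch)$predicted, c(3.5, 3.5))

  logi <- prognostic_model("logistic", intercept = 0,
                           coefficients = c(x1 = 1, x2 = 1),
                           schema = sch, training_meta = tm)
  chb <- cohort(d, sch, outcome_scale = "binary")
  expect_equal(predict_virtual_controls(logi, chb)$predicted, c(0.5, 0.5))
})

test_that("subjects with missing covariates are skipped and listed", {
  m <- fit_prognostic_model(toy_cohort(n = 60, seed = 3))
  tx <- toy_cohort(n = 10, seed = 4, treated = 1L)
  tx$data$x2[c(2, 5)] <- NA
  expect_warning(vcs <- predict_virtual_controls(m, tx), "skipping 2")
  expect_equal(nrow(vcs), 8)
  expect_identical(attr(vcs, "skipped"), tx$data$id[c(2, 5)])
  expect_error(predict_virtual_controls(m, toy_cohort(n = 5, treated = 0L)),
               "contract error.*treated == 1")
})

test_that("extrapolation beyond training support is flagged per subject", {
  m <- fit_prognostic_model(toy_cohort(n = 50, seed = 5))
  tx <- toy_cohort(n = 6, seed = 6, treated = 1L)
  tx$data$x1[4] <- max(m$schema$support$x1) + 5
  vcs <- predict_virtual_controls(m, tx)
  expect_identical(which(vcs$extrapolated), 4L)
  est <- estimate_effect_continuous(tx, vcs)
  expect_equal(est$n_extrapolated, 1)
})

test_that("added-value scores are observed minus predicted and linear in the mean", {
  tx <- toy_cohort(n = 30, seed = 7, treated = 1L)
  vcs <- manual_vc_set(tx$data$id, tx$data$outcome)
  expect_equal(added_value_scores(tx, vcs)$score, rep(0, 30))
  vcs1 <- manual_vc_set(tx$data$id, tx$data$outcome - 1)
  sc <- added_value_scores(tx, vcs1)
  expect_equal(sc$score, rep(1, 30))
  set.seed(8)
  vcs2 <- manual_vc_set(tx$data$id, rnorm(30))
  sc2 <- added_value_scores(tx, vcs2)
  expect_equal(mean(sc2$score), mean(sc2$observed) - mean(sc2$predicted),
               tolerance = 1e-12)
  bad <- manual_vc_set(c("nope", tx$data$id[-1]), rnorm(30))
  expect_error(added_value_scores(tx, bad), "alignment error")
})

test_that("continuous effect CI matches the textbook one-sample t on a toy vector", {
  scores <- c(1, 2, 3, 4, 5)
  tx <- cohort(data.frame(id = letters[1:5], treated = 1L, outcome = scores,
                          x1 = 0, x2 = 0),
               toy_schema(), outcome_scale = "continuous")
  vcs <- manual_vc_set(tx$data$id, rep(0, 5))
  est <- estimate_effect_continuous(tx, vcs)
  # hand computation: mean 3, se sqrt(2.5/5), t_{0.975,4} = 2.776445
  expect_equal(est$point, 3)
  expect_equal(est$ci, c(3 - 2.776445 * sqrt(0.5), 3 + 2.776445 * sqrt(0.5)),
               tolerance = 1e-5)
  expect_equal(est$standardized, 3 / sqrt(2.5), tolerance = 1e-12)
  expect_identical(est$uncertainty_mode, "plugin")
  # degenerate zero-variance case
  vcs0 <- manual_vc_set(tx$data$id, scores)
  est0 <- estimate_effect_continuous(tx, vcs0)
  expect_equal(est0$point, 0)
  expect_equal(est0$test$p.value, 1)
  expect_true(est0$degenerate)
  expect_error(estimate_effect_continuous(
    cohort(tx$data[1, ], toy_schema(), outcome_scale = "continuous"),
    manual_vc_set(tx$data$id[1], 0)), "insufficient-data")
})

test_that("the assist-device configuration gives risk difference 0.58", {
  n <- 100
  tx <- cohort(data.frame(id = as.character(1:n), treated = 1L,
                          outcome = c(rep(1, 69), rep(0, 31)),
                          x1 = 0, x2 = 0),
               toy_schema(), outcome_scale = "binary")
  vcs <- manual_vc_set(tx$data$id, rep(0.11, n), family = "logistic")
  est <- estimate_effect_binary(tx, vcs, B = 0)
  expect_equal(est$point, 0.58, tolerance = 1e-12)
  expect_equal(est$risk_ratio, 0.69 / 0.11, tolerance = 1e-12)
  expect_lt(est$test$p.value, 1e-10)
})

test_that("predictions equal to the event rate give zero risk difference", {
  set.seed(9)
  n <- 50
  y <- rbinom(n, 1, 0.4)
  tx <- cohort(data.frame(id = as.character(1:n), treated = 1L, outcome = y,
                          x1 = 0, x2 = 0),
               toy_schema(), outcome_scale = "binary")
  vcs <- manual_vc_set(tx$data$id, rep(mean(y), n), family = "logistic")
  est <- estimate_effect_binary(tx, vcs, B = 0)
  expect_equal(est$point, 0, tolerance = 1e-12)
  expect_lt(abs(est$test$statistic), 1e-10)
  bad <- manual_vc_set(tx$data$id, c(1.2, rep(0.5, n - 1)),
                       family = "logistic")
  expect_error(estimate_effect_binary(tx, bad, B = 0),
               "contract error.*\\[0, 1\\]")
})

test_that("exact Poisson-binomial tail equals exhaustive 2^10 enumeration", {
  set.seed(10)
  p <- runif(10, 0.05, 0.9)
  mu <- sum(p)
  grid <- as.matrix(expand.grid(rep(list(0:1), 10)))
  probs <- apply(grid, 1, function(g) prod(ifelse(g == 1, p, 1 - p)))
  counts <- rowSums(grid)
  for (k in c(0, 3, 7, 10)) {
    brute <- sum(probs[abs(counts - mu) >= abs(k - mu) - 1e-12])
    expect_equal(virtualcontrols:::poisson_binomial_pvalue(k, p), brute,
                 tolerance = 1e-12)
  }
  # normal approximation is close to exact in a moderate configuration
  y <- c(rep(1, 7), rep(0, 3))
  tx <- cohort(data.frame(id = as.character(1:10), treated = 1L,
                          outcome = y, x1 = 0, x2 = 0),
               toy_schema(), outcome_scale = "binary")
  vcs <- manual_vc_set(tx$data$id, p, family = "logistic")
  exact <- estimate_effect_binary(tx, vcs, B = 0)$test$p.value
  z <- (sum(y) - mu) / sqrt(sum(p * (1 - p)))
  expect_equal(2 * pnorm(-abs(z)), exact, tolerance = 0.12)
})

test_that("risk difference is invariant to subject ordering and deterministic", {
  set.seed(11)
  n <- 40
  y <- rbinom(n, 1, 0.5)
  p <- runif(n, 0.1, 0.9)
  tx <- cohort(data.frame(id = as.character(1:n), treated = 1L, outcome = y,
                          x1 = 0, x2 = 0),
               toy_schema(), outcome_scale = "binary")
  vcs <- manual_vc_set(tx$data$id, p, family = "logistic")
  e1 <- estimate_effect_binary(tx, vcs, B = 0)
  perm <- sample(n)
  tx2 <- cohort(tx$data[perm, ], toy_schema(), outcome_scale = "binary")
  vcs2 <- manual_vc_set(tx$data$id[perm], p[perm], family = "logistic")
  e2 <- estimate_effect_binary(tx2, vcs2, B = 0)
  expect_equal(e1$point, e2$point, tolerance = 1e-12)
  expect_equal(e1$test$p.value, e2$test$p.value, tolerance = 1e-12)
})

test_that("bootstrap propagation is reproducible, bookkept, and wider than plugin", {
  tr <- toy_cohort(n = 50, seed = 12)
  tx <- toy_cohort(n = 50, seed = 13, treated = 1L, tau = 0.5)
  expect_error(bootstrap_propagate(tr, tx, B = 10), "B >= 100")
  b1 <- bootstrap_propagate(tr, tx, B = 100, seed = 99)
  b2 <- bootstrap_propagate(tr, tx, B = 100, seed = 99)
  expect_identical(b1$ci, b2$ci)
  expect_equal(b1$B_used + b1$B_failed, 100)
  expect_identical(b1$uncertainty_mode, "bootstrap-propagated")

  # propagated intervals are on average at least as wide as pure plugin
  set.seed(14)
  w_boot <- w_plug <- numeric(20)
  for (r in 1:20) {
    tr_r <- toy_cohort(n = 40, seed = 200 + r)
    tx_r <- toy_cohort(n = 40, seed = 300 + r, treated = 1L)
    m_r <- fit_prognostic_model(tr_r)
    vc_r <- predict_virtual_controls(m_r, tx_r)
    w_plug[r] <- diff(estimate_effect_continuous(tx_r, vc_r,
                                                 propagate = "none")$ci)
    w_boot[r] <- diff(bootstrap_propagate(tr_r, tx_r, B = 100, seed = r)$ci)
  }
  expect_gte(mean(w_boot), mean(w_plug))
})
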