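---
title: "Virtual controls: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual controls: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualcontrols)
```

## The method

Randomized comparison groups exist to supply a counterfactual: what
would have happened to the treated patients without the intervention.
When outcomes under no treatment (or standard of care) are predictable
from measured covariates, that counterfactual can instead be generated
statistically. The framework implemented here proceeds in a loop:

1. Collect untreated cohorts in which the outcome and candidate
   predictors are measured.
2. Fit a prognostic model — ordinary least squares for a continuous
   outcome, maximum-likelihood logistic regression for a binary one —
   and quantify its precision (R² for linear models, Brier score and
   calibration for logistic ones). Record the observed range of every
   continuous covariate as the model's *support*.
3. Enroll patients in a single-arm study of the new intervention and
   measure the same covariates.
4. Plug each participant's covariates into the model. The predicted
   outcomes (values, or event probabilities) are the **virtual
   controls**.
5. Observe the actual outcomes under treatment.
6. Estimate the effect by comparing actual outcomes with the virtual
   controls. For continuous outcomes the per-subject **added-value
   score** is observed minus predicted; its mean estimates the effect,
   with a one-sample t interval, and mean/SD of the scores is the
   standardized effect size. For binary outcomes the estimate is the
   risk difference between the observed event rate and the mean
   predicted probability, tested against the Poisson-binomial null
   (exact for n ≤ 20, normal approximation with variance
   Σpᵢ(1−pᵢ) above).
7. As data accumulate, pool cohorts, extend the covariate set, and
   refit (`pool_and_refit()`); version numbers track the evolving
   coefficient sets, which are themselves a research product
   (`write_model()`/`read_model()`).

The per-patient end product is `patient_report()`: predicted outcome
without and with the intervention, each with an interval, for one
patient's covariates.

## Uncertainty: what the intervals account for

The t construction on added-value scores treats the predictions as
known. But predictions from a model estimated on a finite training
cohort share that model's estimation error, which is *common to all
scores* and therefore not captured by their sample variance. Ignoring
it inflates the test: the true variance of the mean score is
σ²(1/n_t + x̄ᵀ(XᵀX)⁻¹x̄) ≈ σ²(1/n_t + 1/n_train), while the naive
standard error estimates only the first term — at n_train = 500 and
n_t = 100 that alone pushes a nominal 5% test to about 7% rejection
under the null.

`estimate_effect_continuous()` therefore defaults to
`propagate = "model"`: the variance of the mean linear predictor,
available from the stored coefficient covariance, is added to the
squared standard error. `propagate = "none"` gives the pure plugin
analysis (which matches how published case studies typically treat
predictions as given) and is retained for comparison.
`bootstrap_propagate()` offers a third route: a full nonparametric
bootstrap that resamples *both* the training cohort (refitting the
model each time) and the treated cohort, so its percentile intervals
reflect both uncertainty sources; this is also why its intervals are on
average at least as wide as plugin intervals. Degrees of freedom stay
at n_t − 1, a slightly conservative choice when the propagated term is
non-negligible.

For binary outcomes the test is plugin (probabilities as given): the
Poisson-binomial null is already heterogeneous per subject, and the
exact tail is evaluated by direct convolution of the probability mass
function for n ≤ 20.

## The synthetic cohorts

`simulation_scenario()` fixes a generative truth with the structure the
method assumes and the failure modes discussed in the intervention-
research literature:

* **Covariates**: p independent standard-normal predictors (default
  p = 3 with β = 1/√3 each, so Var(xᵀβ) = 1), optionally exchangeably
  correlated (`rho`) and augmented with binary covariates of stated
  prevalence. Real prognostic variables are correlated, skewed, and
  measured with error; only the correlation knob is modelled.
* **Prognostic accuracy**: residual σ and hidden-confounder weight γ
  fix the true R² in closed form,
  R² = Var(xᵀβ)/(Var(xᵀβ) + γ² + σ²), and `scenario_with_r2()`
  back-solves σ for a target R² — the control used by the
  accuracy-to-power sweep.
* **Hidden confounding and self-selection**: one standard-normal
  variable u (a "motivation for improvement" analogue) adds γ·u to the
  outcome and can drive opt-in into the single-arm study with
  probability plogis(offset + strength·u). The induced bias of the
  virtual-control estimator is γ·E[u | opt-in], a logistic-normal
  integral that `ground_truth()` evaluates by quadrature — the analytic
  oracle the Monte-Carlo cells are checked against. Selection on an
  *observed* covariate induces no bias, since the model conditions on
  it: today's confounder, once measured, is tomorrow's predictor.
* **Preference and demoralization**: in an unblinded randomized trial
  with preference fraction π for the treatment arm and 1:1 assignment,
  the treatment arm has expected fraction π pleased with its assignment
  and the control arm 1 − π. Subjects randomized against their
  preference have a non-negative penalty subtracted from their outcome
  (log-odds for binary outcomes). The worked 100-participant case
  (π = 0.8): about 40 treatment-preferrers per 50-person arm, so 80% of
  the treatment arm pleased and 80% of the control arm displeased,
  biasing the unadjusted arm difference by 0.6 × penalty. Magnitudes of
  demoralization penalties are illustrative defaults, not estimates
  from data.

Defaults (n_train = 500, n_treated = 100, n_rct_per_arm = 100, σ = 1,
i.e. R² = 0.5) are the cohort sizes used throughout the operating-
characteristics checks; they are desk-scale but large enough for
asymptotic behaviour to show.

What passing tests on these cohorts show is that the estimators are
correct *under the stated generative laws*. They do not show that any
real registry's covariates suffice for prediction, that missingness is
ignorable, or that outcome definitions are stable across sites — the
judgments a real application would still have to defend.

## Operating characteristics

`run_cell()` runs the full pipeline per replicate (generate training
cohort → fit → generate single-arm cohort → predict → estimate; or
generate a two-arm randomized cohort → covariate-adjusted two-arm
analysis) and aggregates bias, RMSE, CI coverage, and the rejection
rate of the two-sided α = 0.05 test against zero effect — the declared
convention for a "correct decision", configurable via `alpha`.
Replicate i uses seed `seed + i`, so any replicate can be reproduced in
isolation; failed replicates are excluded and counted, and a cell with
more than 5% failures is flagged invalid.

Two comparisons deserve a note:

* **Design equivalence.** With selection, confounding, and
  demoralization all zero, both designs estimate the same estimand and
  should agree in bias and power when given comparable information. The
  randomized comparator is analysed with covariate adjustment, and the
  equivalence check uses n_rct_per_arm = 2·n_treated with a large
  training cohort, so both designs have (asymptotically) the same
  standard error ≈ σ√(2/N): the power comparison is like-for-like by
  construction, rather than conflating design bias with sample-size
  bookkeeping.
* **The accuracy-to-power map.** `r2_sweep()` back-solves σ from each
  grid R², runs a cell per value, reports the smallest grid R² whose
  power meets the threshold, and checks monotonicity (allowing 3
  pooled MC standard errors of sampling slack). At τ = 0.4 with 60
  treated subjects, 80% power arrives around R² ≈ 0.6; as R² → 0 the
  rejection rate collapses to α.

`power_two_proportion()` supports the rare-event argument for
nonrandomized safety surveillance: the two-sided pooled-z power is
computed by exact binomial enumeration over the effective outcome
supports whenever that is feasible (it always is in the rare-event
regime), and by normal approximation otherwise. At an adverse-event
rate of 10⁻⁵ against 0, trials with 15,000 per arm have power of about
2 × 10⁻⁵ — indistinguishable from nothing.

## Numerical and interface choices

* Model families are fixed to ordinary linear and logistic regression —
  the stated baseline of the framework; the `family` field leaves room
  for extensions. No regularization, splines, or learners; no automated
  variable selection; no survival outcomes (a natural extension, not
  implemented).
* Logistic fitting: IRLS with iteration cap 100 and deviance tolerance
  1e-8. Perfect separation is detected explicitly (fitted probabilities
  saturated in both classes) and raised as a convergence error rather
  than returning divergent coefficients.
* Missing covariates: rows are excluded from fits and skipped (with a
  warning and an id list) in prediction — never imputed, so the
  estimator's contract stays transparent.
* Calibration slope for a zero-variance prediction vector is reported
  as `NA` (undefined), not an error.
* Categorical covariates use reference-level dummy coding; the first
  listed level is the reference.
* Cohorts are CSV (UTF-8, "." decimal); models are JSON coefficient
  sets serialized with 17 significant digits so doubles survive the
  decimal round-trip exactly; scenarios are YAML. Machine-readable
  outputs have a fixed field order, making seeded runs byte-identical.
* Pooling refits from scratch on the concatenated data (the refit is
  the oracle, not an approximation); schema extension treats the new
  variable as missing in older cohorts, excluding those rows from the
  extended fit. Fitted models keep their training cohort in memory to
  make this possible; serialized coefficient sets do not, by design.

## Known limitations

* The hidden-confounder model is a single additive normal variable;
  real selection is richer.
* Propagated intervals use n−1 degrees of freedom rather than a
  Satterthwaite correction; coverage is marginally conservative.
* Binary-outcome effect estimation does not propagate training
  uncertainty analytically (use `bootstrap_propagate()`).
* Multiplicity across outcome variables, time-varying treatments, and
  survival endpoints are out of scope.
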