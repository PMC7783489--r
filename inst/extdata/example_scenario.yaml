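# Example simulation scenario for virtualcontrols.
# Every field maps to an argument of simulation_scenario(); omitted
# fields take the documented defaults.

p: 3                  # continuous standard-normal covariates
beta: [0.577, 0.577, 0.577]   # true coefficients; Var(x'beta) ~ 1
intercept: 0.0
sigma: 1.0            # residual s.d.; with the betas above, true R2 = 0.5
tau: 0.5              # true treatment effect (additive / log-odds)
gamma: 0.0            # hidden-confounder weight on the outcome
selection:
  mode: none          # none | observed | hidden
  strength: 0.0       # slope of the logistic opt-in probability
  offset: 0.0         # baseline opt-in log-odds
preference: 0.8       # fraction of trial volunteers preferring treatment
demoralization: 0.0   # outcome penalty for assignment against preference
n_train: 500
n_treated: 100
n_rct_per_arm: 100
rho: 0.0              # exchangeable correlation among covariates
outcome_scale: continuous   # continuous | binary
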