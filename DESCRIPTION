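Package: virtualcontrols
Title: Virtual-Control Counterfactuals for Single-Arm Intervention Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for evaluating interventions in single-arm studies by
    comparing observed outcomes against per-patient counterfactual
    predictions ("virtual controls") from prognostic models trained on
    untreated or standard-of-care cohorts. Provides cohort and
    coefficient-set data structures with validated text serialization,
    linear and logistic prognostic model fitting with external validation
    and iterative pooling, added-value effect estimation with
    model-propagated and bootstrap uncertainty, a Poisson-binomial test
    for binary outcomes, per-patient decision-support reports, synthetic
    cohort generators with controllable prognostic R-squared, hidden
    confounding, self-selection, and preference/demoralization
    mechanisms, and a Monte-Carlo engine for operating characteristics
    (bias, coverage, type-I error, power) of virtual-control versus
    randomized designs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
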