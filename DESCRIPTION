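Package: necsuff
Title: Degrees of Necessity and Sufficiency for Binary and Survival Outcomes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the degree to which levels of a prognostic factor are
    necessary (DN) or sufficient (DS) for a dichotomous or right-censored
    survival outcome, together with the associated explained-variation (EV)
    decomposition. DN generalizes the attributable risk and DS the reverse
    attributable risk to continuous factors and to survival outcomes, using
    unconditional and conditional event probabilities (or cumulative
    incidences) from any calibrated model. Includes closed forms for 2x2
    tables, inverse-probability-of-censoring-weighted estimators over the
    distinct event times, the Schemper-Henderson explained variation for
    survival, percentile and BCa bootstrap confidence intervals with a
    direction-consistency truncation rule, exact and quadrature-based
    population-value calculators for two-point, logistic-normal and
    two-group exponential scenarios, and a seeded simulation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
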