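Package: jmsens
Title: Pattern-Mixture Sensitivity Analysis for Joint Models of
    Longitudinal Cognition and Time to Dementia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian joint modelling of a bounded longitudinal cognitive
    outcome and the hazard of dementia, with an adaptive
    Metropolis-within-Gibbs sampler, delayed entry, and a lagged
    current-value plus current-slope association structure.  Implements a
    pattern-mixture multiple-imputation sensitivity analysis for dropout
    that may be missing not at random: missing post-dropout outcomes are
    imputed under delta-adjusted pattern-mixture models (constant,
    age-threshold, or age-varying cubic delta), the substantive joint
    model is refitted to each completed data set, and results are pooled
    across imputations.  Also provides subject-specific dynamic
    prediction of the longitudinal trajectory and of the cumulative
    incidence of the event, and a seeded generator of multi-cohort
    longitudinal studies with informative dropout for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    splines,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
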