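Package: adtraj
Title: Group-Based Trajectory Modeling of Medication Adherence from Pharmacy Claims
Version: 0.1.0
Authors@R:
    person("adtraj", "maintainers", email = "adtraj@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping longitudinal medication adherence from
    administrative pharmacy claims. Builds daily supply calendars with
    stockpiling, computes 30-day monthly proportion of days covered (PDC)
    and dichotomized adherence indicators, fits group-based trajectory
    models (finite mixtures of logistic polynomial trajectories) by EM,
    performs BIC-guided specification search with per-group polynomial
    order reduction, reports classification adequacy diagnostics (average
    posterior probability, odds of correct classification, relative
    entropy), and relates trajectory-group membership probabilities to
    baseline covariates via fractional multinomial logit with
    heteroskedasticity-robust standard errors. Includes a synthetic claims
    cohort generator so the full pipeline is testable without restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
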