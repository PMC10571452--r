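Package: jointvitals
Title: Joint Modelling of Bivariate Vital-Sign Trajectories and Time to Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Joint maximum-likelihood analysis of two correlated longitudinal
    vital signs (pulse rate and body temperature) and a right-censored time to
    recovery. Provides a bivariate linear mixed sub-model with correlated
    random intercepts and slopes across outcomes, a proportional-hazards
    survival sub-model with a piecewise-constant baseline hazard, and a shared
    random-effects joint model with current-value, current-value-and-slope, or
    shared-random-effects association structures, estimated by adaptive
    Gauss-Hermite quadrature. Includes a synthetic cohort generator that
    simulates from the exact joint data-generating model (closed-form inverse
    cumulative-hazard event times), Kaplan-Meier and log-rank exploratory
    summaries, marginal correlation evolution between the two outcomes, and a
    reproducible simulate-explore-fit-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
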