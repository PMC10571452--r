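# jointvitals

Joint maximum-likelihood modelling of two correlated longitudinal vital
signs — pulse rate (PR, bpm) and body temperature (BT, °C), measured every
six hours during hospital treatment — together with the right-censored time
to recovery in hours.  The package is aimed at biostatisticians analysing
repeated vital-sign measurements linked to a clinical event, and at anyone
running simulation studies of shared-random-effects joint models.

## The model

A bivariate linear mixed sub-model with correlated random intercepts and
slopes across the two outcomes,

    y_ik(t) = x_ik' beta_k + b_ik0 + b_ik1 t + e_ik(t),   e ~ N(0, sigma_k^2),
    b_i = (b_PR0, b_PR1, b_BT0, b_BT1) ~ N(0, D)   (unstructured 4x4 D),

is linked to a proportional-hazards survival sub-model with a
piecewise-constant baseline hazard,

    h_i(t|b) = lambda_0(t) exp{ gamma' w_i + assoc_i(b, t) },

through one of three association structures: the current (noise-free)
biomarker values `alpha_1 w_PR(t) + alpha_2 w_BT(t)`, current values plus
subject-specific slopes, or the shared random slopes directly.  The joint
likelihood integrates the shared random effects by adaptive Gauss–Hermite
quadrature; because the log hazard is linear in t, the 4-dimensional
integral reduces exactly to at most 2 dimensions and the cumulative hazard
is closed-form per baseline piece.  Hazard ratios are `exp(coef)`
throughout.

The package also provides the separate analyses (bivariate LMM by ML with
GLS-profiled fixed effects; Cox PH via the `survival` package), exploratory
tools (Kaplan–Meier curves, log-rank tests, descriptive tables, profile
plots, the model-implied marginal correlation between PR and BT over time),
dynamic conditional-survival predictions, and a synthetic cohort generator
that simulates from the exact joint model with analytic inverse-hazard
event times.

## A worked example

```r
library(jointvitals)

cfg <- sim_config(n_subjects = 214, seed = 1)   # study-design defaults
sim <- simulate_cohort(cfg)
co  <- sim$cohort
co
#> Cohort: 214 subjects, 4152 longitudinal measurements ( PR, BT )
#> Events: 186 recovered, 28 censored

km <- kaplan_meier(co$surv$event_time, co$surv$status)
median_survival(km)
#> $median
#> [1] 68.0779
#> $defined
#> [1] TRUE

fit <- fit_joint(co, association = "shared_random_effects",
                 fixed = list(PR = "time_h", BT = "time_h"),
                 survival_covariates = c("danger_yes", "comorbid_yes"),
                 n_pieces = 3)
association_summary(fit)[, c("term", "estimate", "se", "hr", "p")]
#>       term estimate      se     hr       p
#> 1 alpha_PR  -0.2173 0.09293 0.8047 0.01938
#> 2 alpha_BT  -0.1936 0.11910 0.8240 0.10396
```

The cohort above was generated with shared-random-effects association
(-0.4268, -0.2931): both fitted coefficients come out negative —
faster-declining vital-sign trajectories go with a higher recovery
hazard — though attenuated on this single cohort, where 214 subjects
identify the slope-association coefficients only weakly (the vignette's
recovery study quantifies the estimator's behaviour across replicates).
`summary(fit)` prints the longitudinal
and survival coefficient blocks, `information_criteria(fit)` the AIC/BIC
with their longitudinal/survival conditional decomposition, and
`conditional_survival(fit, id, t, horizon)` dynamic predictions for one
subject.

A configuration-driven end-to-end run (simulate → explore → fit-lmm →
fit-cox → fit-joint → report, with a checksummed manifest) is

```r
run_pipeline(list(simulate = list(n_subjects = 120),
                  fit = list(association = "shared_random_effects",
                             fixed = list(PR = "time_h", BT = "time_h"),
                             survival_covariates = "danger_yes",
                             n_pieces = 3),
                  seed = 42), out_dir = "run1")
```

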