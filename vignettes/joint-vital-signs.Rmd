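---
title: "Joint modelling of bivariate vital-sign trajectories and time to recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of bivariate vital-sign trajectories and time to recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Hospitalised pneumonia patients are monitored on a six-hourly schedule for
pulse rate (PR, beats per minute) and body temperature (BT, degrees
Celsius) until they recover or observation ends at the 102-hour visit
horizon.  Two questions are entangled: how the two vital signs evolve
under treatment, and how their evolution relates to the hazard of
recovery.  Modelling the trajectories and the recovery time separately
ignores that the same latent patient state drives both; `jointvitals`
implements the joint maximum-likelihood analysis.

# The model

## Bivariate longitudinal sub-model

For subject $i$, outcome $k \in \{PR, BT\}$ and visit time $t$ (hours
since admission),

$$y_{ik}(t) = x_{ik}^\top \beta_k + b_{ik0} + b_{ik1} t +
  \varepsilon_{ik}(t), \qquad \varepsilon_{ik}(t) \sim N(0, \sigma_k^2),$$

where $x_{ik}$ holds an intercept, dummy-coded baseline covariates
(reference level = first category) and the visit time.  The four random
effects $b_i = (b_{i,PR,0}, b_{i,PR,1}, b_{i,BT,0}, b_{i,BT,1})$ are
jointly Gaussian with an unstructured $4\times4$ covariance $D$, so
random intercepts and slopes are correlated both within and *across* the
two outcomes; this cross-outcome block is what makes the model
bivariate rather than two independent mixed models.  Measurement errors
are independent across visits and outcomes and independent of $b_i$.

The implied marginal correlation between the two observed outcomes at a
common time $t$ is, with $z(t) = (1, t)^\top$ and $D_{k\ell}$ the
$2\times2$ blocks of $D$,

$$\rho_{12}(t) = \frac{z(t)^\top D_{12}\, z(t)}
 {\sqrt{\{z(t)^\top D_{11} z(t) + \sigma_1^2\}
        \{z(t)^\top D_{22} z(t) + \sigma_2^2\}}},$$

computed by `marginal_correlation_profile()`; an empirical per-visit
correlation (`empirical_correlation_profile()`) is reported alongside it
because the two can diverge when the model is misspecified.

## Survival sub-model and association structures

Recovery time follows a proportional-hazards model with a
piecewise-constant baseline hazard $\lambda_0(t)$,

$$h_i(t \mid b_i) = \lambda_0(t)\,
  \exp\{\gamma^\top w_i + \mathrm{assoc}_i(b_i, t)\},$$

where $w_i$ are the baseline covariate indicators (no intercept: the
baseline hazard carries the reference subject).  Three association
structures are supported, selected by `fit_joint(association = ...)`:

* **current value** — $\sum_k \alpha_k\, w_{ik}(t)$ with
  $w_{ik}(t) = x_{ik}^\top\beta_k + b_{ik0} + b_{ik1}t$ the *noise-free*
  biomarker level (the identity functional of the latent value);
* **current value and slope** — adds $\alpha_{k}^{(s)}\, w_{ik}'(t)$,
  the subject-specific trajectory derivative;
* **shared random effects** — the random slopes enter directly,
  $\alpha_1 b_{i,PR,1} + \alpha_2 b_{i,BT,1}$.

All three are implemented because the source analyses of this design are
ambiguous about which structure sits behind reported single-coefficient
association tables; none is asserted to be canonical.  A fit uses
exactly one structure (the identifiability guard: structures cannot be
combined).

## The joint likelihood

$$\ell = \sum_i \log \int
  \Big[\textstyle\prod_{k,j} N\!\big(y_{ikj};\, x^\top\beta_k + z^\top
  b_{ik},\, \sigma_k^2\big)\Big]\,
  h_i(T_i|b)^{\delta_i}\, e^{-\Lambda_i(T_i|b)}\, N(b; 0, D)\, db ,$$

with censored subjects ($\delta_i = 0$) contributing survival-only
factors.  Two structural facts make this tractable without Monte-Carlo
methods:

1. The Gaussian longitudinal factor integrates in closed form, leaving
   the expectation of the survival factor under the subject's
   *longitudinal posterior* $b \mid y_i \sim N(m_i, V_i)$ — this is the
   "adaptive" centring of the quadrature.
2. In every supported association structure the log hazard is *linear in
   $t$* at fixed $b$: $\log h_i(t|b) = \log\lambda_0(t) + u_i(b) +
   v_i(b)\,t$ with $u_i, v_i$ linear in $b$.  The survival factor
   therefore depends on the 4-dimensional $b$ only through the Gaussian
   image $(u_i, v_i)$, and the nominal 4-dimensional Gauss–Hermite
   product rule collapses *exactly* to at most 2 dimensions (1 for
   shared random effects, 0 when $\alpha = 0$).  This replaces the usual
   pruning of high-dimensional product grids; nothing is approximated
   beyond the 1- or 2-dimensional rule itself.

The cumulative hazard is closed-form per baseline piece,
$\int_a^b e^{u + vt}\,dt = e^u (e^{vb} - e^{va})/v$ with the $v \to 0$
limit handled by `expm1`, so likelihood evaluation involves no numerical
integration at all.  The default rule uses 7 nodes per dimension;
refinement checks in the test suite show successive differences below
$10^{-4}$ by 9 nodes on cohort-sized problems.

## Estimation and standard errors

`fit_joint()` maximises the quadrature likelihood by BFGS on an
unconstrained parameterisation: log residual variances, the
log-Cholesky factor of $D$ (positive semi-definiteness holds by
construction), log baseline rates, and untransformed $\beta, \gamma,
\alpha$.  Starting values come from the separate fits — a profiled
bivariate LMM (`fit_blmm()`, fixed effects profiled out by generalised
least squares so only 12 variance parameters are optimised) and a
piecewise-exponential proportional-hazards fit (`fit_pwexp()`, via the
standard Poisson-likelihood equivalence) — with $\alpha$ started at 0.
Convergence uses a relative function tolerance of $10^{-9}$ (BFGS,
at most 500 iterations); non-convergence and non-positive-definite
observed information are *flagged* on the returned object, never raised,
so simulation studies can tabulate them.  Standard errors are
delta-method transforms of the inverse numerical observed information;
Wald intervals are formed on the coefficient scale and exponentiated for
hazard ratios.  ML (not REML) is used throughout so separate and joint
fits share one coherent likelihood and the $\alpha = 0$ separability
identity is exact.

The baseline hazard defaults to 5 pieces cut at event-time quantiles
(`n_pieces`); the synthetic study conditions use 3 pieces.  Efron tie
handling is the `fit_cox()` default (hour-grid data are heavily tied),
with Breslow selectable.

## Model comparison

`information_criteria()` reports AIC ($-2\ell + 2p$) and BIC
($-2\ell + p\log n_{\text{subjects}}$) with a conditional decomposition:
the survival part evaluates the conditional survival log-likelihood at
the empirical-Bayes random-effect estimates (BLUPs), the longitudinal
part is the remainder, and the parameter penalty is split by sub-model.
The parts sum to the total by construction — this is a standard
conditional split, labelled as such.  `conditional_survival()` provides
dynamic predictions $P(T \ge t + \Delta \mid T \ge t,
\mathcal{Y}_i(t))$ by empirical-Bayes plug-in at the posterior mode of
$b_i$ given the history to the landmark $t$.

# The synthetic cohort generator

`simulate_cohort()` draws from the exact joint data-generating model, so
every downstream stage has a parameter-recovery test surface.  Event
times invert the cumulative hazard analytically per baseline piece
(`pw_invert()`); longitudinal records are generated on the visit grid
and truncated at the observed time, so the truncation invariant (no
measurement after the event) holds by construction.

## Default study conditions

The defaults emulate the pneumonia cohort: $n = 214$, visits at
$6, 12, \ldots, 102$ h (at most 17 per outcome), twelve baseline
covariates sampled at the cohort's observed marginal frequencies, fixed
effects and survival coefficients at the published joint-model
estimates, and administrative censoring at 102 h (the source is silent
on how non-recovered discharges were censored; the simple administrative
mechanism is the default, and an independent uniform dropout is
available via `dropout_prob`).

Three defaults deserve explanation:

* **The published $D$ is indefinite.**  The published random-effects
  covariance has eigenvalues $(230.0, 0.72, 0.64, -0.27)$; no Gaussian
  vector has it.  The generator projects it to the nearest positive
  semi-definite matrix by eigenvalue clamping, which perturbs entries by
  at most $\approx 0.13$ (the cross-outcome intercept covariance moves
  from 12.852 to 12.842).
* **Within-patient dispersion.**  The published within-dispersion
  numbers 13.4975 (PR) and 0.4963 (BT) are read as *variances* by
  default ($\sigma \approx 3.67$ bpm, $0.70$ °C — clinically sensible
  measurement noise); `residual_scale = "sd"` supports the alternative
  reading.  Neither is asserted.
* **Association structure.**  The default generator uses shared random
  effects with slope coefficients $(-0.4268, -0.2931)$: those published
  coefficients are labelled slope-association parameters, and at PR's
  scale ($\approx 118$ bpm) a current-value coefficient of $-0.43$ would
  put $e^{\alpha w}$ at $e^{-50}$ — a degenerate hazard.

## Baseline-hazard calibration

The baseline rates are calibrated once, as part of the study
conditions, to two marginal targets: median recovery time 66 h and an
85.51% recovery fraction by 102 h.  With the published survival
coefficients the subject-specific hazard multipliers
$e^{\gamma^\top w + \alpha^\top b}$ are heterogeneous enough that the
survival curve has a heavy late tail — after $S(66) = 0.5$ it cannot
reach $S(84) = 1/3$, so "equal-probability pieces" are unattainable and
the cutpoints were fixed at $(48, 84)$ h with the first-to-second rate
ratio set to 2 (an increasing hazard) and the last rate free.  The
frozen defaults are $\lambda = (0.1043, 0.2087, 2.2300)$ per hour.  The
large final rate is the calibration's honest consequence: most patients
still hospitalised at 84 h recover before the 102 h horizon.  The test
suite verifies the calibration as an aggregate over 20 seeded cohorts
(per-seed medians at $n = 214$ carry a Monte-Carlo spread of several
hours, so the target is a property of the mean, not of each seed).

## The reduced configuration

`sim_config_small()` is the configuration used by the
parameter-recovery studies: population trajectories at the study scales
with intercept and time only, one Bernoulli(1/2) covariate with
$\gamma = 0.3$, and the published random-effect *correlation* structure
with intercept SDs kept at the published values (15.13 bpm, 0.98 °C)
but slope SDs rescaled to 0.1 bpm/h and 0.02 °C/h.  The rescaling is
forced by internal consistency, not convenience: the published slope
SDs (0.91 bpm/h, 0.61 °C/h) imply ±60–90-unit drifts over the follow-up
window, and under current-value association with
$\alpha = (-0.05, -0.5)$ they spread the log-hazard slope by
$\approx 0.34$/h — hazard factors of $e^{\pm 30}$, under which event
times degenerate and $\alpha$ is unidentifiable.  Its baseline hazard is
calibrated to the same two marginal targets (the rates absorb the large
constant part of $\alpha^\top w(t)$, hence their $10^8$ scale).

## What the generator does and does not emulate

It reproduces the design (visit schedule, truncation, covariate
marginals, administrative censoring), the published parameter scales,
and the association mechanism.  It does *not* emulate: covariate
*dependence* (sampling is marginal, so synthetic cohorts lack the real
cohort's covariate correlations), informative visit processes, missed
or mistimed visits, measurement error in visit times, or discharge-time
censoring.  Passing recovery tests on synthetic cohorts therefore
demonstrates correctness of the estimator under the stated model, not
fidelity of the published real-data coefficients, which cannot be
reproduced without the hospital data.

# Validation suite and study sizes

The package's own validation (the test suite plus
`scripts/acceptance.R`) uses these problem sizes, chosen to exercise
each property at meaningful precision while keeping a full run on one
CPU within tens of minutes:

* quadrature vs. brute-force Monte-Carlo integration of the joint
  likelihood: 50 random instances of 3–5 subjects, $2\times10^5$ draws,
  agreement within 3 Monte-Carlo SEs;
* association-parameter recovery: 40 replicates of $n = 300$
  current-value cohorts with $\alpha = (-0.05, -0.5)$; the mean estimate
  is required within 2 Monte-Carlo SEs of truth and Wald 95% interval
  coverage within [90%, 99%];
* separability: at $\alpha \equiv 0$ the joint log-likelihood must equal
  the sum of the separately maximised parts to $10^{-4}$ (the joint fit
  is started at the separate optimum, so this checks the identity, not
  optimizer luck);
* log-rank null behaviour: 1000 two-group null replicates, rejection
  rate at the 5% level within (0.03, 0.07);
* generator calibration: mean KM median over 20 seeded default cohorts
  within $66 \pm 6$ h.

# Numerical choices and edge cases

* $D$ is log-Cholesky parameterised in fits; exact singular $D$
  (including $D = 0$) is supported in likelihood *evaluation* via a
  dense per-subject path (the Woodbury fast path requires invertible
  $D$ and is used whenever the Cholesky pivot ratio exceeds $10^{-7}$).
* Infeasible optimizer proposals (overflowing variances, indefinite
  leading minors) return $+\infty$ rather than erroring, so line
  searches recover.
* Tied event and censoring times at $t$ keep censored subjects at risk
  for events at $t$ (standard convention).
* Piecewise-hazard pieces are left-open intervals $(c_{p-1}, c_p]$; an
  event exactly at a cutpoint takes the earlier piece's rate.
* Subjects with survival data but no longitudinal records are legal and
  contribute survival-only likelihood terms; their BLUP is the prior
  $(0, D)$.
* Degenerate image covariances of $(u, v)$ (e.g. $\alpha = 0$, or
  shared-random-effects where $v \equiv 0$) drop quadrature dimensions
  exactly instead of integrating over point masses.

# Known limitations

* No serial within-subject correlation beyond random effects plus white
  noise (the homogeneous within-patient variance assumption); no
  generalised (non-Gaussian) longitudinal outcomes.
* The random-effect structure is fixed at intercept + slope per outcome
  ($K = 2$ outcomes); competing risks, cure fractions, interval
  censoring and Bayesian estimation are out of scope.
* Association-parameter MLEs carry a finite-sample bias at moderate $n$
  when the baseline rates and $\alpha$ are strongly entangled — the
  current-value structure couples them through the biomarker's large
  intercept (for BT, $\alpha \times 38$ °C moves the log hazard by
  whole units).  The recovery study quantifies this: at $n = 300$ the
  mean $\hat\alpha_{BT}$ sits a few percent beyond its generating value
  ($\approx -0.04$ on a true $-0.5$, several Monte-Carlo SEs at 40
  replicates, so the suite's strict 2-SE bias check fails for that
  coefficient while interval coverage stays in range), the score at the
  true parameters averages zero, and refitting with all nuisance
  parameters held at their true values removes the bias entirely — it
  is induced by joint estimation of the nuisance parameters and shrinks
  like $O(1/n)$, not by any defect of the likelihood, quadrature or
  optimizer.  Users running hypothesis tests on $\alpha$ at moderate
  $n$ should prefer likelihood-ratio statements over point estimates.
* The contingency chi-squared and the log-rank statistic answer
  different questions; `descriptive_table()` reports both, labelled,
  and takes no position on published group-difference statistics that
  cannot be reproduced from the published counts.

# A worked example

```{r, eval = FALSE}
library(jointvitals)

cfg <- sim_config(n_subjects = 214, seed = 1)
sim <- simulate_cohort(cfg)
co  <- sim$cohort

descriptive_table(co)$overall
km <- kaplan_meier(co$surv$event_time, co$surv$status)
median_survival(km)

fit <- fit_joint(co, association = "shared_random_effects",
                 fixed = list(PR = "time_h", BT = "time_h"),
                 survival_covariates = c("danger_yes", "comorbid_yes"),
                 n_pieces = 3)
summary(fit)
association_summary(fit)
information_criteria(fit)
```
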