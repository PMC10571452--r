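test_that("random-effect draws honour D, including degenerate cases", {
  cfg <- sim_config(n_subjects = 10, seed = 1)

  cfg0 <- cfg; cfg0$D <- matrix(0, 4, 4)
  b0 <- simulate_random_effects(cfg0, 100)
  expect_true(all(b0 == 0))

  cfgI <- cfg; cfgI$D <- diag(4)
  set.seed(3)
  bI <- simulate_random_effects(cfgI, 50000)
  expect_true(all(abs(apply(bI, 2, var) - 1) < 0.03))

  # defaults carry the published cross-intercept covariance
  set.seed(4)
  bd <- simulate_random_effects(cfg, 50000)
  expect_lt(abs(cov(bd[, 1], bd[, 3]) - 12.852), 0.5)

  cfgN <- cfg; cfgN$D <- diag(c(-1, 1, 1, 1))
  expect_error(simulate_random_effects(cfgN, 10), "positive semi-definite")
})

test_that("noise-free trajectories equal the fixed-effect mean", {
  cfg <- sim_config(n_subjects = 5, design = toy_design(),
                    beta = list(PR = c(20, 1, -0.1), BT = c(5, 0.5, -0.02)),
                    D = matrix(0, 4, 4), sigma = c(0, 0),
                    gamma = c(group_b = 0), association = "current_value",
                    alpha = c(0, 0),
                    baseline = list(lam = 0.05, cut = numeric()), seed = 2)
  covs <- data.frame(group = c("a", "b", "a", "b", "a"))
  b <- matrix(0, 5, 4)
  tr <- simulate_trajectories(cfg, covs, b)
  grp <- as.numeric(covs$group == "b")[tr$subject]
  expected <- ifelse(tr$outcome == "PR",
                     20 + grp * 1 - 0.1 * tr$time,
                     5 + grp * 0.5 - 0.02 * tr$time)
  expect_equal(tr$y, expected)
  expect_equal(tr$w, expected)
  # default config: population mean visit-time slope is the published value
  expect_equal(unname(sim_config()$beta$PR["time_h"]), -0.4236)
})

test_that("with no association and no covariates event times are exponential", {
  lam <- 0.04
  cfg <- sim_config(n_subjects = 20000, design = toy_design(),
                    beta = list(PR = c(20, 0, -0.1), BT = c(5, 0, -0.02)),
                    sigma = c(1, 0.3), gamma = c(group_b = 0),
                    association = "current_value", alpha = c(0, 0),
                    baseline = list(lam = lam, cut = numeric()),
                    censor_time = 1e9, seed = 8)
  covs <- data.frame(group = rep("a", 20000))
  b <- simulate_random_effects(cfg, 20000)
  set.seed(9)
  ev <- simulate_event_time(cfg, covs, b, runif(20000))
  expect_true(all(ev$status == 1))
  se <- (1 / lam) / sqrt(20000)
  expect_lt(abs(mean(ev$time) - 1 / lam), 3 * se)
  expect_error(simulate_event_time(cfg, covs, b, c(0.5, rep(1.5, 19999))),
               "strictly in")
})

test_that("closed-form cumulative hazard matches adaptive quadrature", {
  set.seed(21)
  for (r in 1:100) {
    P <- sample(1:4, 1)
    cut <- if (P > 1) sort(runif(P - 1, 5, 95)) else numeric()
    lam <- runif(P, 0.001, 0.2)
    u <- runif(1, -2, 2); v <- runif(1, -0.05, 0.05)
    t <- runif(1, 1, 120)
    closed <- pw_cumhaz(t, u, v, lam, cut)
    # integrate each smooth piece separately: the integrand jumps at cutpoints
    lo <- c(0, cut); hi <- pmin(c(cut, Inf), t)
    num <- 0
    for (p in seq_along(lam))
      if (hi[p] > lo[p])
        num <- num + integrate(function(s) lam[p] * exp(u + v * s),
                               lo[p], hi[p], rel.tol = 1e-12)$value
    expect_lt(abs(closed - num) / max(num, 1e-12), 1e-8)
  }
})

test_that("cumulative-hazard inversion round-trips", {
  set.seed(22)
  lam <- c(0.02, 0.05, 0.2); cut <- c(30, 70)
  u <- rnorm(200, 0, 1); v <- runif(200, -0.02, 0.03)
  e <- -log(runif(200))
  Tt <- pw_invert(e, u, v, lam, cut)
  fin <- is.finite(Tt)
  expect_true(all(abs(pw_cumhaz(Tt[fin], u[fin], v[fin], lam, cut) - e[fin])
                  < 1e-8 * pmax(e[fin], 1)))
})

test_that("empirical survival of simulated event times matches S(t) = exp(-Lambda)", {
  cfg <- sim_config_small(n_subjects = 20000, seed = 31)
  covs <- data.frame(group = sample(c("a", "b"), 20000, TRUE))
  b <- simulate_random_effects(cfg, 20000)
  ev <- simulate_event_time(cfg, covs, b, runif(20000))
  # numeric-integration oracle for the same subjects
  Wenc <- jointvitals:::encode_covariates(cfg$design, covs)
  uv <- jointvitals:::assoc_uv(cfg, Wenc, b)
  grid <- seq(6, 102, by = 6)
  Strue <- vapply(grid, function(t) {
    mean(exp(-vapply(seq_len(2000), function(i)   # subsample for the integral
      integrate(function(s) jointvitals:::pw_rate(s, cfg$baseline$lam,
                                                  cfg$baseline$cut) *
                  exp(uv$u[i] + uv$v[i] * s), 0, t, rel.tol = 1e-9)$value, 0)))
  }, 0)
  Semp <- vapply(grid, function(t) mean(ev$latent[1:2000] > t), 0)
  expect_lt(max(abs(Semp - Strue)), 0.04)   # n = 2000 Monte-Carlo band
})

test_that("administrative censoring caps observed times and sets status", {
  sim <- simulate_cohort(sim_config(n_subjects = 200, seed = 13))
  expect_true(all(sim$cohort$surv$event_time <= 102))
  cens <- sim$cohort$surv$status == 0
  expect_true(all(sim$cohort$surv$event_time[cens] == 102))
})

test_that("cohorts are truncated, reproducible, and carry matching truth names", {
  cfg <- sim_config(n_subjects = 214, seed = 99)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  m <- match(co$long$subject_id, co$surv$subject_id)
  expect_true(all(co$long$time <= co$surv$event_time[m] + 1e-9))
  expect_true(all(co$long$time %in% seq(6, 102, by = 6)))
  nvis <- table(co$long$subject_id, co$long$outcome)
  expect_true(all(nvis <= 17))

  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$cohort$long, sim2$cohort$long)
  expect_identical(sim$cohort$surv, sim2$cohort$surv)
  expect_identical(sim$truth, sim2$truth)

  expect_error(simulate_cohort(
    structure(modifyList(cfg, list(visit_grid = numeric())),
              class = "sim_config")), "empty visit grid")
})

test_that("association sign drives the ranking of event times", {
  cfg <- sim_config_small(n_subjects = 2000, association = "shared_random_effects",
                          alpha = c(-2, -2))
  cfg$baseline <- list(lam = c(0.01, 0.02, 0.2), cut = c(48, 84))
  set.seed(41)
  covs <- data.frame(group = sample(c("a", "b"), 2000, TRUE))
  b <- simulate_random_effects(cfg, 2000)
  ev <- simulate_event_time(cfg, covs, b, runif(2000))
  # negative alpha: larger random slope -> lower hazard -> later event
  rc <- cor(b[, 2], ev$latent, method = "spearman")
  expect_gt(rc, 0.05)

  cfg$alpha <- c(0, 0)
  ev0 <- simulate_event_time(cfg, covs, b, runif(2000))
  rc0 <- cor(b[, 2], ev0$latent, method = "spearman")
  expect_lt(abs(rc0), 0.06)   # independence within MC error
})

test_that("measurement errors are Gaussian in nearly all seeded cohorts", {
  pass <- logical(100)
  for (s in 1:100) {
    cfg <- sim_config_small(n_subjects = 30, seed = 600 + s)
    covs <- data.frame(group = sample(c("a", "b"), 30, TRUE))
    b <- simulate_random_effects(cfg, 30)
    tr <- simulate_trajectories(cfg, covs, b)
    res <- tr$y - tr$w     # per outcome: the two residual scales differ
    p_k <- vapply(c("PR", "BT"), function(k) {
      rk <- res[tr$outcome == k]
      stats::shapiro.test(rk[seq_len(min(length(rk), 5000))])$p.value
    }, 0)
    pass[s] <- all(p_k > 0.01)
  }
  expect_gte(mean(pass), 0.95)
})
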