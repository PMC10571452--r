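test_that("marginal log-likelihood equals the dense MVN oracle", {
  sim <- toy_cohort(n = 3, seed = 20)
  co <- sim$cohort
  beta <- list(PR = c(19, 0.8, -0.09), BT = c(5.2, 0.4, -0.018))
  sig2 <- c(1.2, 0.09)
  D <- matrix(c(4, 0.1, 1, 0.05,
                0.1, 0.02, 0.05, 0.004,
                1, 0.05, 0.5, 0.01,
                0.05, 0.004, 0.01, 0.002), 4, 4)
  ll <- blmm_loglik(co, beta, sig2, D)
  expect_equal(as.numeric(ll), blmm_loglik_dense(co, beta, sig2, D),
               tolerance = 1e-10)

  # property: random parameter draws on random small cohorts
  set.seed(21)
  for (r in 1:20) {
    simr <- toy_cohort(n = sample(2:5, 1), seed = 100 + r, balanced = TRUE)
    A <- matrix(rnorm(16, sd = 0.5), 4, 4)
    Dr <- A %*% t(A) + diag(1e-4, 4)
    br <- list(PR = rnorm(3, c(20, 1, -0.1), 0.3),
               BT = rnorm(3, c(5, 0.5, -0.02), 0.1))
    s2 <- runif(2, 0.3, 2)
    expect_equal(as.numeric(blmm_loglik(simr$cohort, br, s2, Dr)),
                 blmm_loglik_dense(simr$cohort, br, s2, Dr),
                 tolerance = 1e-8)
  }
})

test_that("with D = 0 the likelihood separates into independent regressions", {
  sim <- toy_cohort(n = 4, seed = 23)
  co <- sim$cohort
  beta <- list(PR = c(20, 1, -0.1), BT = c(5, 0.5, -0.02))
  sig2 <- c(1.3, 0.2)
  ll <- as.numeric(blmm_loglik(co, beta, sig2, matrix(0, 4, 4)))
  des <- build_design(co)
  direct <- 0
  for (ki in 1:2) {
    k <- co$outcomes[ki]
    y <- co$long$value[co$long$outcome == k]
    mu <- drop(des$X[[k]] %*% beta[[k]])
    direct <- direct + sum(dnorm(y, mu, sqrt(sig2[ki]), log = TRUE))
  }
  expect_equal(ll, direct, tolerance = 1e-10)
})

test_that("a covariate entering with coefficient zero leaves the value unchanged", {
  sim <- toy_cohort(n = 4, seed = 24)
  co <- sim$cohort
  sig2 <- c(1, 0.1); D <- diag(c(2, 0.01, 0.5, 0.005))
  with_cov <- blmm_loglik(co, list(PR = c(20, 0, -0.1), BT = c(5, 0, -0.02)),
                          sig2, D)
  without <- blmm_loglik(co, list(PR = c(20, -0.1), BT = c(5, -0.02)),
                         sig2, D, fixed = list(PR = "time_h", BT = "time_h"))
  expect_equal(as.numeric(with_cov), as.numeric(without), tolerance = 1e-12)
})

test_that("ML fit recovers the generator and is order-invariant", {
  cfg <- sim_config_small(n_subjects = 150, seed = 30)
  sim <- simulate_cohort(cfg)
  fit <- fit_blmm(sim$cohort)
  expect_equal(fit$convergence, 0)
  expect_lt(abs(fit$beta["PR:time_h"] - (-0.4236)), 0.05)
  expect_lt(abs(fit$beta["BT:time_h"] - (-0.0119)), 0.01)
  expect_lt(abs(fit$sigma[1] - 3.674) / 3.674, 0.1)
  expect_lt(abs(fit$sigma[2] - 0.704) / 0.704, 0.1)

  # subject reordering leaves the estimates unchanged
  co2 <- sim$cohort
  set.seed(1)
  ord <- sample(nrow(co2$surv))
  co2 <- jointvitals:::new_cohort(co2$long, co2$surv[ord, ], co2$design)
  fit2 <- fit_blmm(co2)
  expect_equal(unname(fit2$beta), unname(fit$beta), tolerance = 1e-4)
  expect_equal(unclass(fit2$D), unclass(fit$D), tolerance = 5e-3)
})

test_that("the profile deviance is flat at the reported optimum", {
  sim <- simulate_cohort(sim_config_small(n_subjects = 80, seed = 31))
  fit <- fit_blmm(sim$cohort, fixed = list(PR = "time_h", BT = "time_h"))
  jd <- fit$jd
  fn <- function(theta) {
    par <- list(beta = numeric(4), sig2 = exp(theta[1:2]),
                D = jointvitals:::dpar_to_D(theta[3:12]),
                gamma = numeric(), alpha = numeric(), lam = 1)
    jointvitals:::jm_nll_cpp(jd, par, 0L, 1L, FALSE, TRUE, FALSE)$nll
  }
  g <- vapply(seq_along(fit$theta), function(j) {
    h <- 1e-5 * max(1, abs(fit$theta[j]))
    tp <- tm <- fit$theta; tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (fn(tp) - fn(tm)) / (2 * h)
  }, 0)
  # a raw gradient norm is meaningless on a surface with 1e8-scale curvature:
  # judge flatness by the attainable improvement (Newton decrement) instead
  H <- optimHess(fit$theta, fn)
  decrement <- drop(t(g) %*% solve(H, g)) / 2
  expect_lt(decrement / max(1, abs(fit$loglik)), 1e-4)
  # and no perturbation in any coordinate direction improves the deviance
  for (j in seq_along(fit$theta)) for (s in c(-1, 1)) {
    th <- fit$theta; th[j] <- th[j] + s * 0.05 * max(1, abs(th[j]))
    expect_gte(fn(th) + 1e-5, -fit$loglik)
  }
})

test_that("BLUPs shrink correctly across information regimes", {
  # subject with no longitudinal data gets the prior (0, D)
  sim <- toy_cohort(n = 5, seed = 33)
  co <- sim$cohort
  extra <- co$surv[1, ]; extra$subject_id <- "ZZZ"
  co2 <- jointvitals:::new_cohort(co$long, rbind(co$surv, extra), co$design)
  fit <- fit_blmm(co2, fixed = list(PR = "time_h", BT = "time_h"))
  bl <- blup(fit, "ZZZ")
  expect_equal(unname(bl$mean[1, ]), rep(0, 4))
  expect_equal(matrix(bl$var[1, ], 4), unclass(fit$D), ignore_attr = TRUE)

  # sigma -> 0: BLUP recovers each subject's true random effects
  cfg <- sim_config_small(n_subjects = 60, seed = 34)
  cfg$sigma <- c(0.01, 0.01)
  cfg$baseline <- list(lam = c(0.005, 0.01, 0.05), cut = c(48, 84))
  set.seed(35)
  covs <- data.frame(group = sample(c("a", "b"), 60, TRUE))
  b <- simulate_random_effects(cfg, 60)
  tr <- simulate_trajectories(cfg, covs, b)
  surv <- data.frame(subject_id = sprintf("S%04d", 1:60),
                     event_time = 102, status = 1,
                     group = covs$group, stringsAsFactors = FALSE)
  long <- data.frame(subject_id = sprintf("S%04d", tr$subject),
                     outcome = tr$outcome, time = tr$time, value = tr$y,
                     stringsAsFactors = FALSE)
  co3 <- jointvitals:::new_cohort(long, surv, cfg$design)
  fit3 <- fit_blmm(co3, fixed = list(PR = "time_h", BT = "time_h"))
  bl3 <- blup(fit3)
  # fixed-effect estimation error shifts every BLUP by the same offset;
  # the per-subject recovery is judged after removing it
  expect_lt(sd(bl3$mean[, "PR_slope"] - b[, 2]), 0.01)
  expect_lt(sd(bl3$mean[, "BT_slope"] - b[, 4]), 0.01)
  expect_lt(mean(abs(bl3$mean[, "PR_slope"] - b[, 2])), 0.05)
  expect_lt(mean(abs(bl3$mean[, "BT_slope"] - b[, 4])), 0.05)

  # shrinkage centring: BLUPs average to ~0 over a large cohort
  sim4 <- simulate_cohort(sim_config_small(n_subjects = 400, seed = 36))
  fit4 <- fit_blmm(sim4$cohort, fixed = list(PR = "time_h", BT = "time_h"))
  bl4 <- blup(fit4)
  expect_lt(max(abs(colMeans(bl4$mean)) /
                  pmax(sqrt(diag(unclass(fit4$D))), 0.01)), 0.15)
})

test_that("fitted, residuals and accessors are mutually consistent", {
  sim <- toy_cohort(n = 6, seed = 37)
  fit <- fit_blmm(sim$cohort)
  expect_equal(fitted(fit) + residuals(fit), fit$jd$y)
  rc <- residuals(fit, type = "conditional")
  expect_lt(sd(rc), sd(residuals(fit)))
  expect_equal(AIC(fit), -2 * fit$loglik + 2 * fit$df)
  s <- summary(fit)
  expect_true(all(s$fixed$PR$lower <= s$fixed$PR$estimate &
                    s$fixed$PR$estimate <= s$fixed$PR$upper))
})

test_that("interval coverage for fixed effects is near nominal", {
  hits <- 0; total <- 0
  for (r in 1:40) {
    sim <- simulate_cohort(sim_config_small(n_subjects = 60, seed = 700 + r))
    fit <- fit_blmm(sim$cohort, fixed = list(PR = "time_h", BT = "time_h"))
    truth <- c(117.92, -0.4236, 38.2809, -0.0119)
    z <- abs(fit$beta - truth) / fit$se_beta
    hits <- hits + sum(z <= qnorm(0.975)); total <- total + 4
  }
  expect_gte(hits / total, 0.85)
  expect_lte(hits / total, 1.0)
})
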