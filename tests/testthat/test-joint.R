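test_that("with alpha = 0 the joint likelihood separates exactly", {
  sim <- toy_cohort(n = 8, seed = 50)
  co <- sim$cohort
  beta <- list(PR = c(20, 1, -0.1), BT = c(5, 0.5, -0.02))
  sig2 <- c(1, 0.09)
  D <- diag(c(3, 0.02, 0.4, 0.004))
  gamma <- 0.3; lam <- c(0.01, 0.03); cut <- 24
  jl <- joint_loglik(co, beta, sig2, D, gamma, alpha = c(0, 0), lam, cut,
                     association = "current_value")
  ll_long <- as.numeric(blmm_loglik(co, beta, sig2, D))
  W <- build_design(co)$W
  eta <- drop(W %*% gamma)
  surv <- co$surv[match(rownames(W), co$surv$subject_id), ]
  ll_surv <- sum(surv$status * (log(jointvitals:::pw_rate(surv$event_time, lam, cut)) + eta)) -
    sum(exp(eta) * pw_cumhaz(surv$event_time, 0, 0, lam, cut))
  expect_equal(as.numeric(jl), ll_long + ll_surv, tolerance = 1e-6)
})

test_that("quadrature likelihood matches Monte-Carlo integration on toys", {
  set.seed(51)
  for (assoc in c("current_value", "current_value_and_slope",
                  "shared_random_effects")) {
    na <- jointvitals:::n_alpha_for(assoc)
    sim <- toy_cohort(n = 5, seed = 52, balanced = TRUE)
    co <- sim$cohort
    beta <- list(PR = c(20, 1, -0.1), BT = c(5, 0.5, -0.02))
    sig2 <- c(1, 0.09)
    D <- matrix(c(4, 0.1, 1, 0.05,
                  0.1, 0.02, 0.05, 0.004,
                  1, 0.05, 0.5, 0.01,
                  0.05, 0.004, 0.01, 0.002), 4, 4)
    alpha <- c(-0.04, -0.25, 0.1, 0.3)[seq_len(na)]
    gamma <- 0.25; lam <- c(0.02, 0.05); cut <- 24
    jl <- joint_loglik(co, beta, sig2, D, gamma, alpha, lam, cut,
                       association = assoc, nq = 9)
    mc <- joint_loglik_mc(co, beta, sig2, D, gamma, alpha, lam, cut,
                          association = assoc, B = 1e5, seed = 53)
    expect_lt(abs(as.numeric(jl) - mc$loglik), 3 * mc$se + 1e-6)
  }
})

test_that("the quadrature refines monotonically with the node count", {
  sim <- toy_cohort(n = 10, seed = 54)
  co <- sim$cohort
  args <- list(co, beta = list(PR = c(20, 1, -0.1), BT = c(5, 0.5, -0.02)),
               sig2 = c(1, 0.09),
               D = matrix(c(4, 0.1, 1, 0.05,
                            0.1, 0.02, 0.05, 0.004,
                            1, 0.05, 0.5, 0.01,
                            0.05, 0.004, 0.01, 0.002), 4, 4),
               gamma = 0.25, alpha = c(-0.04, -0.25), lam = c(0.02, 0.05),
               cut = 24, association = "current_value")
  lls <- vapply(c(5, 9, 15), function(nq)
    as.numeric(do.call(joint_loglik, c(args, nq = nq))), 0)
  expect_lt(abs(lls[3] - lls[2]), abs(lls[2] - lls[1]) + 1e-12)
  expect_lt(abs(lls[3] - lls[2]), 1e-4)
})

test_that("quadrature failures name the offending subject", {
  sim <- toy_cohort(n = 3, seed = 55)
  expect_error(
    joint_loglik(sim$cohort, beta = list(PR = c(2000, 1, -0.1), BT = c(5, 0.5, -0.02)),
                 sig2 = c(1, 0.09), D = diag(c(4, 0.02, 0.5, 0.002)),
                 gamma = 0.25, alpha = c(5, 0), lam = c(0.02, 0.05), cut = 24,
                 association = "current_value"),
    "subject")
})

test_that("fixing alpha at zero reproduces the separate fits", {
  sim <- simulate_cohort(sim_config_small(n_subjects = 100, seed = 56))
  co <- sim$cohort
  jfit <- fit_joint(co, association = "current_value",
                    fixed = list(PR = "time_h", BT = "time_h"),
                    cut = c(48, 84), fix_alpha = c(0, 0), se = FALSE)
  bfit <- fit_blmm(co, fixed = list(PR = "time_h", BT = "time_h"))
  W <- build_design(co)$W
  pfit <- fit_pwexp(co$surv$event_time, co$surv$status, W, cut = c(48, 84))
  expect_equal(jfit$loglik, bfit$loglik + pfit$loglik, tolerance = 1e-4)
  expect_equal(unname(jfit$beta), unname(bfit$beta), tolerance = 1e-3)
  expect_equal(unname(jfit$gamma), unname(pfit$gamma), tolerance = 1e-3)
})

test_that("joint estimates carry the same names as the generator truth", {
  cfg <- sim_config_small(n_subjects = 60, seed = 57)
  sim <- simulate_cohort(cfg)
  fit <- fit_joint(sim$cohort, association = "current_value",
                   cut = cfg$baseline$cut, se = FALSE,
                   control = list(maxit = 5))    # name layout only
  expect_setequal(names(fit$estimates), names(sim$truth))
})

test_that("association summary and information criteria are self-consistent", {
  sim <- simulate_cohort(sim_config_small(n_subjects = 120, seed = 58))
  fit <- fit_joint(sim$cohort, association = "current_value",
                   fixed = list(PR = "time_h", BT = "time_h"), cut = c(48, 84))
  as_ <- association_summary(fit)
  expect_equal(as_$hr, exp(as_$estimate))
  expect_equal(as_$hr_lower, exp(as_$lower))
  expect_true(all(as_$lower <= as_$estimate & as_$estimate <= as_$upper))

  ic <- information_criteria(fit)
  tot <- ic[ic$part == "total", ]
  parts <- ic[ic$part != "total", ]
  expect_equal(sum(parts$m2ll), tot$m2ll, tolerance = 1e-8)
  expect_equal(sum(parts$AIC), tot$AIC, tolerance = 1e-8)
  expect_equal(sum(parts$BIC), tot$BIC, tolerance = 1e-8)
  expect_equal(tot$AIC, -2 * fit$loglik + 2 * fit$df)
  expect_equal(tot$BIC, -2 * fit$loglik + fit$df * log(fit$n_subjects))

  # nesting: freeing alpha can only improve the maximised likelihood
  fit0 <- fit_joint(sim$cohort, association = "current_value",
                    fixed = list(PR = "time_h", BT = "time_h"),
                    cut = c(48, 84), fix_alpha = c(0, 0), se = FALSE)
  expect_gte(fit$loglik + 1e-6, fit0$loglik)
})

test_that("dynamic predictions behave like conditional survival probabilities", {
  sim <- simulate_cohort(sim_config_small(n_subjects = 120, seed = 59))
  fit <- fit_joint(sim$cohort, association = "current_value",
                   fixed = list(PR = "time_h", BT = "time_h"), cut = c(48, 84),
                   se = FALSE)
  id <- fit$jd$subjects[which(fit$jd$Tv > 60)[1]]
  ps <- conditional_survival(fit, id, t = 36, horizon = c(0, 6, 12, 24, 48))
  expect_equal(ps$prob[1], 1)
  expect_true(all(diff(ps$prob) <= 1e-12))
  expect_true(all(ps$prob >= 0 & ps$prob <= 1))
  expect_error(conditional_survival(fit, id, 36, -1), "nonnegative")

  # alpha = 0: prediction equals the marginal piecewise-exponential ratio
  fit0 <- fit_joint(sim$cohort, association = "current_value",
                    fixed = list(PR = "time_h", BT = "time_h"),
                    cut = c(48, 84), fix_alpha = c(0, 0), se = FALSE)
  ps0 <- conditional_survival(fit0, id, t = 36, horizon = c(6, 24))
  W <- fit0$jd$W[match(id, fit0$jd$subjects), , drop = FALSE]
  eta <- drop(W %*% fit0$gamma)
  L <- function(t) pw_cumhaz(t, eta, 0, fit0$lam, fit0$cut)
  expect_equal(ps0$prob, exp(-(L(36 + c(6, 24)) - L(36))), tolerance = 1e-6)
})

test_that("simulate() on a full-design fit returns parametric replicates", {
  sim <- simulate_cohort(sim_config_small(n_subjects = 60, seed = 61))
  fit <- fit_joint(sim$cohort, association = "current_value",
                   cut = c(48, 84), se = FALSE)
  reps <- simulate(fit, nsim = 2, seed = 62)
  expect_length(reps, 2)
  expect_s3_class(reps[[1]]$cohort, "cohort")
  expect_equal(nrow(reps[[1]]$cohort$surv), 60)
  expect_setequal(names(reps[[1]]$truth), names(fit$estimates))
})
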