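#' Joint log-likelihood of the bivariate longitudinal and survival model
#'
#' Evaluates, at a given parameter set, the marginal joint log-likelihood
#' \deqn{\sum_i \log \int \Big[\prod_{k,j} N(y_{ikj};\,x^\top\beta_k +
#'   z^\top b_{ik}, \sigma_k^2)\Big]\, h_i(T_i|b)^{\delta_i}
#'   e^{-\Lambda_i(T_i|b)}\, N(b; 0, D)\, db}
#' with the hazard \eqn{h_i(t|b) = \lambda_0(t) \exp(\gamma^\top w_i +
#' \mathrm{assoc}_i(b, t))}.  The Gaussian longitudinal factor integrates
#' in closed form; the survival factor, whose log is linear in b in every
#' supported association structure, is integrated by adaptive
#' Gauss-Hermite quadrature centred at the longitudinal posterior of the
#' random effects (an exact dimension reduction of the 4-dim integral to
#' at most 2 dimensions).  Censored subjects contribute survival-only
#' terms.
#'
#' @param cohort a cohort object.
#' @param beta named list of per-outcome fixed-effect vectors, or a single
#'   stacked vector (design-column order).
#' @param sig2 residual variances (length 2).
#' @param D 4x4 random-effects covariance.
#' @param gamma survival coefficients (one per survival design column).
#' @param alpha association coefficients (length by structure).
#' @param lam,cut piecewise-constant baseline rates and interior cutpoints.
#' @param association association structure label.
#' @param fixed optional per-outcome design-column subsets.
#' @param nq Gauss-Hermite nodes per dimension (>= 3).
#' @return log-likelihood (scalar) with attributes `"ll_long"` and
#'   `"ll_surv"` holding per-subject contributions.
#' @export
joint_loglik <- function(cohort, beta, sig2, D, gamma, alpha, lam,
                         cut = numeric(),
                         association = c("current_value",
                                         "current_value_and_slope",
                                         "shared_random_effects"),
                         fixed = NULL, nq = 7L) {
  association <- match.arg(association)
  stopifnot(nq >= 3L)
  jd <- prepare_jdata(cohort, fixed = fixed, cut = cut, nq = nq)
  jd$cut <- as.numeric(cut)
  b <- if (is.list(beta)) unlist(beta, use.names = FALSE) else as.numeric(beta)
  if (length(b) != jd$p1 + jd$p2)
    stop("beta has length ", length(b), ", expected ", jd$p1 + jd$p2)
  if (length(gamma) != ncol(jd$W))
    stop("gamma must have ", ncol(jd$W), " entries")
  check_D(D)
  stopifnot(length(lam) == length(cut) + 1L, all(lam > 0))
  acode <- assoc_code(association)
  if (length(alpha) != n_alpha_for(association))
    stop("alpha must have ", n_alpha_for(association), " entries for ",
         association)
  res <- jm_nll_cpp(jd, list(beta = b, sig2 = sig2, D = unname(as.matrix(D)),
                             gamma = as.numeric(gamma),
                             alpha = as.numeric(alpha), lam = as.numeric(lam)),
                    acode, nq, TRUE, FALSE, FALSE)
  if (any(!is.finite(res$ll_surv)))
    stop("non-finite quadrature for subject(s): ",
         paste(jd$subjects[!is.finite(res$ll_surv)], collapse = ", "))
  structure(-res$nll, ll_long = res$ll_long, ll_surv = res$ll_surv)
}

assoc_code <- function(association) {
  switch(association, none = 0L, current_value = 1L,
         current_value_and_slope = 2L, shared_random_effects = 3L)
}

#' Fit the joint model by maximum likelihood
#'
#' Simultaneous estimation of the bivariate linear mixed sub-model and the
#' piecewise-constant-baseline proportional-hazards sub-model linked by
#' the chosen association structure:
#' * `"current_value"`: log-hazard term \eqn{\alpha_1 w_{PR}(t) + \alpha_2
#'   w_{BT}(t)} (true, noise-free biomarker levels);
#' * `"current_value_and_slope"`: adds \eqn{\alpha_3 w'_{PR} + \alpha_4
#'   w'_{BT}} (subject-specific trajectory slopes);
#' * `"shared_random_effects"`: \eqn{\alpha_1 b_{PR,slope} + \alpha_2
#'   b_{BT,slope}} (random slopes enter the hazard directly).
#'
#' The quadrature likelihood (see [joint_loglik()]) is maximised by BFGS
#' from separate-fit starting values (profiled bivariate LMM; Poisson-trick
#' piecewise-exponential PH fit) with association coefficients started at
#' zero.  The random-effects covariance is log-Cholesky parameterised and
#' the fit is deterministic given data and settings.  Standard errors come
#' from the inverse numerical observed information; a non-positive-definite
#' Hessian or non-convergence is flagged in `$flags`, not raised.
#'
#' @param cohort a cohort object.
#' @param association association structure (see above).
#' @param fixed optional named per-outcome list of design columns for the
#'   longitudinal means.
#' @param survival_covariates optional subset of survival design columns.
#' @param cut interior cutpoints of the baseline hazard; default
#'   `n_pieces` pieces at event-time quantiles.
#' @param n_pieces number of baseline-hazard pieces when `cut` is `NULL`.
#' @param nq Gauss-Hermite nodes per dimension (default 7).
#' @param fix_alpha optional numeric vector: hold the association
#'   coefficients fixed at these values (e.g. 0 for a no-association fit).
#' @param se compute standard errors (default TRUE).
#' @param init optional list of starting values (`beta`, `sig2`, `D`,
#'   `gamma`, `alpha`, `lam`).
#' @param control optimizer settings: `maxit` (default 500), `reltol`
#'   (default 1e-9).
#' @return an object of class `jointfit`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_subjects = 80, seed = 7)
#' co <- simulate_cohort(cfg)$cohort
#' fit <- fit_joint(co, association = "shared_random_effects",
#'                  fixed = list(PR = "time_h", BT = "time_h"),
#'                  survival_covariates = "danger_yes", n_pieces = 3)
#' summary(fit)
#' }
#' @export
fit_joint <- function(cohort,
                      association = c("current_value",
                                      "current_value_and_slope",
                                      "shared_random_effects"),
                      fixed = NULL, survival_covariates = NULL,
                      cut = NULL, n_pieces = 5L, nq = 7L,
                      fix_alpha = NULL, se = TRUE, init = NULL,
                      control = list()) {
  association <- match.arg(association)
  ctl <- modifyList(list(maxit = 500L, reltol = 1e-9), control)
  stopifnot(nq >= 3L, n_pieces >= 1L)
  jd <- prepare_jdata(cohort, fixed = fixed, cut = cut, n_pieces = n_pieces,
                      nq = nq)
  if (!is.null(survival_covariates)) {
    miss <- setdiff(survival_covariates, jd$wnames)
    if (length(miss)) stop("unknown survival design column(s): ",
                           paste(miss, collapse = ", "))
    jd$W <- jd$W[, survival_covariates, drop = FALSE]
    jd$wnames <- survival_covariates
  }
  n <- length(jd$subjects)
  if (n < 20L) warning("fewer than 20 subjects; joint fit may be unstable")
  p <- jd$p1 + jd$p2; q <- ncol(jd$W); P <- length(jd$cut) + 1L
  acode <- assoc_code(association)
  na <- n_alpha_for(association)
  alpha_fixed <- !is.null(fix_alpha)
  if (alpha_fixed && length(fix_alpha) != na)
    stop("fix_alpha must have length ", na)

  ## starting values from separate fits
  if (is.null(init)) {
    bl <- fit_blmm(cohort, fixed = fixed)
    pw <- fit_pwexp(jd$Tv, jd$delta, if (q > 0) jd$W else NULL, cut = jd$cut)
    init <- list(beta = unname(bl$beta), sig2 = unname(bl$sig2),
                 D = unclass(bl$D), gamma = unname(pw$gamma),
                 alpha = if (alpha_fixed) fix_alpha else numeric(na),
                 lam = pw$lam)
  }
  theta0 <- c(init$beta, log(init$sig2), D_to_dpar(init$D), init$gamma,
              if (!alpha_fixed) init$alpha, log(init$lam))

  build_par <- function(theta) {
    i <- 0L
    beta <- theta[i + seq_len(p)]; i <- i + p
    sig2 <- exp(theta[i + 1:2]); i <- i + 2L
    D <- dpar_to_D(theta[i + 1:10]); i <- i + 10L
    gamma <- if (q > 0) theta[i + seq_len(q)] else numeric(); i <- i + q
    alpha <- if (alpha_fixed) fix_alpha else theta[i + seq_len(na)]
    if (!alpha_fixed) i <- i + na
    lam <- exp(theta[i + seq_len(P)])
    list(beta = beta, sig2 = sig2, D = D, gamma = gamma, alpha = alpha,
         lam = lam)
  }
  fn <- function(theta) {
    v <- jm_nll_cpp(jd, build_par(theta), acode, nq, TRUE, FALSE, FALSE)$nll
    if (!is.finite(v)) 1e10 else v      # keep finite for BFGS line searches
  }

  opt <- optim(theta0, fn, method = "BFGS",
               control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  flags <- character()
  if (opt$convergence != 0)
    flags <- c(flags, paste0("optimizer convergence code ", opt$convergence))

  par_hat <- build_par(opt$par)
  details <- jm_nll_cpp(jd, par_hat, acode, nq, TRUE, FALSE, TRUE)

  free_names <- c(jd$pnames, paste0("log_sigma2_", jd$outcomes),
                  paste0("dpar", 1:10),
                  if (q > 0) paste0("gamma:", jd$wnames),
                  if (!alpha_fixed) alpha_names(jd$outcomes, association),
                  paste0("log_lambda", seq_len(P)))

  vcov_free <- matrix(NA_real_, length(theta0), length(theta0),
                      dimnames = list(free_names, free_names))
  if (se) {
    H <- tryCatch(optimHess(opt$par, fn), error = function(e) NULL)
    Vf <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    if (is.null(Vf) || any(!is.finite(diag(Vf))) || any(diag(Vf) < 0)) {
      flags <- c(flags, "observed information not positive definite; SEs unreliable")
      if (!is.null(Vf)) vcov_free[] <- Vf
    } else vcov_free[] <- Vf
  }

  ## natural-scale estimates and delta-method covariance
  nat_of <- function(theta) {
    pp <- build_par(theta)
    natural_vector(pp$beta, pp$sig2, pp$D, pp$gamma, pp$alpha, pp$lam,
                   jd$pnames, jd$outcomes, jd$wnames, association)
  }
  est <- nat_of(opt$par)
  se_nat <- rep(NA_real_, length(est)); names(se_nat) <- names(est)
  vcov_nat <- matrix(NA_real_, length(est), length(est),
                     dimnames = list(names(est), names(est)))
  if (se && all(is.finite(diag(vcov_free)))) {
    J <- num_jacobian(nat_of, opt$par)
    vcov_nat[] <- J %*% vcov_free %*% t(J)
    se_nat <- sqrt(pmax(diag(vcov_nat), 0))
    if (alpha_fixed) se_nat[alpha_names(jd$outcomes, association)] <- NA_real_
  }
  z <- qnorm(0.975)

  renames <- paste(rep(jd$outcomes, each = 2), c("int", "slope"), sep = "_")
  D <- par_hat$D; dimnames(D) <- list(renames, renames)
  beta <- setNames(par_hat$beta, jd$pnames)

  structure(list(
    estimates = est, se = se_nat,
    lower = est - z * se_nat, upper = est + z * se_nat,
    p = 2 * pnorm(-abs(est / se_nat)),
    beta = beta,
    coefficients = split(beta, rep(jd$outcomes, c(jd$p1, jd$p2))),
    sig2 = setNames(par_hat$sig2, jd$outcomes),
    sigma = setNames(sqrt(par_hat$sig2), jd$outcomes),
    D = D, gamma = setNames(par_hat$gamma, jd$wnames),
    alpha = setNames(par_hat$alpha, alpha_names(jd$outcomes, association)),
    lam = par_hat$lam, cut = jd$cut, association = association,
    loglik = -opt$value, df = length(theta0),
    df_long = p + 12L, df_surv = q + (if (alpha_fixed) 0L else na) + P,
    ll_long = details$ll_long, ll_surv = details$ll_surv,
    post_mean = details$post_mean, post_var = details$post_var,
    n_subjects = n, n_obs = length(jd$y), n_events = sum(jd$delta),
    convergence = opt$convergence, counts = opt$counts, flags = flags,
    vcov = vcov_nat, vcov_free = vcov_free, par_free = setNames(opt$par, free_names),
    fix_alpha = fix_alpha, nq = nq, jd = jd, cohort = cohort,
    call = match.call()
  ), class = "jointfit")
}

## central-difference Jacobian of vector-valued f at x ----------------------
num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

## per-subject log-hazard intercept/slope at a random-effect value ---------
jd_uv <- function(jd, beta, gamma, alpha, acode, b) {
  f1 <- drop(jd$Xs1 %*% beta); f2 <- drop(jd$Xs2 %*% beta)
  g1 <- beta[jd$tc1]; g2 <- beta[jd$tc2]
  gw <- if (ncol(jd$W) > 0) drop(jd$W %*% gamma) else numeric(nrow(jd$Xs1))
  if (acode == 1L) {
    u <- gw + alpha[1] * (f1 + b[, 1]) + alpha[2] * (f2 + b[, 3])
    v <- alpha[1] * (g1 + b[, 2]) + alpha[2] * (g2 + b[, 4])
  } else if (acode == 2L) {
    u <- gw + alpha[1] * (f1 + b[, 1]) + alpha[2] * (f2 + b[, 3]) +
      alpha[3] * (g1 + b[, 2]) + alpha[4] * (g2 + b[, 4])
    v <- alpha[1] * (g1 + b[, 2]) + alpha[2] * (g2 + b[, 4])
  } else if (acode == 3L) {
    u <- gw + alpha[1] * b[, 2] + alpha[2] * b[, 4]
    v <- rep(0, length(u))
  } else {
    u <- gw; v <- rep(0, length(u))
  }
  # u inherits length n from the design; v can collapse to a scalar when b
  # has one row (all terms scalar) -- keep the two aligned
  list(u = u, v = rep_len(v, length(u)))
}

#' @export
print.jointfit <- function(x, digits = 4, ...) {
  cat("Joint model fit (", x$association, " association)\n", sep = "")
  cat("  subjects:", x$n_subjects, " events:", x$n_events,
      " longitudinal obs:", x$n_obs, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 9),
      "  AIC:", format(-2 * x$loglik + 2 * x$df, digits = 9), "\n")
  cat("Association:\n")
  print(association_summary(x), digits = digits)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tabulated summary of a joint-model fit
#'
#' Longitudinal fixed-effect blocks per outcome (estimate, 95% CI, SE,
#' p-value), the survival block (coefficients with hazard ratios), the
#' association block, variance components, and information criteria --
#' laid out the way joint-model results tables are usually printed,
#' with 4-decimal formatting.
#'
#' @param object a `jointfit`.
#' @param ... unused.
#' @export
summary.jointfit <- function(object, ...) {
  nm <- names(object$estimates)
  block <- function(keep) data.frame(
    term = nm[keep], estimate = object$estimates[keep], se = object$se[keep],
    lower = object$lower[keep], upper = object$upper[keep],
    p = object$p[keep], row.names = NULL)
  long <- lapply(object$jd$outcomes, function(k)
    block(grepl(paste0("^", k, ":"), nm)))
  names(long) <- object$jd$outcomes
  surv <- block(grepl("^gamma:", nm))
  if (nrow(surv)) surv$hr <- exp(surv$estimate)
  structure(list(
    longitudinal = long, survival = surv,
    association = association_summary(object),
    D = object$D, sigma = object$sigma,
    criteria = information_criteria(object),
    loglik = object$loglik, flags = object$flags
  ), class = "summary.jointfit")
}

#' @export
print.summary.jointfit <- function(x, digits = 4, ...) {
  for (k in names(x$longitudinal)) {
    cat("Longitudinal sub-model,", k, ":\n")
    print(format_fit_table(x$longitudinal[[k]], digits))
    cat("\n")
  }
  cat("Survival sub-model:\n")
  print(format_fit_table(x$survival, digits))
  cat("\nAssociation:\n")
  print(format_fit_table(x$association, digits))
  cat("\nRandom-effects covariance:\n")
  print(round(x$D, digits))
  cat("Residual SD:", paste(names(x$sigma), round(x$sigma, digits),
                            collapse = ", "), "\n")
  cat("\n")
  print(x$criteria)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.jointfit <- function(object, ...) {
  c(object$coefficients,
    list(gamma = object$gamma, alpha = object$alpha))
}

#' @export
logLik.jointfit <- function(object, ...) {
  structure(object$loglik, df = object$df,
            nobs = object$n_subjects, class = "logLik")
}

#' @export
vcov.jointfit <- function(object, ...) object$vcov

#' Association coefficients with hazard ratios
#'
#' One row per association coefficient: estimate, SE, Wald 95% CI, the
#' hazard ratio `exp(coef)` with its exponentiated CI, the percent change
#' in the recovery hazard, and the p-value.
#'
#' @param fit a `jointfit`.
#' @return data frame.
#' @export
association_summary <- function(fit) {
  stopifnot(inherits(fit, "jointfit"))
  an <- names(fit$alpha)
  est <- fit$estimates[an]; se <- fit$se[an]
  hrt <- hazard_ratio(unname(est))
  data.frame(term = an, estimate = unname(est), se = unname(se),
             lower = unname(fit$lower[an]), upper = unname(fit$upper[an]),
             hr = hrt$hr, hr_lower = exp(unname(fit$lower[an])),
             hr_upper = exp(unname(fit$upper[an])),
             percent_change = hrt$percent_change,
             p = unname(fit$p[an]), row.names = NULL)
}

#' Information criteria with a conditional decomposition
#'
#' Total `AIC = -2 loglik + 2 p` and `BIC = -2 loglik + p log(n_subjects)`
#' for the joint fit, split into a survival part -- based on the
#' conditional survival log-likelihood evaluated at the empirical Bayes
#' random-effect estimates (BLUPs) -- and a longitudinal part defined as
#' the remainder, so that the two parts sum to the total by construction.
#' The parameter penalty is split by sub-model (longitudinal: fixed
#' effects + variance components; survival: baseline rates, covariate and
#' association coefficients).
#'
#' @param fit a `jointfit`.
#' @return object of class `ic_decomposition`: data frame with rows
#'   `total`, `longitudinal`, `survival` and columns `m2ll`, `df`, `AIC`,
#'   `BIC`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "jointfit"))
  jd <- fit$jd
  acode <- assoc_code(fit$association)
  uv <- jd_uv(jd, unname(fit$beta), unname(fit$gamma), unname(fit$alpha),
              acode, fit$post_mean)
  ll_surv_cond <- jd$delta * (log(pw_rate(jd$Tv, fit$lam, fit$cut)) +
                                uv$u + uv$v * jd$Tv) -
    pw_cumhaz(jd$Tv, uv$u, uv$v, fit$lam, fit$cut)
  m2ll_total <- -2 * fit$loglik
  m2ll_surv <- -2 * sum(ll_surv_cond)
  m2ll_long <- m2ll_total - m2ll_surv
  N <- fit$n_subjects
  df <- c(fit$df, fit$df_long, fit$df_surv)
  m2 <- c(m2ll_total, m2ll_long, m2ll_surv)
  out <- data.frame(part = c("total", "longitudinal", "survival"),
                    m2ll = m2, df = df,
                    AIC = m2 + 2 * df, BIC = m2 + df * log(N),
                    row.names = NULL)
  class(out) <- c("ic_decomposition", "data.frame")
  out
}

#' Dynamic conditional survival prediction
#'
#' Empirical Bayes plug-in prediction
#' \eqn{P(T \ge t + \Delta \mid T \ge t, \mathcal{Y}_i(t))}: the posterior
#' mode of the subject's random effects given their longitudinal history
#' up to t and survival to t, then the ratio of plug-in survival
#' functions \eqn{\exp\{-[\Lambda(t+\Delta|\hat b) - \Lambda(t|\hat b)]\}}.
#'
#' @param fit a `jointfit`.
#' @param subject subject id present in the fitted cohort.
#' @param t landmark time (hours); history is truncated at t.
#' @param horizon nonnegative prediction horizons (hours beyond t).
#' @return data frame with `horizon` and `prob` (nonincreasing in the
#'   horizon; `prob = 1` at horizon 0).
#' @export
conditional_survival <- function(fit, subject, t, horizon) {
  stopifnot(inherits(fit, "jointfit"))
  if (any(horizon < 0)) stop("horizon must be nonnegative")
  jd <- fit$jd
  i <- match(as.character(subject), jd$subjects)
  if (is.na(i)) stop("unknown subject: ", subject)
  acode <- assoc_code(fit$association)
  beta <- unname(fit$beta); D <- unclass(fit$D); sig2 <- unname(fit$sig2)

  ## longitudinal history up to the landmark
  rows <- integer()
  if (jd$long_start[i] > 0) {
    rows <- seq(jd$long_start[i], jd$long_end[i])
    rows <- rows[jd$t[rows] <= t + 1e-9]
  }
  neg_post <- function(b) {
    bmat <- matrix(b, 1L)
    uv <- jd_uv(jd, beta, unname(fit$gamma), unname(fit$alpha), acode, bmat)
    lp <- -0.5 * drop(b %*% solve(D + diag(1e-10, 4)) %*% b)
    if (length(rows)) {
      kk <- jd$k[rows]
      mu <- drop(jd$X[rows, , drop = FALSE] %*% beta) +
        b[2 * (kk - 1) + 1] + b[2 * (kk - 1) + 2] * jd$t[rows]
      lp <- lp + sum(dnorm(jd$y[rows], mu, sqrt(sig2[kk]), log = TRUE))
    }
    lp <- lp - pw_cumhaz(t, uv$u[i], uv$v[i], fit$lam, fit$cut)
    if (!is.finite(lp)) 1e10 else -lp
  }
  bhat <- optim(fit$post_mean[i, ], neg_post, method = "BFGS")$par
  uv <- jd_uv(jd, beta, unname(fit$gamma), unname(fit$alpha), acode,
              matrix(bhat, 1L))
  L0 <- pw_cumhaz(t, uv$u[i], uv$v[i], fit$lam, fit$cut)
  Lh <- pw_cumhaz(t + horizon, rep(uv$u[i], length(horizon)),
                  rep(uv$v[i], length(horizon)), fit$lam, fit$cut)
  data.frame(horizon = horizon, prob = exp(-(Lh - L0)))
}

#' Simulate cohorts from a fitted joint model
#'
#' Parametric-bootstrap style simulation: new random effects, measurement
#' errors and recovery times are drawn from the fitted parameters,
#' conditional on the observed baseline covariates.  Only available for
#' fits that used the full longitudinal and survival design.
#'
#' @param object a `jointfit`.
#' @param nsim number of cohorts.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `simulate_cohort()` results, one per replicate.
#' @export
simulate.jointfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  design <- object$cohort$design
  if (length(object$beta) != 2 * length(design$x_cols) ||
      length(object$gamma) != length(design$w_cols))
    stop("simulate() needs a fit with the full longitudinal and survival design")
  outc <- object$jd$outcomes
  beta <- lapply(outc, function(k)
    setNames(unname(object$coefficients[[k]]), design$x_cols))
  names(beta) <- outc
  cfg <- sim_config(
    n_subjects = object$n_subjects, design = design, beta = beta,
    D = unclass(object$D), sigma = unname(object$sigma),
    gamma = setNames(unname(object$gamma), design$w_cols),
    association = object$association, alpha = unname(object$alpha),
    baseline = list(lam = object$lam, cut = object$cut))
  covs <- object$cohort$surv[names(design$covariates)]
  lapply(seq_len(nsim), function(s) simulate_cohort(cfg, covariates = covs))
}
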