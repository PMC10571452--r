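#' Log-likelihood of the bivariate linear mixed model
#'
#' Evaluates the exact marginal Gaussian log-likelihood
#' \deqn{\sum_i \log N(y_i;\, X_i\beta,\; Z_i D Z_i^\top + R_i)}
#' where \eqn{y_i} stacks both outcomes' measurements for subject i,
#' \eqn{Z_i} holds random intercepts and slopes per outcome, \eqn{D} is the
#' 4x4 random-effects covariance (order: PR intercept, PR slope, BT
#' intercept, BT slope) and \eqn{R_i} is diagonal with the outcome-specific
#' residual variances.  Computed stably via per-subject Cholesky
#' factorisation.
#'
#' @param cohort a cohort object.
#' @param beta named list with one fixed-effect vector per outcome (in the
#'   column order of [build_design()]), or a single stacked vector.
#' @param sig2 length-2 vector of residual variances.
#' @param D 4x4 random-effects covariance (symmetric PSD).
#' @param fixed optional named list of design-column subsets per outcome.
#' @return the log-likelihood (scalar) with attribute `"subject"` holding
#'   per-subject contributions.
#' @export
blmm_loglik <- function(cohort, beta, sig2, D, fixed = NULL) {
  jd <- prepare_jdata(cohort, fixed = fixed)
  b <- if (is.list(beta)) unlist(beta, use.names = FALSE) else as.numeric(beta)
  if (length(b) != jd$p1 + jd$p2)
    stop("beta has length ", length(b), ", expected ", jd$p1 + jd$p2)
  check_D(D)
  res <- jm_nll_cpp(jd, list(beta = b, sig2 = sig2, D = D,
                             gamma = numeric(), alpha = numeric(), lam = 1),
                    0L, 1L, FALSE, FALSE, FALSE)
  structure(-res$nll, subject = res$ll_long)
}

check_D <- function(D) {
  stopifnot(is.matrix(D), all(dim(D) == 4L))
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("D must be positive semi-definite")
  invisible(TRUE)
}

#' Fit the bivariate linear mixed model by maximum likelihood
#'
#' Correlated random intercepts and slopes across the two outcomes (full
#' 4x4 covariance `D`, log-Cholesky parameterised so positive
#' semi-definiteness holds by construction), outcome-specific residual
#' variances, and per-outcome fixed effects (intercept, baseline covariate
#' indicators, visit time).  The fixed effects are profiled out by
#' generalised least squares at each variance-parameter value, and the
#' 12-dimensional profile deviance is minimised by `nlminb` from
#' least-squares-based starting values.  Estimation is by ML (not REML) so
#' the fit is directly comparable with, and nested in, the joint model.
#'
#' @param cohort a cohort object.
#' @param fixed optional named list (per outcome) of design columns to keep
#'   in the mean model; default uses every available column.
#' @param control list: `maxit` (default 500), `reltol` (default 1e-12).
#' @return an object of class `blmm`; see [summary.blmm()].  Non-convergence
#'   is flagged in `$convergence`, not raised.
#' @examples
#' cfg <- sim_config(n_subjects = 60, seed = 1)
#' co <- simulate_cohort(cfg)$cohort
#' fit <- fit_blmm(co, fixed = list(PR = "time_h", BT = "time_h"))
#' fit
#' @export
fit_blmm <- function(cohort, fixed = NULL, control = list()) {
  ctl <- modifyList(list(maxit = 500L, reltol = 1e-12), control)
  jd <- prepare_jdata(cohort, fixed = fixed)
  p <- jd$p1 + jd$p2
  empty_sv <- list(gamma = numeric(), alpha = numeric(), lam = 1)

  # starting values from per-subject least-squares lines: pooled residual
  # variance estimates sigma_k^2, the spread of the per-subject coefficients
  # estimates the diagonal of D
  init <- blmm_start(jd)
  theta0 <- c(log(init$sig2), D_to_dpar(diag(init$dvar)))

  fn <- function(theta) {
    par <- c(list(beta = numeric(p), sig2 = exp(theta[1:2]),
                  D = dpar_to_D(theta[3:12])), empty_sv)
    v <- jm_nll_cpp(jd, par, 0L, 1L, FALSE, TRUE, FALSE)$nll
    if (!is.finite(v)) 1e10 else v      # keep finite for line searches
  }
  opt <- nlminb(theta0, fn, control = list(iter.max = ctl$maxit,
                                           eval.max = 10L * ctl$maxit,
                                           rel.tol = ctl$reltol))
  # convergence is judged by the scaled gradient at the optimum, which is
  # more informative than nlminb's sometimes-pessimistic status code
  gmax <- max(abs(vapply(seq_along(opt$par), function(j) {
    h <- 1e-5 * max(1, abs(opt$par[j]))
    tp <- tm <- opt$par; tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (fn(tp) - fn(tm)) / (2 * h)
  }, 0)))
  converged <- gmax / max(1, abs(opt$objective)) < 1e-3 ||
    opt$convergence == 0L
  opt$value <- opt$objective
  par_hat <- c(list(beta = numeric(p), sig2 = exp(opt$par[1:2]),
                    D = dpar_to_D(opt$par[3:12])), empty_sv)
  final <- jm_nll_cpp(jd, par_hat, 0L, 1L, FALSE, TRUE, FALSE)
  beta <- drop(final$beta_hat)
  names(beta) <- jd$pnames
  vcov_beta <- final$beta_vcov
  dimnames(vcov_beta) <- list(jd$pnames, jd$pnames)

  sig2 <- exp(opt$par[1:2]); names(sig2) <- jd$outcomes
  D <- dpar_to_D(opt$par[3:12])
  renames <- paste(rep(jd$outcomes, each = 2), c("int", "slope"), sep = "_")
  dimnames(D) <- list(renames, renames)

  ll <- -opt$value
  df <- p + 12L
  structure(list(
    coefficients = split(beta, rep(jd$outcomes, c(jd$p1, jd$p2))),
    beta = beta, vcov_beta = vcov_beta, se_beta = sqrt(diag(vcov_beta)),
    D = D, sig2 = sig2, sigma = sqrt(sig2),
    theta = opt$par, loglik = ll, df = df,
    n_subjects = length(jd$subjects), n_obs = length(jd$y),
    convergence = if (converged) 0L else 1L,
    optimizer_message = opt$message, scaled_gradient = gmax / max(1, abs(ll)),
    counts = opt$evaluations,
    jd = jd, call = match.call()
  ), class = "blmm")
}

## per-subject OLS lines -> sigma^2 and D-diagonal starting values ----------
blmm_start <- function(jd) {
  sig2 <- c(1, 1); dvar <- c(1, 0.01, 1, 0.01)
  ni <- ifelse(jd$long_start > 0L, jd$long_end - jd$long_start + 1L, 0L)
  sub_of_row <- rep(seq_along(jd$subjects), ni)   # rows contiguous by subject
  for (ki in 1:2) {
    rows <- which(jd$k == ki)
    sid <- sub_of_row[rows]
    rss <- 0; nres <- 0; coefs <- NULL
    for (i in unique(sid)) {
      rr <- rows[sid == i]
      if (length(rr) < 3L) next
      tt <- jd$t[rr]; yy <- jd$y[rr]
      f <- lm.fit(cbind(1, tt), yy)
      rss <- rss + sum(f$residuals^2); nres <- nres + length(rr) - 2L
      coefs <- rbind(coefs, f$coefficients)
    }
    if (nres > 0) sig2[ki] <- max(rss / nres, 1e-6)
    else sig2[ki] <- max(var(jd$y[rows]) / 2, 1e-6)
    if (!is.null(coefs) && nrow(coefs) > 2) {
      dvar[2 * ki - 1] <- max(var(coefs[, 1]), 1e-6)
      dvar[2 * ki] <- max(var(coefs[, 2]), 1e-8)
    } else {
      dvar[2 * ki - 1] <- max(var(jd$y[rows]) / 2, 1e-6)
      dvar[2 * ki] <- dvar[2 * ki - 1] / (20 * max(var(jd$t), 1))
    }
  }
  list(sig2 = sig2, dvar = dvar)
}

#' @export
print.blmm <- function(x, digits = 4, ...) {
  cat("Bivariate linear mixed model (ML)\n")
  cat("  subjects:", x$n_subjects, "  observations:", x$n_obs, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      "  AIC:", format(-2 * x$loglik + 2 * x$df, digits = 8), "\n")
  cat("  residual SD:", paste(names(x$sig2), round(x$sigma, digits),
                              collapse = ", "), "\n")
  cat("Random-effects covariance (D):\n")
  print(round(x$D, digits))
  if (x$convergence != 0) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Coefficient table for a bivariate LMM fit
#'
#' @param object a `blmm` fit.
#' @param level confidence level for Wald intervals.
#' @param ... unused.
#' @return a list of per-outcome data frames (estimate, SE, CI, p-value)
#'   plus the variance components, of class `summary.blmm`.
#' @export
summary.blmm <- function(object, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  tabs <- lapply(names(object$coefficients), function(k) {
    est <- object$coefficients[[k]]
    nm <- sub("^[^:]+:", "", names(est))
    se <- object$se_beta[paste0(k, ":", nm)]
    data.frame(term = nm, estimate = est, se = se,
               lower = est - z * se, upper = est + z * se,
               p = 2 * pnorm(-abs(est / se)), row.names = NULL)
  })
  names(tabs) <- names(object$coefficients)
  structure(list(fixed = tabs, D = object$D, sigma = object$sigma,
                 loglik = object$loglik, df = object$df,
                 n_subjects = object$n_subjects,
                 convergence = object$convergence),
            class = "summary.blmm")
}

#' @export
print.summary.blmm <- function(x, digits = 4, ...) {
  for (k in names(x$fixed)) {
    cat("Fixed effects,", k, ":\n")
    print(format_fit_table(x$fixed[[k]], digits))
    cat("\n")
  }
  cat("Residual SD:", paste(names(x$sigma), round(x$sigma, digits),
                            collapse = ", "), "\n")
  cat("log-likelihood:", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

format_fit_table <- function(tab, digits = 4) {
  out <- tab
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) formatC(v, digits = digits, format = "f"))
  out
}

#' @export
coef.blmm <- function(object, ...) object$coefficients

#' @export
logLik.blmm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
vcov.blmm <- function(object, ...) object$vcov_beta

#' @export
fitted.blmm <- function(object, ...) {
  drop(object$jd$X %*% object$beta)
}

#' Residuals of a bivariate LMM fit
#'
#' @param object a `blmm` fit.
#' @param type `"marginal"` (y minus X beta) or `"conditional"` (also
#'   subtracting the BLUP random-effect contribution).
#' @param ... unused.
#' @export
residuals.blmm <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  r <- object$jd$y - fitted(object)
  if (type == "conditional") {
    b <- blup(object)$mean
    jd <- object$jd
    ni <- ifelse(jd$long_start > 0L, jd$long_end - jd$long_start + 1L, 0L)
    sub_of_row <- rep(seq_along(jd$subjects), ni)   # rows contiguous by subject
    off <- 2L * (jd$k - 1L)
    r <- r - (b[cbind(sub_of_row, off + 1L)] + b[cbind(sub_of_row, off + 2L)] * jd$t)
  }
  r
}

#' Empirical Bayes random-effect estimates (BLUPs)
#'
#' Posterior mean \eqn{D Z_i^\top V_i^{-1}(y_i - X_i\hat\beta)} and
#' covariance of each subject's random-effect vector given their observed
#' measurements.  A subject without longitudinal data gets the prior
#' (mean 0, covariance `D`).
#'
#' @param fit a `blmm` or `jointfit` object.
#' @param subject optional subject id (or vector); default all.
#' @return list with `mean` (n x 4 matrix, rownames subject ids) and `var`
#'   (n x 16, row-wise vectorised 4x4 covariances).
#' @export
blup <- function(fit, subject = NULL) {
  jd <- fit$jd
  par <- blup_par(fit)
  res <- jm_nll_cpp(jd, par, 0L, 1L, FALSE, FALSE, TRUE)
  mean <- res$post_mean; var <- res$post_var
  rownames(mean) <- rownames(var) <- jd$subjects
  colnames(mean) <- paste(rep(jd$outcomes, each = 2), c("int", "slope"), sep = "_")
  if (!is.null(subject)) {
    keep <- match(as.character(subject), jd$subjects)
    if (anyNA(keep)) stop("unknown subject id(s)")
    mean <- mean[keep, , drop = FALSE]; var <- var[keep, , drop = FALSE]
  }
  list(mean = mean, var = var)
}

blup_par <- function(fit) {
  if (inherits(fit, "blmm"))
    list(beta = unname(fit$beta), sig2 = unname(fit$sig2), D = unclass(fit$D),
         gamma = numeric(), alpha = numeric(), lam = 1)
  else if (inherits(fit, "jointfit"))
    list(beta = unname(fit$beta), sig2 = unname(fit$sig2), D = unclass(fit$D),
         gamma = numeric(), alpha = numeric(), lam = 1)
  else stop("blup() needs a 'blmm' or 'jointfit' object")
}
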