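#' Cox proportional-hazards fit for time to recovery
#'
#' Separate-analysis survival model: \eqn{h_i(t) = h_0(t)\exp(\gamma^\top
#' w_i)} with the baseline covariate indicators of the cohort design.
#' Partial-likelihood maximisation and the Breslow baseline cumulative
#' hazard are delegated to the `survival` package; ties are handled by the
#' Efron approximation by default (hour-grid data are heavily tied), with
#' Breslow selectable.
#'
#' Monotone likelihood (perfect separation) is detected from the fit
#' diagnostics and flagged in `$flags` rather than raised.
#'
#' @param cohort a cohort object.
#' @param covariates optional character vector of survival design columns
#'   (default: all).
#' @param ties `"efron"` or `"breslow"`.
#' @return an object of class `coxfit` with `gamma`, `se`, `ci`, `hr`,
#'   `p`, `loglik` (partial), `basehaz` (Breslow cumulative hazard data
#'   frame), `flags`, and the underlying `coxph` object in `$engine`.
#' @export
fit_cox <- function(cohort, covariates = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(cohort, "cohort"))
  if (sum(cohort$surv$status == 1) < 1) stop("no events in cohort")
  des <- build_design(cohort)
  W <- des$W
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, colnames(W))
    if (length(miss)) stop("unknown survival design column(s): ",
                           paste(miss, collapse = ", "))
    W <- W[, covariates, drop = FALSE]
  }
  surv <- cohort$surv[match(rownames(W), cohort$surv$subject_id), ]
  dat <- data.frame(.time = surv$event_time, .status = surv$status)
  form <- if (ncol(W) > 0) {
    dat <- cbind(dat, as.data.frame(W))
    stats::as.formula(paste("Surv(.time, .status) ~",
                            paste(sprintf("`%s`", colnames(W)), collapse = "+")))
  } else Surv(.time, .status) ~ 1
  fit <- coxph(form, data = dat, ties = ties)
  flags <- character()
  if (ncol(W) > 0) {
    se <- sqrt(diag(fit$var))
    if (any(!is.finite(se)) || any(abs(coef(fit)) > 15))
      flags <- c(flags, "possible monotone likelihood / separation")
  }
  gamma <- if (ncol(W) > 0) coef(fit) else setNames(numeric(), character())
  names(gamma) <- colnames(W)
  se <- if (ncol(W) > 0) setNames(sqrt(diag(fit$var)), colnames(W)) else gamma
  z <- qnorm(0.975)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(
    gamma = gamma, se = se,
    ci = cbind(lower = gamma - z * se, upper = gamma + z * se),
    hr = exp(gamma), p = 2 * pnorm(-abs(gamma / se)),
    loglik = fit$loglik[length(fit$loglik)],
    basehaz = data.frame(time = bh$time, cumhaz = bh$hazard),
    ties = ties, flags = flags, n = nrow(dat),
    n_events = sum(dat$.status), engine = fit, call = match.call()
  ), class = "coxfit")
}

#' @export
print.coxfit <- function(x, digits = 4, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties): ",
      x$n, " subjects, ", x$n_events, " events\n", sep = "")
  if (length(x$gamma)) {
    tab <- data.frame(coef = x$gamma, se = x$se,
                      lower = x$ci[, 1], upper = x$ci[, 2],
                      HR = x$hr, p = x$p)
    print(round(tab, digits))
  } else cat("(no covariates; baseline hazard only)\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.coxfit <- function(object, ...) object$gamma

#' @export
logLik.coxfit <- function(object, ...) {
  structure(object$loglik, df = length(object$gamma), nobs = object$n,
            class = "logLik")
}

#' @export
summary.coxfit <- function(object, ...) {
  data.frame(term = names(object$gamma), coef = object$gamma,
             se = object$se, lower = object$ci[, 1], upper = object$ci[, 2],
             hr = object$hr, p = object$p, row.names = NULL)
}

#' Hazard ratio and percent change for a log-hazard coefficient
#'
#' `HR = exp(coef)`; the percent change is reported as a decrease
#' (`100 (1 - HR)`) for negative coefficients and an increase
#' (`100 (HR - 1)`) otherwise, matching the way fitted recovery-hazard
#' effects are usually read out loud.
#'
#' @param coef finite log-hazard coefficient(s).
#' @return data frame with `coef`, `hr`, `percent_change`, `direction`.
#' @examples
#' hazard_ratio(c(-1.0626, 0.1254, 0))
#' @export
hazard_ratio <- function(coef) {
  stopifnot(all(is.finite(coef)))
  hr <- exp(coef)
  data.frame(
    coef = coef, hr = hr,
    percent_change = ifelse(coef < 0, 100 * (1 - hr), 100 * (hr - 1)),
    direction = ifelse(coef < 0, "decrease", ifelse(coef > 0, "increase", "none")),
    stringsAsFactors = FALSE)
}
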