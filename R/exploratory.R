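#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric survival curve for the recovery times, with tied times
#' grouped and censored subjects at a time t kept at risk for events at t
#' (the standard convention).  Computation is delegated to
#' `survival::survfit`.
#'
#' @param time positive event/censoring times (hours).
#' @param status 0/1 event indicators (1 = recovery).
#' @return object of class `km_curve`: data frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `se`.
#' @examples
#' kaplan_meier(c(1, 2, 3), c(1, 1, 1))$surv   # 2/3, 1/3, 0
#' @export
kaplan_meier <- function(time, status) {
  if (!length(time)) stop("empty input")
  stopifnot(length(time) == length(status), all(time > 0),
            all(status %in% c(0, 1)))
  sf <- survfit(Surv(time, status) ~ 1, conf.type = "none")
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv, se = sf$std.err * sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
plot.km_curve <- function(x, xlab = "hours", ylab = "S(t)", ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest observed time at which the estimated survival drops to
#' 0.5 or below; flagged undefined when the curve never reaches 0.5
#' (e.g. heavy censoring).
#'
#' @param curve a [kaplan_meier()] curve.
#' @return list with `median` (hours, `NA` when undefined) and `defined`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- which(curve$surv <= 0.5 + 1e-12)
  if (!length(idx)) list(median = NA_real_, defined = FALSE)
  else list(median = curve$time[min(idx)], defined = TRUE)
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve up to the largest observed time.
#'
#' @param curve a [kaplan_meier()] curve.
#' @return hours.
#' @export
restricted_mean_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  tt <- c(0, curve$time)
  ss <- c(1, curve$surv)
  sum(diff(tt) * ss[-length(ss)])
}

#' Log-rank test for survival differences between groups
#'
#' Observed-minus-expected statistic with hypergeometric variance,
#' referred to a chi-squared distribution with (groups - 1) degrees of
#' freedom; computed via `survival::survdiff`.
#'
#' @param time,status as in [kaplan_meier()].
#' @param group group labels (>= 2 distinct values).
#' @return list of class `logrank_result`: `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, status, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("need at least 2 groups")
  sd <- survdiff(Surv(time, status) ~ group)
  structure(list(statistic = unname(sd$chisq),
                 df = length(sd$n) - 1L,
                 p = unname(pchisq(sd$chisq, length(sd$n) - 1L,
                                   lower.tail = FALSE))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test: chi-squared =", format(x$statistic, digits = 5),
      "on", x$df, "df, p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Descriptive frequency table with recovery percentages
#'
#' Per covariate level: subject count, percent of the cohort, recovered
#' and not-recovered counts with within-level percentages.  Two test
#' statistics are attached per covariate and labelled explicitly: the
#' contingency chi-squared of level vs. recovery status, and the log-rank
#' statistic comparing the level-specific recovery-time curves -- they
#' answer different questions and are reported side by side.
#'
#' @param cohort a cohort object.
#' @return list of class `descriptive_table`: `table` (data frame),
#'   `tests` (data frame with `chisq_contingency`, `p_contingency`,
#'   `logrank`, `p_logrank` per covariate), `overall` (recovered count and
#'   percentage).
#' @export
descriptive_table <- function(cohort) {
  surv <- cohort$surv
  n <- nrow(surv)
  pct <- function(a, b) if (b > 0) 100 * a / b else 0
  rows <- list(); tests <- list()
  for (cv in cohort$design$covariates) {
    val <- factor(surv[[cv$name]], levels = cv$levels)
    for (lev in cv$levels) {
      m <- val == lev
      nl <- sum(m); nr <- sum(m & surv$status == 1)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv$name, level = lev, n = nl,
        percent = round(pct(nl, n), 2),
        recovered = nr, recovered_pct = round(pct(nr, nl), 2),
        not_recovered = nl - nr,
        not_recovered_pct = round(pct(nl - nr, nl), 2),
        stringsAsFactors = FALSE)
    }
    observed <- droplevels(val)
    cs <- if (nlevels(observed) >= 2L)
      suppressWarnings(chisq.test(table(observed, surv$status), correct = FALSE))
    else list(statistic = NA_real_, p.value = NA_real_)
    lr <- if (nlevels(observed) >= 2L)
      logrank_test(surv$event_time, surv$status, observed)
    else list(statistic = NA_real_, p = NA_real_)
    tests[[length(tests) + 1L]] <- data.frame(
      covariate = cv$name,
      chisq_contingency = unname(cs$statistic), p_contingency = cs$p.value,
      logrank = lr$statistic, p_logrank = lr$p,
      stringsAsFactors = FALSE)
  }
  structure(list(
    table = do.call(rbind, rows),
    tests = do.call(rbind, tests),
    overall = data.frame(n = n, recovered = sum(surv$status == 1),
                         recovered_pct = round(pct(sum(surv$status == 1), n), 2))
  ), class = "descriptive_table")
}

#' @export
print.descriptive_table <- function(x, ...) {
  cat("Cohort of", x$overall$n, "subjects;",
      x$overall$recovered, sprintf("(%.2f%%) recovered\n", x$overall$recovered_pct))
  print(x$table, row.names = FALSE)
  cat("\nPer-covariate tests (contingency chi-squared vs. log-rank):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Individual and mean trajectory profiles
#'
#' Per-subject trajectories of one outcome plus the visit-time-aligned
#' mean trajectory; subjects contribute to a visit's mean only while still
#' under observation, and visits with no subjects are omitted.
#'
#' @param cohort a cohort object.
#' @param outcome outcome label (e.g. `"PR"`).
#' @return list of class `profile_set`: `individual` (subject, time,
#'   value), `mean` (time, mean, n).
#' @export
profiles <- function(cohort, outcome) {
  stopifnot(outcome %in% cohort$outcomes)
  lk <- cohort$long[cohort$long$outcome == outcome, , drop = FALSE]
  if (!nrow(lk)) stop("no measurements for outcome ", outcome)
  mn <- aggregate(lk$value, by = list(time = lk$time),
                  FUN = function(v) c(mean = mean(v), n = length(v)))
  mean_df <- data.frame(time = mn$time, mean = mn$x[, "mean"],
                        n = as.integer(mn$x[, "n"]))
  structure(list(
    individual = data.frame(subject_id = lk$subject_id, time = lk$time,
                            value = lk$value, stringsAsFactors = FALSE),
    mean = mean_df[order(mean_df$time), ], outcome = outcome
  ), class = "profile_set")
}

#' @export
plot.profile_set <- function(x, xlab = "hours", ylab = x$outcome, ...) {
  ids <- unique(x$individual$subject_id)
  graphics::plot(NULL, xlim = range(x$individual$time),
                 ylim = range(x$individual$value), xlab = xlab, ylab = ylab, ...)
  for (id in ids) {
    d <- x$individual[x$individual$subject_id == id, ]
    lines(d$time, d$value, col = grDevices::grey(0.75))
  }
  lines(x$mean$time, x$mean$mean, lwd = 3)
  invisible(x)
}

#' Model-based marginal correlation between the two outcomes over time
#'
#' From a fitted bivariate mixed model (or explicit variance components),
#' the correlation between the two observed outcomes at the same time t:
#' \deqn{\rho_{12}(t) = \frac{z(t)^\top D_{12} z(t)}
#'  {\sqrt{(z(t)^\top D_{11} z(t)+\sigma_1^2)(z(t)^\top D_{22} z(t)+\sigma_2^2)}}}
#' with \eqn{z(t) = (1, t)^\top} and \eqn{D_{kk}, D_{12}} the 2x2 blocks of
#' the random-effects covariance.
#'
#' @param fit a `blmm` or `jointfit` object, or a list with `D` (4x4) and
#'   `sig2` (length 2).
#' @param times evaluation times (hours).
#' @return data frame with `time` and `correlation`.
#' @export
marginal_correlation_profile <- function(fit, times) {
  D <- fit$D; sig2 <- fit$sig2
  check_D(unname(as.matrix(D)))
  D <- unname(as.matrix(D))
  sapply_rho <- vapply(times, function(t) {
    z <- c(1, t)
    v1 <- drop(z %*% D[1:2, 1:2] %*% z) + sig2[1]
    v2 <- drop(z %*% D[3:4, 3:4] %*% z) + sig2[2]
    drop(z %*% D[1:2, 3:4] %*% z) / sqrt(v1 * v2)
  }, 0)
  data.frame(time = times, correlation = unname(sapply_rho))
}

#' Empirical per-visit correlation between the two outcomes
#'
#' Pearson correlation of the paired measurements at each visit time,
#' among subjects observed for both outcomes at that time.  Reported
#' alongside the model-based [marginal_correlation_profile()].
#'
#' @param cohort a cohort object.
#' @param times optional visit times (default: all shared times).
#' @return data frame with `time`, `correlation`, `n`.
#' @export
empirical_correlation_profile <- function(cohort, times = NULL) {
  lo <- cohort$long
  o1 <- lo[lo$outcome == cohort$outcomes[1L], ]
  o2 <- lo[lo$outcome == cohort$outcomes[2L], ]
  if (is.null(times)) times <- sort(intersect(o1$time, o2$time))
  rows <- lapply(times, function(t) {
    a <- o1[o1$time == t, ]; b <- o2[o2$time == t, ]
    ids <- intersect(a$subject_id, b$subject_id)
    if (length(ids) < 3L)
      return(data.frame(time = t, correlation = NA_real_, n = length(ids)))
    data.frame(time = t,
               correlation = cor(a$value[match(ids, a$subject_id)],
                                 b$value[match(ids, b$subject_id)]),
               n = length(ids))
  })
  do.call(rbind, rows)
}
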