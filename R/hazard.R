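#' Gauss-Hermite rule for a standard normal weight
#'
#' Nodes and weights for \eqn{\int f(z)\phi(z)dz \approx \sum_i w_i f(x_i)}
#' with \eqn{\phi} the standard normal density, computed by the
#' Golub-Welsch eigenvalue method on the Jacobi matrix of the probabilists'
#' Hermite polynomials.  Weights sum to 1.
#'
#' @param n number of nodes (>= 1).
#' @return list with numeric vectors `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1L))
  J[cbind(1:(n - 1L), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1L, ord])^2)
}

## exp-integral over a piece: int_a^b exp(v t) dt, stable as v -> 0 ----------
pw_J <- function(v, a, b) {
  # exp(v*a) * expm1(v*(b-a)) / v keeps relative accuracy for small v*(b-a)
  ifelse(abs(v) < 1e-12, b - a, exp(v * a) * expm1(v * (b - a)) / v)
}

#' Piecewise-exponential cumulative hazard with log-linear subject effect
#'
#' Cumulative hazard \eqn{\Lambda(t) = e^u \sum_p \lambda_p
#' \int_{[c_{p-1},c_p] \cap [0,t]} e^{v s} ds} for a hazard
#' \eqn{h(s) = \lambda(s) e^{u + v s}} with piecewise-constant baseline
#' rates `lam` on the intervals defined by interior cutpoints `cut`
#' (first interval starts at 0, last is unbounded).  `t`, `u`, `v` are
#' recycled to a common length; the integral is available in closed form
#' per piece, with the \eqn{v \to 0} limit handled.
#'
#' @param t nonnegative times.
#' @param u,v log-hazard intercept and slope per subject.
#' @param lam positive baseline rates, one per piece.
#' @param cut strictly increasing interior cutpoints (length `length(lam)-1`).
#' @return numeric vector of cumulative hazards.
#' @export
pw_cumhaz <- function(t, u, v, lam, cut = numeric()) {
  stopifnot(length(lam) == length(cut) + 1L, all(lam > 0),
            !is.unsorted(cut, strictly = TRUE))
  n <- max(length(t), length(u), length(v))
  t <- rep_len(t, n); u <- rep_len(u, n); v <- rep_len(v, n)
  lo <- c(0, cut); hi <- c(cut, Inf)
  S <- numeric(n)
  for (p in seq_along(lam)) {
    b <- pmin(t, hi[p])
    act <- b > lo[p]
    if (any(act))
      S[act] <- S[act] + lam[p] * pw_J(v[act], lo[p], b[act])
  }
  exp(u) * S
}

## baseline rate at time t ----------------------------------------------------
pw_rate <- function(t, lam, cut = numeric()) {
  idx <- findInterval(t, c(0, cut), left.open = TRUE)   # pieces (lo, hi]
  lam[pmin(pmax(idx, 1L), length(lam))]
}

#' Invert the piecewise-exponential cumulative hazard
#'
#' Solves \eqn{\Lambda(T) = e} for `T` given the hazard of [pw_cumhaz()],
#' accumulating the closed-form integral piece by piece and solving inside
#' the piece that brackets the target.  Returns `Inf` when the total
#' cumulative hazard stays below `e` (possible when `v < 0`).
#'
#' @param e positive targets (e.g. `-log(U)`, `U` uniform).
#' @inheritParams pw_cumhaz
#' @return event times (may be `Inf`).
#' @export
pw_invert <- function(e, u, v, lam, cut = numeric()) {
  n <- max(length(e), length(u), length(v))
  e <- rep_len(e, n); u <- rep_len(u, n); v <- rep_len(v, n)
  stopifnot(all(e > 0), all(is.finite(e)))
  lo <- c(0, cut); hi <- c(cut, Inf)
  Tout <- rep(NA_real_, n)
  rem <- e / exp(u)                       # target on the baseline-integral scale
  for (p in seq_along(lam)) {
    idx <- which(is.na(Tout))
    if (!length(idx)) break
    a <- lo[p]
    dp <- lam[p] * pw_J(v[idx], a, rep_len(hi[p], length(idx)))  # piece mass, Inf ok
    inside <- rem[idx] <= dp                                      # target falls here
    solve_in <- idx[inside]
    if (length(solve_in)) {
      vv <- v[solve_in]; rr <- rem[solve_in]
      Tout[solve_in] <- ifelse(abs(vv) < 1e-12,
                               a + rr / lam[p],
                               a + log1p(vv * rr / (lam[p] * exp(vv * a))) / vv)
    }
    passed <- idx[!inside]
    rem[passed] <- rem[passed] - dp[!inside]
  }
  Tout[is.na(Tout)] <- Inf                # hazard exhausted below target
  Tout
}

#' Maximum-likelihood piecewise-exponential proportional-hazards fit
#'
#' Fits \eqn{h_i(t) = \lambda(t) e^{\gamma^\top w_i}} with
#' piecewise-constant baseline rates by maximum likelihood, via the
#' standard Poisson-likelihood equivalence on the (subject, piece)
#' exposure table.  Used for the separate survival fit compared against
#' the joint model and for joint-fit initial values.
#'
#' @param time,status event/censoring times (hours) and 0/1 indicators.
#' @param W baseline design matrix (may have zero columns).
#' @param cut interior cutpoints; defaults to event-time terciles.
#' @return list with `gamma`, `lam`, `cut`, `loglik`, `vcov` (for gamma
#'   and log-rates jointly, Poisson-glm based), `df`.
#' @export
fit_pwexp <- function(time, status, W = NULL,
                      cut = unname(quantile(time[status == 1], c(1, 2) / 3))) {
  stopifnot(length(time) == length(status), all(time > 0))
  if (is.null(W)) W <- matrix(0, length(time), 0)
  W <- as.matrix(W)
  cut <- cut[cut > 0 & cut < max(time)]
  cut <- sort(unique(cut))
  lo <- c(0, cut); hi <- c(cut, Inf)
  P <- length(lo)
  n <- length(time)
  # exposure and event count per (subject, piece)
  expo <- outer(time, seq_len(P), function(t, p) pmax(0, pmin(t, hi[p]) - lo[p]))
  dmat <- outer(time, seq_len(P), function(t, p)
    as.numeric(t > lo[p] & (t <= hi[p] | p == P))) * status
  keep <- expo > 0
  piece <- factor(rep(seq_len(P), each = n)[keep], levels = seq_len(P))
  d <- dmat[keep]; ex <- expo[keep]
  Wrep <- W[rep(seq_len(n), P)[keep], , drop = FALSE]
  df <- data.frame(d = d, piece = piece)
  glm_dat <- cbind(df, as.data.frame(Wrep))
  form <- if (ncol(W) > 0)
    stats::as.formula(paste("d ~ piece - 1 +",
                            paste(sprintf("`%s`", colnames(Wrep)), collapse = "+")))
  else d ~ piece - 1
  fit <- stats::glm(form, family = stats::poisson(),
                    offset = log(ex), data = glm_dat)
  cf <- coef(fit)
  lam <- exp(cf[seq_len(P)])
  gamma <- if (ncol(W) > 0) cf[-seq_len(P)] else numeric()
  names(gamma) <- colnames(W)
  eta <- if (ncol(W) > 0) drop(W %*% gamma) else rep(0, n)
  ll <- sum(status * (log(pw_rate(time, lam, cut)) + eta)) -
    sum(exp(eta) * pw_cumhaz(time, 0, 0, lam, cut))
  list(gamma = gamma, lam = unname(lam), cut = cut, loglik = ll,
       vcov = suppressWarnings(stats::vcov(fit)), df = length(cf))
}
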