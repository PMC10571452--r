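# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (dense algebra, brute-force sums) so it cannot share a
# code path with the package internals it checks.

## dense multivariate normal log-density --------------------------------------
dmvnorm_log <- function(y, mu, S) {
  L <- t(chol(S))
  w <- forwardsolve(L, y - mu)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(w^2))
}

## dense bivariate-LMM log-likelihood straight from the cohort tables ---------
blmm_loglik_dense <- function(cohort, beta_list, sig2, D) {
  des <- build_design(cohort)
  total <- 0
  for (id in cohort$surv$subject_id) {
    ys <- Zs <- mus <- list()
    for (ki in 1:2) {
      k <- cohort$outcomes[ki]
      sel <- des$index[[k]]$subject_id == id
      if (!any(sel)) next
      X <- des$X[[k]][sel, , drop = FALSE]
      tt <- des$index[[k]]$time[sel]
      Zk <- matrix(0, sum(sel), 4)
      Zk[, 2 * ki - 1] <- 1; Zk[, 2 * ki] <- tt
      ys[[length(ys) + 1]] <- cohort$long$value[cohort$long$outcome == k &
                                                  cohort$long$subject_id == id]
      Zs[[length(Zs) + 1]] <- Zk
      mus[[length(mus) + 1]] <- drop(X %*% beta_list[[k]])
    }
    if (!length(ys)) next
    y <- unlist(ys); Z <- do.call(rbind, Zs); mu <- unlist(mus)
    Rdiag <- unlist(lapply(seq_along(ys), function(j)
      rep(sig2[if (any(Zs[[j]][, 1] == 1)) 1 else 2], length(ys[[j]]))))
    V <- Z %*% D %*% t(Z) + diag(Rdiag, length(y))
    total <- total + dmvnorm_log(y, mu, V)
  }
  total
}

## Monte-Carlo joint log-likelihood over b ~ N(0, D) --------------------------
## Importance sampling from a Gaussian centred at each subject's dense
## longitudinal posterior (scale inflated 1.5x).  Unbiased for any proposal,
## so correctness does not rest on the centring; it only buys variance.
joint_loglik_mc <- function(cohort, beta_list, sig2, D, gamma, alpha, lam, cut,
                            association, B = 2e5, seed = 1) {
  set.seed(seed)
  des <- build_design(cohort)
  W <- des$W
  ldet_prior <- determinant(D, logarithm = TRUE)$modulus
  Dinv <- solve(D)
  out_ll <- out_se <- numeric(nrow(cohort$surv))
  for (i in seq_len(nrow(cohort$surv))) {
    id <- cohort$surv$subject_id[i]
    # dense posterior of b given this subject's longitudinal data
    ys <- Zs <- mus <- list(); Rd <- numeric()
    for (ki in 1:2) {
      k <- cohort$outcomes[ki]
      sel <- des$index[[k]]$subject_id == id
      if (!any(sel)) next
      tt <- des$index[[k]]$time[sel]
      Zk <- matrix(0, sum(sel), 4)
      Zk[, 2 * ki - 1] <- 1; Zk[, 2 * ki] <- tt
      ys[[length(ys) + 1]] <- cohort$long$value[cohort$long$outcome == k &
                                                  cohort$long$subject_id == id]
      Zs[[length(Zs) + 1]] <- Zk
      mus[[length(mus) + 1]] <- drop(des$X[[k]][sel, , drop = FALSE] %*%
                                       beta_list[[ki]])
      Rd <- c(Rd, rep(sig2[ki], sum(sel)))
    }
    if (length(ys)) {
      yi <- unlist(ys); Zi <- do.call(rbind, Zs); ri <- yi - unlist(mus)
      Vi <- Zi %*% D %*% t(Zi) + diag(Rd, length(yi))
      DZt <- D %*% t(Zi)
      m <- drop(DZt %*% solve(Vi, ri))
      Cp <- D - DZt %*% solve(Vi, t(DZt))
    } else { m <- rep(0, 4); Cp <- D }
    Cq <- 1.5^2 * (Cp + t(Cp)) / 2 + diag(1e-10, 4)
    Lq <- t(chol(Cq))
    bdraws <- t(m + Lq %*% matrix(rnorm(4 * B), 4, B))
    # log proposal density
    wq <- forwardsolve(Lq, t(bdraws) - m)
    lq <- -0.5 * (4 * log(2 * pi) + 2 * sum(log(diag(Lq))) + colSums(wq^2))
    # log prior density
    lp <- -0.5 * (4 * log(2 * pi) + ldet_prior +
                    rowSums((bdraws %*% Dinv) * bdraws))
    lg <- as.numeric(lp - lq)
    # longitudinal likelihood at each draw
    if (length(ys)) {
      mu_all <- matrix(unlist(mus), nrow = B, ncol = length(yi),
                       byrow = TRUE) + bdraws %*% t(Zi)
      for (j in seq_along(yi))
        lg <- lg + dnorm(yi[j], mu_all[, j], sqrt(Rd[j]), log = TRUE)
    }
    # association terms (current_value / cv+slope / shared RE)
    w <- W[match(id, rownames(W)), ]
    xk <- lapply(1:2, function(ki) {
      k <- cohort$outcomes[ki]
      cn <- colnames(des$X[[k]])
      xr <- c(1, as.numeric(w), 0)          # intercept, dummies, time zeroed
      names(xr) <- cn
      xr
    })
    f <- vapply(1:2, function(ki) sum(xk[[ki]] * beta_list[[ki]]), 0)
    g <- vapply(1:2, function(ki) beta_list[[ki]][length(beta_list[[ki]])], 0)
    gw <- sum(w * gamma)
    if (association == "current_value") {
      u <- gw + alpha[1] * (f[1] + bdraws[, 1]) + alpha[2] * (f[2] + bdraws[, 3])
      v <- alpha[1] * (g[1] + bdraws[, 2]) + alpha[2] * (g[2] + bdraws[, 4])
    } else if (association == "current_value_and_slope") {
      u <- gw + alpha[1] * (f[1] + bdraws[, 1]) + alpha[2] * (f[2] + bdraws[, 3]) +
        alpha[3] * (g[1] + bdraws[, 2]) + alpha[4] * (g[2] + bdraws[, 4])
      v <- alpha[1] * (g[1] + bdraws[, 2]) + alpha[2] * (g[2] + bdraws[, 4])
    } else {
      u <- gw + alpha[1] * bdraws[, 2] + alpha[2] * bdraws[, 4]
      v <- rep(0, B)
    }
    Ti <- cohort$surv$event_time[i]; di <- cohort$surv$status[i]
    lo <- c(0, cut); hi <- c(cut, Inf)
    H <- numeric(B)
    for (j in seq_along(lam)) {
      bnd <- min(Ti, hi[j])
      if (bnd <= lo[j]) break
      H <- H + lam[j] * ifelse(abs(v) < 1e-12, bnd - lo[j],
                               (exp(v * bnd) - exp(v * lo[j])) / v)
    }
    p <- findInterval(Ti, c(0, cut), left.open = TRUE)
    lg <- lg + di * (log(lam[p]) + u + v * Ti) - exp(u) * H
    mx <- max(lg)
    gvals <- exp(lg - mx)
    mhat <- mean(gvals)
    out_ll[i] <- mx + log(mhat)
    out_se[i] <- sd(gvals) / (mhat * sqrt(B))   # delta-method SE of log mean
  }
  list(loglik = sum(out_ll), se = sqrt(sum(out_se^2)),
       subject = out_ll, subject_se = out_se)
}

## hand-rolled log-rank statistic (2+ groups, ties allowed) -------------------
logrank_brute <- function(time, status, group) {
  group <- as.factor(group)
  G <- nlevels(group)
  tev <- sort(unique(time[status == 1]))
  O <- E <- numeric(G)
  Vsum <- matrix(0, G, G)
  for (tj in tev) {
    atrisk <- time >= tj
    nj <- sum(atrisk)
    dj <- sum(status == 1 & time == tj)
    njg <- vapply(levels(group), function(g) sum(atrisk & group == g), 0)
    djg <- vapply(levels(group), function(g)
      sum(atrisk & group == g & status == 1 & time == tj), 0)
    O <- O + djg
    E <- E + dj * njg / nj
    if (nj > 1) {
      for (a in 1:G) for (b in 1:G) {
        Vsum[a, b] <- Vsum[a, b] + dj * (nj - dj) / (nj - 1) *
          ((a == b) * njg[a] / nj - njg[a] * njg[b] / nj^2)
      }
    }
  }
  d <- (O - E)[-1]
  V <- Vsum[-1, -1, drop = FALSE]
  drop(t(d) %*% solve(V) %*% d)
}

## Efron/Breslow-free partial log-likelihood (requires untied event times) ----
cox_partial_brute <- function(beta, time, status, x) {
  stopifnot(!anyDuplicated(time[status == 1]))
  eta <- x * beta
  sum(vapply(which(status == 1), function(i)
    eta[i] - log(sum(exp(eta[time >= time[i]]))), 0))
}

## tiny deterministic cohorts -------------------------------------------------
toy_design <- function() {
  covariate_design(list(group = list(levels = c("a", "b"), probs = c(0.5, 0.5))))
}

toy_cohort <- function(n = 3, seed = 42, sigma = c(1, 0.3),
                       D = NULL, assoc = "current_value",
                       alpha = c(-0.03, -0.2), balanced = FALSE) {
  if (is.null(D))
    D <- matrix(c(4, 0.1, 1, 0.05,
                  0.1, 0.02, 0.05, 0.004,
                  1, 0.05, 0.5, 0.01,
                  0.05, 0.004, 0.01, 0.002), 4, 4)
  cfg <- sim_config(
    n_subjects = n, visit_grid = seq(6, 48, by = 6), design = toy_design(),
    beta = list(PR = c(20, 1, -0.1), BT = c(5, 0.5, -0.02)),
    D = D, sigma = sigma, gamma = c(group_b = 0.3),
    association = assoc, alpha = alpha,
    baseline = list(lam = c(0.01, 0.03), cut = 24), censor_time = 48,
    seed = seed)
  covs <- if (balanced)
    data.frame(group = rep(c("a", "b"), length.out = n)) else NULL
  simulate_cohort(cfg, covariates = covs)
}

write_toy_files <- function(dir = tempfile()) {
  dir.create(dir)
  long <- data.frame(
    subject_id = c("A", "A", "B", "B"),
    outcome = c("PR", "BT", "PR", "PR"),
    time_h = c(6, 6, 6, 12),
    value = c(110.5, 37.9, 95.25, 92))
  surv <- data.frame(
    subject_id = c("A", "B"),
    event_time_h = c(18, 30), status = c(1, 0),
    group = c("a", "b"))
  write.csv(long, file.path(dir, "long.csv"), row.names = FALSE)
  write.csv(surv, file.path(dir, "surv.csv"), row.names = FALSE)
  dir
}
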