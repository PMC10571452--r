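## Internal model-data layout shared by the bivariate LMM and the joint model.
##
## Longitudinal rows are sorted by (subject, outcome, time) and the two
## outcomes' fixed-effect designs are laid out block-wise in one matrix with
## p = p1 + p2 columns (zeros outside a row's own outcome block), so that a
## single coefficient vector beta = (beta_PR, beta_BT) applies.  Random
## effects are ordered (PR intercept, PR slope, BT intercept, BT slope).

prepare_jdata <- function(cohort, fixed = NULL, cut = NULL, n_pieces = 5L,
                          nq = 7L) {
  stopifnot(inherits(cohort, "cohort"))
  des <- build_design(cohort)
  outcomes <- cohort$outcomes
  surv <- cohort$surv
  subjects <- surv$subject_id

  cols <- lapply(outcomes, function(k) {
    ck <- colnames(des$X[[k]])
    if (!is.null(fixed[[k]])) {
      miss <- setdiff(fixed[[k]], ck)
      if (length(miss)) stop("unknown design column(s) for ", k, ": ",
                             paste(miss, collapse = ", "))
      ck <- c("(Intercept)",
              intersect(ck, setdiff(fixed[[k]], "(Intercept)")))
      if (!cohort$design$time_col %in% ck) ck <- c(ck, cohort$design$time_col)
      ck <- unique(ck)
      ck <- ck[order(match(ck, colnames(des$X[[k]])))]
    }
    ck
  })
  names(cols) <- outcomes
  p1 <- length(cols[[1L]]); p2 <- length(cols[[2L]])
  pnames <- c(paste0(outcomes[1L], ":", cols[[1L]]),
              paste0(outcomes[2L], ":", cols[[2L]]))

  # stacked longitudinal rows, sorted subject -> outcome -> time
  lparts <- lapply(seq_along(outcomes), function(ki) {
    k <- outcomes[ki]
    idx <- des$index[[k]]
    Xk <- des$X[[k]][, cols[[k]], drop = FALSE]
    data.frame(subject_id = idx$subject_id, k = ki, t = idx$time,
               stringsAsFactors = FALSE)
  })
  ldat <- do.call(rbind, lparts)
  yl <- unlist(lapply(outcomes, function(k)
    cohort$long$value[cohort$long$outcome == k]), use.names = FALSE)
  Xblocks <- matrix(0, nrow(ldat), p1 + p2, dimnames = list(NULL, pnames))
  r1 <- ldat$k == 1L
  Xblocks[r1, seq_len(p1)] <- des$X[[outcomes[1L]]][, cols[[1L]], drop = FALSE]
  Xblocks[!r1, p1 + seq_len(p2)] <- des$X[[outcomes[2L]]][, cols[[2L]], drop = FALSE]

  ord <- order(match(ldat$subject_id, subjects), ldat$k, ldat$t)
  ldat <- ldat[ord, ]; yl <- yl[ord]; Xblocks <- Xblocks[ord, , drop = FALSE]

  sidx <- match(ldat$subject_id, subjects)
  long_start <- long_end <- integer(length(subjects))
  for (i in seq_along(subjects)) {
    w <- which(sidx == i)
    if (length(w)) { long_start[i] <- w[1L]; long_end[i] <- w[length(w)] }
  }

  # per-subject covariate rows at time zero, embedded in the block layout
  Wfull <- des$W[match(subjects, rownames(des$W)), , drop = FALSE]
  base_row <- function(k, colsk, block_off, pk) {
    M <- matrix(0, length(subjects), p1 + p2)
    for (j in seq_along(colsk)) {
      cn <- colsk[j]
      M[, block_off + j] <-
        if (cn == "(Intercept)") 1
        else if (cn == cohort$design$time_col) 0
        else Wfull[, cn]
    }
    M
  }
  Xs1 <- base_row(1L, cols[[1L]], 0L, p1)
  Xs2 <- base_row(2L, cols[[2L]], p1, p2)
  tc1 <- match(cohort$design$time_col, cols[[1L]])
  tc2 <- p1 + match(cohort$design$time_col, cols[[2L]])
  if (is.na(tc1) || is.na(tc2 - p1))
    stop("both outcomes must include the visit-time column")

  if (is.null(cut)) {
    ev <- surv$event_time[surv$status == 1]
    if (length(ev) < 2L) ev <- surv$event_time
    qs <- quantile(ev, seq_len(n_pieces - 1L) / n_pieces, names = FALSE)
    cut <- sort(unique(qs))
    cut <- cut[cut > 0 & cut < max(surv$event_time)]
  }

  gh <- gauss_hermite(nq)
  list(
    subjects = subjects, outcomes = outcomes,
    cols = cols, pnames = pnames, p1 = p1, p2 = p2,
    long_start = long_start, long_end = long_end,
    k = as.integer(ldat$k), t = ldat$t, y = yl, X = Xblocks,
    Xs1 = Xs1, Xs2 = Xs2, tc1 = tc1, tc2 = tc2,
    W = Wfull, wnames = colnames(des$W),
    Tv = surv$event_time, delta = as.numeric(surv$status == 1),
    cut = as.numeric(cut), ghx = gh$nodes, ghw = gh$weights,
    dropped = des$dropped
  )
}

## D (4x4) <-> 10 free parameters via the log-Cholesky factor --------------
d_index <- cbind(row = c(1, 2, 3, 4, 2, 3, 4, 3, 4, 4),
                 col = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4))

dpar_to_D <- function(dpar) {
  L <- matrix(0, 4, 4)
  L[d_index] <- dpar
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

D_to_dpar <- function(D) {
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  # minimal ridge: the log-Cholesky needs strictly positive pivots, but any
  # visible perturbation of a near-singular D would shift the likelihood
  lam <- pmax(e$values, max(e$values, 1) * 1e-14)
  Dp <- e$vectors %*% (lam * t(e$vectors))
  L <- t(chol(Dp))
  dpar <- L[d_index]
  didx <- which(d_index[, 1] == d_index[, 2])
  dpar[didx] <- log(L[cbind(1:4, 1:4)])
  dpar
}

## pack/unpack the full joint parameter vector on the optimizer scale ------
n_alpha_for <- function(association) {
  switch(association, none = 0L, current_value = 2L,
         current_value_and_slope = 4L, shared_random_effects = 2L)
}

pack_par <- function(beta, sig2, D, gamma, alpha, lam) {
  c(beta, log(sig2), D_to_dpar(D), gamma, alpha, log(lam))
}

unpack_par <- function(par, p, q, na, P) {
  i <- 0L
  beta <- par[i + seq_len(p)]; i <- i + p
  lsig <- par[i + 1:2]; i <- i + 2L
  dpar <- par[i + 1:10]; i <- i + 10L
  gamma <- if (q > 0) par[i + seq_len(q)] else numeric(); i <- i + q
  alpha <- if (na > 0) par[i + seq_len(na)] else numeric(); i <- i + na
  lam <- exp(par[i + seq_len(P)])
  list(beta = beta, sig2 = exp(lsig), D = dpar_to_D(dpar),
       gamma = gamma, alpha = alpha, lam = lam)
}

## natural-scale parameter names shared by fitted objects and the
## generator's true-parameter report (name sets must coincide for a
## common design / association / hazard spec)
alpha_names <- function(outcomes, association) {
  switch(association,
    none = character(),
    current_value = paste0("alpha_", outcomes),
    current_value_and_slope = c(paste0("alpha_", outcomes),
                                paste0("alpha_slope_", outcomes)),
    shared_random_effects = paste0("alpha_", outcomes))
}

d_entry_names <- function() {
  paste0("D", d_index[, 1], d_index[, 2])
}

natural_vector <- function(beta, sig2, D, gamma, alpha, lam,
                           pnames, outcomes, wnames, association) {
  setNames(
    c(beta, sqrt(sig2), D[d_index], gamma, alpha, lam),
    c(pnames, paste0("sigma_", outcomes), d_entry_names(),
      if (length(wnames)) paste0("gamma:", wnames),
      alpha_names(outcomes, association),
      paste0("lambda", seq_along(lam))))
}

par_names <- function(jd, na, P, association) {
  anames <- switch(association,
    none = character(),
    current_value = paste0("alpha_", jd$outcomes),
    current_value_and_slope = c(paste0("alpha_", jd$outcomes),
                                paste0("alpha_slope_", jd$outcomes)),
    shared_random_effects = paste0("alpha_", jd$outcomes))
  c(jd$pnames,
    paste0("log_sigma_", jd$outcomes),
    paste0("dpar", 1:10),
    if (length(jd$wnames)) paste0("gamma:", jd$wnames),
    anames,
    paste0("log_lambda", seq_len(P)))
}
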