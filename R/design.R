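#' Covariate design specification
#'
#' Declares the baseline covariates of the cohort: for each covariate its
#' ordered category levels and the reference level (encoded as all-zero
#' indicators).  A covariate with L levels contributes L-1 indicator columns,
#' named `<covariate>_<level>`; visit time enters the longitudinal design as a
#' single continuous column in hours.  The default design mirrors the study's
#' coding: first category of every variable is the reference.
#'
#' @param covariates a named list; each element is a list with fields
#'   `levels` (character vector of category labels, reference first unless
#'   `reference` given), optional `reference`, and optional `probs`
#'   (marginal category probabilities used by the cohort simulator; must sum
#'   to 1).
#' @param time_col name of the visit-time column in longitudinal files.
#' @return an object of class `covariate_design` with components
#'   `covariates`, `x_cols` (longitudinal fixed-effect columns: intercept,
#'   indicators, time), `w_cols` (survival baseline columns: indicators only)
#'   and `time_col`.
#' @examples
#' d <- covariate_design(list(
#'   sex = list(levels = c("female", "male")),
#'   age = list(levels = c("le14", "15_24", "25_64", "ge65"))
#' ))
#' d$x_cols
#' @export
covariate_design <- function(covariates, time_col = "time_h") {
  stopifnot(is.list(covariates), length(names(covariates)) == length(covariates))
  covs <- lapply(names(covariates), function(nm) {
    cv <- covariates[[nm]]
    lev <- as.character(cv$levels)
    if (length(lev) < 2L) stop("covariate '", nm, "' needs at least 2 levels")
    if (anyDuplicated(lev)) stop("covariate '", nm, "' has duplicated levels")
    ref <- if (!is.null(cv$reference)) as.character(cv$reference) else lev[1L]
    if (!ref %in% lev) stop("reference level '", ref, "' not among levels of '", nm, "'")
    lev <- c(ref, setdiff(lev, ref))      # reference first, original order kept otherwise
    probs <- cv$probs
    if (!is.null(probs)) {
      if (length(probs) != length(cv$levels))
        stop("probs length mismatch for covariate '", nm, "'")
      names(probs) <- as.character(cv$levels)
      probs <- probs[lev]
      if (abs(sum(probs) - 1) > 1e-6) stop("probs of '", nm, "' must sum to 1")
    }
    list(name = nm, levels = lev, reference = ref, probs = probs)
  })
  names(covs) <- names(covariates)
  dummy_cols <- unlist(lapply(covs, function(cv)
    paste(cv$name, sanitize_level(cv$levels[-1L]), sep = "_")), use.names = FALSE)
  structure(list(
    covariates = covs,
    x_cols = c("(Intercept)", dummy_cols, time_col),
    w_cols = dummy_cols,
    time_col = time_col
  ), class = "covariate_design")
}

sanitize_level <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' @export
print.covariate_design <- function(x, ...) {
  cat("Covariate design:", length(x$covariates), "covariates,",
      length(x$w_cols), "indicator columns\n")
  for (cv in x$covariates)
    cat("  ", cv$name, ": ", paste(cv$levels, collapse = ", "),
        " (ref = ", cv$reference, ")\n", sep = "")
  invisible(x)
}

#' Default study design
#'
#' The twelve baseline covariates of the pneumonia cohort with their category
#' codings (first category = reference) and marginal category frequencies
#' taken from the observed cohort of 214 patients, used as sampling
#' probabilities by [simulate_cohort()].
#'
#' @return a [covariate_design()] object.
#' @export
default_design <- function() {
  f <- function(counts, levels) list(levels = levels, probs = counts / 214)
  covariate_design(list(
    sex       = f(c(101, 113), c("female", "male")),
    age       = f(c(95, 36, 41, 42), c("le14", "15_24", "25_64", "ge65")),
    residence = f(c(110, 104), c("urban", "rural")),
    danger    = f(c(110, 104), c("no", "yes")),
    income    = f(c(70, 69, 75), c("le500", "500_1500", "gt1500")),
    comorbid  = f(c(84, 130), c("no", "yes")),
    severity  = f(c(50, 91, 73), c("nonsevere", "mildsevere", "severe")),
    toilet    = f(c(126, 88), c("open", "ventilated")),
    water     = f(c(89, 125), c("piped", "other")),
    symptom   = f(c(44, 103, 67), c("cough", "breathing", "other")),
    occupation = f(c(93, 121), c("unemployed", "employed")),
    famsize   = f(c(135, 79), c("le4", "gt4"))
  ))
}

## indicator encoding of one covariate data frame (rows = subjects) ----------
encode_covariates <- function(design, covdf) {
  stopifnot(inherits(design, "covariate_design"))
  n <- nrow(covdf)
  out <- matrix(0, n, length(design$w_cols),
                dimnames = list(NULL, design$w_cols))
  j <- 0L
  for (cv in design$covariates) {
    if (!cv$name %in% names(covdf))
      stop("covariate column '", cv$name, "' missing from survival table")
    val <- as.character(covdf[[cv$name]])
    bad <- !val %in% cv$levels
    if (any(bad))
      stop("unknown level(s) for covariate '", cv$name, "': ",
           paste(unique(val[bad]), collapse = ", "),
           " (row ", which(bad)[1L], ")")
    for (lev in cv$levels[-1L]) {
      j <- j + 1L
      out[, j] <- as.numeric(val == lev)
    }
  }
  out
}

#' Build design matrices for a cohort
#'
#' Constructs, for each longitudinal outcome k, the fixed-effect matrix
#' `X_k` (intercept, baseline-covariate indicators, visit time in hours) and
#' the random-effect matrix `Z_k` (intercept, visit time: random intercept
#' and slope), and the survival design `W` (baseline indicators only, no
#' intercept -- the baseline hazard carries the reference level).
#'
#' Covariates with a single observed level in the data are dropped from the
#' matrices with a warning; the dropped column names are recorded in the
#' `dropped` component.
#'
#' @param cohort a [read_cohort()] / [simulate_cohort()] cohort.
#' @return a list with components `X` (named list of per-outcome matrices),
#'   `Z` (same shape), `index` (per-outcome data frame of subject id and
#'   time for each row), `W` (n_subjects x q matrix, rownames = subject id),
#'   and `dropped`.
#' @export
build_design <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  design <- cohort$design
  surv <- cohort$surv
  Wfull <- encode_covariates(design, surv)
  rownames(Wfull) <- surv$subject_id

  observed <- apply(Wfull, 2L, function(col) length(unique(col)) > 1L)
  dropped <- colnames(Wfull)[!observed]
  if (length(dropped))
    warning("dropping constant design column(s): ", paste(dropped, collapse = ", "))
  W <- Wfull[, observed, drop = FALSE]

  X <- Z <- index <- list()
  for (k in cohort$outcomes) {
    lk <- cohort$long[cohort$long$outcome == k, , drop = FALSE]
    m <- match(lk$subject_id, surv$subject_id)
    Xk <- cbind(`(Intercept)` = rep(1, nrow(lk)), W[m, , drop = FALSE])
    Xk <- cbind(Xk, lk$time)
    colnames(Xk)[ncol(Xk)] <- design$time_col
    rownames(Xk) <- NULL
    X[[k]] <- Xk
    Z[[k]] <- cbind(`(Intercept)` = 1, time = lk$time)
    index[[k]] <- data.frame(subject_id = lk$subject_id, time = lk$time,
                             stringsAsFactors = FALSE)
  }
  list(X = X, Z = Z, index = index, W = W, dropped = dropped)
}
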