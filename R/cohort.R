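#' Assemble a cohort from longitudinal and survival tables
#'
#' Internal constructor shared by [read_cohort()] and [simulate_cohort()].
#' Longitudinal rows are sorted by subject, outcome and time.
#'
#' @noRd
new_cohort <- function(long, surv, design, outcomes = c("PR", "BT"),
                       validate = TRUE) {
  long <- long[order(long$subject_id, long$outcome, long$time), , drop = FALSE]
  rownames(long) <- rownames(surv) <- NULL
  x <- structure(list(long = long, surv = surv, design = design,
                      outcomes = outcomes), class = "cohort")
  if (validate) validate_cohort(x)
  x
}

#' Read a cohort from delimited text files
#'
#' Reads the longitudinal table (`subject_id, outcome, time_h, value`) and
#' the per-subject survival table (`subject_id, event_time_h, status`, plus
#' one column per declared baseline covariate), both comma-separated with a
#' mandatory header row.  Missing values (empty fields) in required columns
#' are rejected.  All times are hours since admission; `status` is 1 for
#' recovery and 0 for censored.
#'
#' Subjects present only in the survival table are legal (counted in a
#' warning); subjects with longitudinal data but no survival row, negative
#' times, measurements after the subject's event time, or unknown covariate
#' levels are errors.
#'
#' @param long_path,surv_path paths to the two CSV files.
#' @param design a [covariate_design()]; defaults to [default_design()].
#' @return an object of class `cohort` with components `long`, `surv`,
#'   `design`, `outcomes`.
#' @export
read_cohort <- function(long_path, surv_path, design = default_design()) {
  stopifnot(inherits(design, "covariate_design"))
  long_raw <- read.csv(long_path, stringsAsFactors = FALSE)
  surv_raw <- read.csv(surv_path, stringsAsFactors = FALSE)

  need_long <- c("subject_id", "outcome", design$time_col, "value")
  miss <- setdiff(need_long, names(long_raw))
  if (length(miss))
    stop("longitudinal file missing column(s): ", paste(miss, collapse = ", "))
  need_surv <- c("subject_id", "event_time_h", "status",
                 names(design$covariates))
  miss <- setdiff(need_surv, names(surv_raw))
  if (length(miss))
    stop("survival file missing column(s): ", paste(miss, collapse = ", "))

  num <- function(x, what, file) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) | !is.finite(out))
    if (length(bad))
      stop("non-numeric or missing ", what, " in ", file,
           " (row ", bad[1L], ")")
    out
  }
  long <- data.frame(
    subject_id = as.character(long_raw$subject_id),
    outcome    = as.character(long_raw$outcome),
    time       = num(long_raw[[design$time_col]], "time", "longitudinal file"),
    value      = num(long_raw$value, "value", "longitudinal file"),
    stringsAsFactors = FALSE
  )
  surv <- data.frame(
    subject_id = as.character(surv_raw$subject_id),
    event_time = num(surv_raw$event_time_h, "event time", "survival file"),
    status     = num(surv_raw$status, "status", "survival file"),
    stringsAsFactors = FALSE
  )
  for (nm in names(design$covariates)) surv[[nm]] <- as.character(surv_raw[[nm]])

  cohort <- new_cohort(long, surv, design)
  only_surv <- setdiff(surv$subject_id, long$subject_id)
  if (length(only_surv))
    warning(length(only_surv), " subject(s) have survival data only")
  message("read_cohort: ", nrow(long), " longitudinal rows, ",
          nrow(surv), " survival rows, ",
          length(unique(surv$subject_id)), " subjects")
  cohort
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: writes `long.csv` and `surv.csv` with the
#' declared column names at full printed precision (numbers via
#' `format(..., digits = 15)`), so that read-write round-trips preserve the
#' numeric content.
#'
#' @param cohort a cohort object.
#' @param long_path,surv_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, long_path, surv_path) {
  stopifnot(inherits(cohort, "cohort"))
  fmt <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  lo <- data.frame(subject_id = cohort$long$subject_id,
                   outcome = cohort$long$outcome,
                   time_h = fmt(cohort$long$time),
                   value = fmt(cohort$long$value),
                   stringsAsFactors = FALSE)
  names(lo)[3] <- cohort$design$time_col
  su <- cohort$surv
  su$event_time <- fmt(su$event_time)
  names(su)[names(su) == "event_time"] <- "event_time_h"
  write.csv(lo, long_path, row.names = FALSE, quote = FALSE)
  write.csv(su, surv_path, row.names = FALSE, quote = FALSE)
  invisible(c(long = long_path, surv = surv_path))
}

#' Validate a cohort
#'
#' Checks the cohort invariants: status coded 0/1, event times positive,
#' longitudinal times nonnegative and finite values, outcomes among the
#' declared labels, covariate levels declared, every longitudinal subject
#' has exactly one survival row, no longitudinal measurement after the
#' subject's event time, and strictly increasing times per subject and
#' outcome (duplicates are errors).  Hard violations raise an error listing
#' offending subjects; the returned report summarises counts.
#'
#' @param cohort a cohort object.
#' @return invisibly, a list with `n_subjects`, `n_long` (per outcome),
#'   `n_events`, and `violations` (character, empty when clean).
#' @export
validate_cohort <- function(cohort) {
  long <- cohort$long; surv <- cohort$surv
  viol <- character()
  if (anyDuplicated(surv$subject_id))
    viol <- c(viol, paste("duplicated survival rows for:",
              paste(unique(surv$subject_id[duplicated(surv$subject_id)]), collapse = ", ")))
  if (!all(surv$status %in% c(0, 1)))
    viol <- c(viol, "status values outside {0,1}")
  if (any(surv$event_time <= 0))
    viol <- c(viol, paste("nonpositive event time for:",
              paste(surv$subject_id[surv$event_time <= 0], collapse = ", ")))
  if (any(long$time < 0))
    viol <- c(viol, paste("negative longitudinal time for:",
              paste(unique(long$subject_id[long$time < 0]), collapse = ", ")))
  if (any(!is.finite(long$value)))
    viol <- c(viol, "non-finite longitudinal values")
  bad_out <- !long$outcome %in% cohort$outcomes
  if (any(bad_out))
    viol <- c(viol, paste("unknown outcome label(s):",
              paste(unique(long$outcome[bad_out]), collapse = ", ")))

  orphan <- setdiff(long$subject_id, surv$subject_id)
  if (length(orphan))
    viol <- c(viol, paste("longitudinal subjects without survival row:",
              paste(orphan, collapse = ", ")))

  m <- match(long$subject_id, surv$subject_id)
  late <- !is.na(m) & long$time > surv$event_time[m] + 1e-9
  if (any(late))
    viol <- c(viol, paste("measurements after event time for:",
              paste(unique(long$subject_id[late]), collapse = ", ")))

  key <- paste(long$subject_id, long$outcome, long$time, sep = "\r")
  if (anyDuplicated(key))
    viol <- c(viol, paste("duplicated (subject, outcome, time) rows for:",
              paste(unique(long$subject_id[duplicated(key)]), collapse = ", ")))

  # covariate levels
  for (cv in cohort$design$covariates) {
    if (!cv$name %in% names(surv)) {
      viol <- c(viol, paste("missing covariate column:", cv$name))
      next
    }
    bad <- !surv[[cv$name]] %in% cv$levels
    if (any(bad))
      viol <- c(viol, paste0("unknown level(s) of '", cv$name, "': ",
                paste(unique(surv[[cv$name]][bad]), collapse = ", ")))
  }

  if (length(viol))
    stop("cohort validation failed:\n  - ", paste(viol, collapse = "\n  - "))
  rep <- list(
    n_subjects = length(unique(surv$subject_id)),
    n_long = table(factor(long$outcome, levels = cohort$outcomes)),
    n_events = sum(surv$status == 1),
    violations = viol
  )
  invisible(rep)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", length(unique(x$surv$subject_id)), "subjects,",
      nrow(x$long), "longitudinal measurements (",
      paste(x$outcomes, collapse = ", "), ")\n")
  cat("Events:", sum(x$surv$status == 1), "recovered,",
      sum(x$surv$status == 0), "censored\n")
  invisible(x)
}
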