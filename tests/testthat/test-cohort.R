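test_that("toy files parse into a cohort with typed, validated records", {
  dir <- write_toy_files()
  expect_message(
    co <- read_cohort(file.path(dir, "long.csv"), file.path(dir, "surv.csv"),
                      design = toy_design()),
    "4 longitudinal rows, 2 survival rows")
  expect_s3_class(co, "cohort")
  expect_equal(length(unique(co$surv$subject_id)), 2L)
  expect_equal(nrow(co$long), 4L)
  expect_equal(co$long$value[co$long$subject_id == "A" &
                               co$long$outcome == "BT"], 37.9)
})

test_that("survival-only subjects are legal and counted", {
  dir <- write_toy_files()
  surv <- read.csv(file.path(dir, "surv.csv"))
  surv <- rbind(surv, data.frame(subject_id = "C", event_time_h = 12,
                                 status = 1, group = "a"))
  write.csv(surv, file.path(dir, "surv.csv"), row.names = FALSE)
  expect_warning(
    suppressMessages(
      read_cohort(file.path(dir, "long.csv"), file.path(dir, "surv.csv"),
                  design = toy_design())),
    "1 subject\\(s\\) have survival data only")
})

test_that("malformed input is rejected with informative errors", {
  dir <- write_toy_files()
  long <- read.csv(file.path(dir, "long.csv"))

  bad <- long; bad$time_h[2] <- -6
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "bad.csv"),
                           file.path(dir, "surv.csv"), toy_design()),
               "negative longitudinal time")

  bad <- long; bad$value[1] <- ""
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "bad.csv"),
                           file.path(dir, "surv.csv"), toy_design()),
               "non-numeric or missing value")

  bad <- long[, -3]
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "bad.csv"),
                           file.path(dir, "surv.csv"), toy_design()),
               "missing column")

  surv <- read.csv(file.path(dir, "surv.csv"))
  surv$group[1] <- "zz"
  write.csv(surv, file.path(dir, "bads.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "long.csv"),
                           file.path(dir, "bads.csv"), toy_design()),
               "unknown level")
})

test_that("cohort invariants are enforced as hard errors", {
  sim <- toy_cohort(n = 4, seed = 1)
  co <- sim$cohort
  expect_silent(rep <- validate_cohort(co))
  expect_length(validate_cohort(co)$violations, 0L)

  bad <- co
  bad$long$time[1] <- bad$surv$event_time[1] + 10   # after the event
  expect_error(validate_cohort(bad), "after event time")

  bad <- co
  bad$long <- rbind(bad$long, bad$long[1, ])        # duplicate row
  expect_error(validate_cohort(bad), "duplicated \\(subject, outcome, time\\)")

  bad <- co
  bad$surv <- bad$surv[-1, ]                        # orphan longitudinal rows
  expect_error(validate_cohort(bad), "without survival row")

  bad <- co
  bad$surv$status[1] <- 2
  expect_error(validate_cohort(bad), "status")
})

test_that("design matrices follow the reference-level dummy coding", {
  sim <- simulate_cohort(sim_config(n_subjects = 40, seed = 5))
  des <- build_design(sim$cohort)
  # 1 intercept + sum(L_c - 1) indicators + 1 time column
  n_dummies <- sum(vapply(default_design()$covariates,
                          function(cv) length(cv$levels) - 1L, 1L))
  expect_equal(ncol(des$X$PR), 1L + n_dummies + 1L)
  expect_equal(ncol(des$X$PR), 19L)
  expect_named(des$Z$PR, NULL)
  expect_equal(colnames(des$Z$PR), c("(Intercept)", "time"))
  expect_equal(colnames(des$X$PR)[2:5],
               c("sex_male", "age_15_24", "age_25_64", "age_ge65"))
  # W: dummies only, no intercept, no time
  expect_equal(ncol(des$W), n_dummies)
  expect_false("(Intercept)" %in% colnames(des$W))

  # a subject at all reference levels encodes as (1, 0, ..., 0, t)
  ref <- sim$cohort
  ref$surv[1, names(default_design()$covariates)] <-
    vapply(default_design()$covariates, function(cv) cv$reference, "")
  des2 <- build_design(ref)
  id1 <- ref$surv$subject_id[1]
  row1 <- des2$X$PR[des2$index$PR$subject_id == id1, ][1, ]
  expect_equal(unname(row1[2:18]), rep(0, 17))
  expect_equal(unname(row1[1]), 1)
  expect_equal(unname(row1[19]), des2$index$PR$time[des2$index$PR$subject_id == id1][1])
})

test_that("encoding is invariant to input row order", {
  sim <- toy_cohort(n = 6, seed = 7)
  co <- sim$cohort
  des1 <- build_design(co)
  perm <- co
  set.seed(1)
  perm$long <- perm$long[sample(nrow(perm$long)), ]
  ords <- sample(nrow(perm$surv))
  perm$surv <- perm$surv[ords, ]
  perm <- jointvitals:::new_cohort(perm$long, perm$surv, perm$design)
  des2 <- build_design(perm)
  for (k in c("PR", "BT")) {
    key1 <- paste(des1$index[[k]]$subject_id, des1$index[[k]]$time)
    key2 <- paste(des2$index[[k]]$subject_id, des2$index[[k]]$time)
    expect_equal(des2$X[[k]][match(key1, key2), ], des1$X[[k]],
                 ignore_attr = TRUE)
  }
})

test_that("write_cohort / read_cohort round-trips numeric content exactly", {
  sim <- toy_cohort(n = 5, seed = 11)
  dir <- tempfile(); dir.create(dir)
  write_cohort(sim$cohort, file.path(dir, "l.csv"), file.path(dir, "s.csv"))
  co2 <- suppressWarnings(suppressMessages(
    read_cohort(file.path(dir, "l.csv"), file.path(dir, "s.csv"),
                design = toy_design())))
  expect_equal(co2$long$value, sim$cohort$long$value)
  expect_equal(co2$long$time, sim$cohort$long$time)
  expect_equal(co2$surv$event_time, sim$cohort$surv$event_time)
  expect_equal(co2$surv$status, sim$cohort$surv$status)
  expect_equal(co2$surv$group, sim$cohort$surv$group)
})
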