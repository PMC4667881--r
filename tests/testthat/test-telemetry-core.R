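test_that("series constructor enforces the data-model invariants", {
  t0 <- as.POSIXct("2015-03-02 06:00", tz = "UTC")
  expect_error(telemetry_series("r1", "control", t0, c(37, 37), c(0L)),
               "equal length")
  expect_error(telemetry_series("r1", "control", t0, c(37, 45), c(0L, 1L)),
               "outside")
  expect_error(telemetry_series("r1", "control", t0, c(37, 37), c(0L, -1L)),
               "non-negative")
  expect_error(telemetry_series("r1", "badgroup", t0, 37, 0L))
  ev <- data.frame(time = t0 + 3600, kind = "feeding")
  expect_error(telemetry_series("r1", "control", t0, rep(37, 120),
                                rep(0L, 120), events = ev),
               "unknown event kind")
  ev_out <- data.frame(time = t0 + 86400 * 10, kind = "handling")
  expect_error(telemetry_series("r1", "control", t0, rep(37, 120),
                                rep(0L, 120), events = ev_out),
               "time span")
  # events are sorted on construction
  ev2 <- data.frame(time = t0 + c(7200, 3600), kind = c("handling", "injection"))
  s <- telemetry_series("r1", "control", t0, rep(37, 240), rep(0L, 240),
                        events = ev2)
  expect_equal(s$events$kind, c("injection", "handling"))
})

test_that("CSV round-trip preserves values and missingness flags", {
  cohort <- simulate_cohort(tiny_config())
  # punch some holes to exercise the missing-value policy
  s <- cohort$series[[1]]
  s$temperature[c(5, 100, 101)] <- NA
  s$activity[c(7, 300)] <- NA
  cohort$series[[1]] <- s
  tf <- tempfile(fileext = ".csv")
  ef <- tempfile(fileext = ".csv")
  write_telemetry_csv(cohort$series, tf, events_path = ef)
  back <- read_telemetry_csv(tf, events_path = ef)
  expect_setequal(names(back), names(cohort$series))
  for (id in names(cohort$series)) {
    expect_equal(back[[id]]$temperature, cohort$series[[id]]$temperature,
                 tolerance = 1e-9)
    expect_identical(is.na(back[[id]]$temperature),
                     is.na(cohort$series[[id]]$temperature))
    expect_identical(back[[id]]$activity, cohort$series[[id]]$activity)
    expect_identical(back[[id]]$group, cohort$series[[id]]$group)
    expect_equal(nrow(back[[id]]$events), nrow(cohort$series[[id]]$events))
  }
  # a gap in the minute grid reads back as missing samples
  df <- utils::read.csv(tf, comment.char = "#")
  df <- df[-10, ]  # drop one minute of the first animal
  tf2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, tf2, row.names = FALSE, na = "")
  back2 <- read_telemetry_csv(tf2)
  expect_length(back2[[1]]$temperature, length(cohort$series[[1]]$temperature))
  expect_true(is.na(back2[[1]]$temperature[10]))
})

test_that("reader rejects malformed files and flags bad cells", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,group,timestamp,temperature_c",
               "r1,control,2015-03-02T06:00,37.0"), tf)
  expect_error(read_telemetry_csv(tf), "activity_counts")

  writeLines(c("animal_id,group,timestamp,temperature_c,activity_counts",
               "r1,control,2015-03-02T06:00,37.0,0",
               "r1,control,2015-03-02T06:00,37.1,2"), tf)
  expect_error(read_telemetry_csv(tf), "duplicate")

  writeLines(c("animal_id,group,timestamp,temperature_c,activity_counts",
               "r1,control,2015-03-02T06:00,37.0,0",
               "r1,control,2015-03-02T06:01,oops,1",
               "r1,control,2015-03-02T06:02,37.2,2"), tf)
  expect_warning(out <- read_telemetry_csv(tf), "1 malformed")
  expect_identical(sum(is.na(out$r1$temperature)), 1L)
})

test_that("phase splitting partitions complete days into 720-sample halves", {
  cfg <- tiny_config()
  s <- simulate_cohort(cfg)$series[[1]]
  recs <- split_phases(s)
  expect_length(recs, 2 * cfg$n_days)
  expect_true(all(vapply(recs, function(r) length(r$temperature),
                         integer(1)) == 720L))
  expect_false(any(vapply(recs, `[[`, logical(1), "partial")))
  # light + dark tile each day with no overlap or gap
  expect_identical(sum(lengths(lapply(recs, `[[`, "temperature"))),
                   length(s$temperature))
  phases <- vapply(recs, `[[`, character(1), "phase")
  expect_identical(sum(phases == "light"), sum(phases == "dark"))
})

test_that("a series starting mid-phase yields a flagged partial window", {
  s <- make_series(rep(37, 1440), start = "2015-03-02 12:00")
  recs <- split_phases(s)
  expect_identical(length(recs[[1]]$temperature), 360L)
  expect_true(recs[[1]]$partial)
  expect_identical(recs[[1]]$phase, "light")
  # the following dark window is complete
  expect_identical(length(recs[[2]]$temperature), 720L)
  expect_false(recs[[2]]$partial)
  # dark phase is attributed to the day it starts on
  expect_identical(recs[[2]]$date, as.Date("2015-03-02"))
})

test_that("condition labelling marks whole event days as disturbed", {
  cfg <- tiny_config()  # handling on day 3
  cohort <- simulate_cohort(cfg)
  recs <- label_conditions(split_phases(cohort$series[[1]]), cohort$events)
  cond <- vapply(recs, `[[`, character(1), "condition")
  dates <- as.Date(vapply(recs, function(r) format(r$date), character(1)))
  event_day <- cfg$start_date + 2
  expect_true(all(cond[dates == event_day] == "disturbed"))
  expect_true(all(cond[dates != event_day] == "undisturbed"))
})

test_that("pooling is a pure idempotent filter ordered by animal and date", {
  cfg <- tiny_config()
  cohort <- simulate_cohort(cfg)
  recs <- list()
  for (s in cohort$series)
    recs <- c(recs, label_conditions(split_phases(s), cohort$events))
  pooled <- pool_recordings(recs, phase = "dark", condition = "undisturbed")
  # 4 animals x 2 undisturbed days
  expect_length(pooled, 8L)
  expect_identical(pool_recordings(pooled, phase = "dark",
                                   condition = "undisturbed"), pooled)
  ids <- vapply(pooled, `[[`, character(1), "animal_id")
  expect_identical(ids, sort(ids))
  expect_message(
    empty <- pool_recordings(recs, phase = "dark", condition = "disturbed",
                             max_missing_frac = -1),
    "no recordings")
  expect_length(empty, 0L)
})

test_that("recordings exceeding the missingness threshold are excluded", {
  s <- make_series(rep(37, 1440), rep(0L, 1440))
  recs <- label_conditions(split_phases(s), empty_events_df())
  # 5% of 720 = 36; 37 missing crosses the default threshold
  recs[[1]]$temperature[1:37] <- NA
  recs[[2]]$temperature[1:36] <- NA
  pooled <- pool_recordings(recs)
  expect_length(pooled, 1L)
  expect_identical(pooled[[1]]$phase, "dark")
})
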