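test_that("compliance ratio counts distinct test days over possible days", {
  # 16 distinct days in a 30-day month: ratio 16/30, criterion met
  days <- as.Date("2026-09-01") + 0:15
  r <- compliance_ratio(days, "2026-09", as_of = as.Date("2026-10-05"))
  expect_equal(r$ratio, 16 / 30, tolerance = 1e-12)
  expect_true(r$min16of30_met)

  # no tests
  r0 <- compliance_ratio(as.Date(character(0)), "2026-09",
                         as_of = as.Date("2026-10-01"))
  expect_equal(r0$ratio, 0)
  expect_false(r0$min16of30_met)

  # two tests on the same day count once
  same <- as.POSIXct(c("2026-09-03 08:00:00", "2026-09-03 19:00:00"), tz = "UTC")
  r1 <- compliance_ratio(same, "2026-09", as_of = as.Date("2026-10-01"))
  expect_equal(r1$test_days, 1L)

  # in-progress month: denominator is days elapsed
  r2 <- compliance_ratio(as.Date("2026-09-01") + 0:9, "2026-09",
                         as_of = as.Date("2026-09-10"))
  expect_equal(r2$possible_days, 10L)
  expect_equal(r2$ratio, 1)

  expect_error(compliance_ratio(days, "September"), "YYYY-MM")
  expect_error(compliance_ratio(days, "2026-09", as_of = as.Date("2026-08-01")),
               "not started")
})

test_that("a nominal control session scores high with normal flags", {
  ref <- default_reference()
  sim <- simulate_trace(simulation_params(), seed = 11,
                        meta = list(subject_id = "S1", age_years = 60,
                                    session_time = "2026-09-01T09:00:00"))
  panel <- analyze_session(sim$trace, ref)
  expect_equal(panel$status, "ok")
  expect_gte(panel$mobility_score, 90)
  expect_equal(panel$tremor_severity, 0)
  expect_true(all(panel$panel$flag == "normal"))
  expect_equal(panel$dashboard$hand, "R")
  expect_equal(panel$dashboard$arrhythmicity_pct,
               100 * panel$hand_metrics$isi_cv)
})

test_that("a severely bradykinetic session scores low with abnormal amplitude", {
  ref <- default_reference()
  p <- simulation_params(base_amplitude_mm = 2, isi_mean_s = 1.1,
                         press_duration_s = 0.25, release_duration_s = 0.25,
                         dwell_s = 0.15, amplitude_decay_per_tap = 0.02,
                         isi_cv = 0.15)
  sim <- simulate_trace(p, seed = 12, meta = list(age_years = 65))
  panel <- analyze_session(sim$trace, ref)
  expect_equal(panel$status, "ok")
  expect_lt(panel$mobility_score, 50)
  expect_equal(panel$dashboard$press_amplitude_flag, "abnormal")
})

test_that("a flat trace is insufficient performance, not an error", {
  t <- seq(0, 29.99, by = 0.01)
  flat <- raft_trace(t, rep(0, 3000), rep(0, 3000), 100, "R")
  panel <- analyze_session(flat, default_reference())
  expect_equal(panel$status, "insufficient_performance")
  expect_true(is.na(panel$mobility_score))
  expect_null(panel$panel)
})

test_that("analyze_session equals the composition of independent stage calls", {
  ref <- default_reference()
  sim <- simulate_trace(simulation_params(tremor_pct_target = 9), seed = 31,
                        meta = list(age_years = 70))
  panel <- analyze_session(sim$trace, ref)

  st <- classify_strikes(detect_strikes(sim$trace), sim$trace)
  hm <- hand_metrics(st, trace_duration(sim$trace))
  const <- ref$constants
  z <- vapply(c("isi_s", "isi_cv", "press_speed_mm_s", "press_amplitude_mm",
                "press_amplitude_cv", "release_slope_mm_s"), function(m) {
    e <- ref$metrics[[m]]
    adj <- age_adjust(hm[[m]], 70, e$age_slope, const$reference_age_years)
    directional_z(adj, e$mean, e$sd, e$direction)
  }, numeric(1))
  z[["press_amplitude_mm"]] <- transform_press_amp_z(z[["press_amplitude_mm"]],
                                                     const)
  expect_equal(panel$mobility_score, mobility_score(z, const))
  ts <- tremor_summary(st, trace_duration(sim$trace))
  expect_equal(panel$tremor_severity,
               tremor_severity(ts$rest_tremor_pct, ts$tremor_amplitudes_mm,
                               const))
  expect_equal(panel$hand_metrics$press_amplitude_mm, hm$press_amplitude_mm)
})

test_that("session reports serialize deterministically", {
  ref <- default_reference()
  sim <- simulate_trace(simulation_params(), seed = 41,
                        meta = list(subject_id = "S2", age_years = 58,
                                    session_time = "2026-09-02T10:00:00"))
  panel <- analyze_session(sim$trace, ref)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_session_report(panel, p1)
  write_session_report(analyze_session(sim$trace, ref), p2)
  expect_identical(readLines(p1), readLines(p2))
  parsed <- jsonlite::fromJSON(p1)
  expect_equal(parsed$schema, "qdg-session/1")
  expect_equal(parsed$mobility_score, panel$mobility_score)
})

test_that("timeseries report builds daily series and adherence deltas", {
  ref <- default_reference()
  panels <- lapply(1:3, function(i) {
    sim <- simulate_trace(simulation_params(duration_s = 15), seed = 50 + i,
                          meta = list(age_years = 60,
                                      session_time = sprintf("2026-09-%02dT09:00:00", i)))
    analyze_session(sim$trace, ref)
  })
  meds <- data.frame(
    name = c("CD/LD 25/100", "CD/LD 25/100", "CD/LD 25/100"),
    dose = "1 tab",
    prescribed_time = as.POSIXct(c("2026-09-01 09:00:00", "2026-09-02 09:00:00",
                                   "2026-09-03 09:00:00"), tz = "UTC"),
    actual_time = as.POSIXct(c("2026-09-01 09:25:00", NA,
                               "2026-09-03 08:50:00"), tz = "UTC"))
  rep <- timeseries_report(panels, meds)
  expect_equal(length(unique(rep$metrics$date)), 3)
  mob <- rep$metrics[rep$metrics$metric == "mobility_score", ]
  expect_equal(nrow(mob), 3)
  expect_false(is.unsorted(rep$metrics$date))
  # dose taken 25 min late -> +25; 10 min early -> -10; one missed
  expect_equal(rep$adherence$delta_min, c(25, -10))
  expect_equal(nrow(rep$missed_doses), 1)
  # no medication events -> empty adherence
  rep2 <- timeseries_report(panels)
  expect_equal(nrow(rep2$adherence), 0)
  expect_error(timeseries_report(list()), "no successfully analyzed")
})

test_that("session logs parse from JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "subject_id": "S7",
    "more_affected_hand": "L",
    "tests": [
      {"timestamp": "2026-09-01T08:30:00", "hand": "L", "trace_path": "a.csv"},
      {"timestamp": "2026-09-02T08:40:00", "hand": "R", "trace_path": "b.csv"}
    ],
    "medication_events": [
      {"name": "CD/LD", "dose": "1", "prescribed_time": "2026-09-01T09:00:00",
       "actual_time": "2026-09-01T09:10:00"}
    ]
  }', path)
  log <- read_session_log(path)
  expect_equal(log$subject_id, "S7")
  expect_equal(nrow(log$tests), 2)
  expect_s3_class(log$tests$timestamp, "POSIXct")
  expect_equal(as.numeric(difftime(log$medication_events$actual_time,
                                   log$medication_events$prescribed_time,
                                   units = "mins")), 10)
})
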