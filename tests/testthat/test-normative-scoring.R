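test_that("age slope estimation recovers known slopes", {
  # noiseless one-observation-per-subject: exact OLS limit
  ages <- 50:70
  expect_equal(fit_age_slope(3 + 0.01 * ages, ages, paste0("s", ages)), 0.01,
               tolerance = 1e-8)

  # age-independent values: slope indistinguishable from zero
  set.seed(8)
  v <- rnorm(60)
  a <- runif(60, 45, 80)
  sl <- fit_age_slope(v, a, paste0("s", 1:60))
  se <- summary(lm(v ~ a))$coefficients["a", "Std. Error"]
  expect_lt(abs(sl), 2 * se)

  # random-intercept recovery: slope 0.02, intercept SD 1, noise SD 0.5,
  # 40 subjects x 2 sessions
  set.seed(16)
  subj <- rep(1:40, each = 2)
  ages2 <- rep(runif(40, 45, 80), each = 2)
  vals <- 5 + 0.02 * ages2 + rep(rnorm(40, 0, 1), each = 2) + rnorm(80, 0, 0.5)
  sl2 <- fit_age_slope(vals, ages2, subj)
  expect_lt(abs(sl2 - 0.02) / 0.02, 0.25)

  expect_error(fit_age_slope(1:5, rep(60, 5), 1:5), "degenerate")
})

test_that("age adjustment maps values to the reference age", {
  expect_equal(age_adjust(1.0, 60, 0.01), 1.0)
  expect_equal(age_adjust(1.0, 70, 0), 1.0)
  expect_equal(age_adjust(1.00, 70, 0.01), 0.90)
  expect_equal(age_adjust(1.00, 50, 0.01), 1.10)
  expect_error(age_adjust(1, -5, 0.01), "non-negative")
})

test_that("directional z flips lower-worse metrics and floors at zero", {
  expect_equal(directional_z(8.67, 8.67, 0.12, "lower_worse"), 0)
  # press amplitude 8.43 vs mean 8.67 sd 0.12: raw z -2 -> +2
  expect_equal(directional_z(8.43, 8.67, 0.12, "lower_worse"), 2)
  # above-average amplitude is capped at 0, not credited
  expect_equal(directional_z(9.0, 8.67, 0.12, "lower_worse"), 0)
  # isi one sd above mean: 1.0, no flip
  expect_equal(directional_z(0.55, 0.5, 0.05, "higher_worse"), 1)
  expect_equal(directional_z(0.45, 0.5, 0.05, "higher_worse"), 0)
  expect_error(directional_z(1, 1, 0, "higher_worse"), "positive")
})

test_that("press-amplitude transform is identity below 10, continuous, capped at 20", {
  const <- scoring_constants()
  expect_equal(transform_press_amp_z(5, const), 5)
  expect_equal(transform_press_amp_z(0, const), 0)
  # continuity at the transition: A * 10^k within 0.05 of 10
  expect_lt(abs(const$pa_transform_A * 10^const$pa_transform_k - 10), 0.05)
  just_above <- transform_press_amp_z(10 + 1e-9, const)
  expect_lt(abs(just_above - transform_press_amp_z(10, const)), 0.05)
  # amplitude 0 under control mean 8.67 sd 0.12: z = 72.25, power law ~26.6,
  # clamp binds at 20
  z0 <- directional_z(0, 8.67, 0.12, "lower_worse")
  expect_equal(z0, 72.25, tolerance = 1e-9)
  expect_gt(const$pa_transform_A * z0^const$pa_transform_k, 20)
  expect_equal(transform_press_amp_z(z0, const), 20)
  # continuity and boundedness on a dense grid
  grid <- seq(0, 100, by = 0.01)
  tz <- transform_press_amp_z(grid, const)
  expect_true(all(tz <= 20 + 1e-12))
  expect_true(all(diff(tz) >= -1e-9))       # monotone non-decreasing
  expect_lt(max(abs(diff(tz))), 0.06)       # no jumps anywhere
  expect_error(transform_press_amp_z(-1, const), "non-negative")
})

test_that("mobility score is 100 minus 14 times the mean z, clamped", {
  expect_equal(mobility_score(mobility_z(0)), 100)
  expect_equal(mobility_score(mobility_z(1)), 86)
  expect_equal(mobility_score(mobility_z(8)), 0)
  z <- mobility_z(0); z["isi_s"] <- 3
  expect_equal(mobility_score(z), 100 - 14 * 3 / 6)
  expect_error(mobility_score(mobility_z(1)[-1]), "missing metric")
  expect_error(mobility_score(mobility_z(-1)), "non-negative")

  # monotone non-increasing in every directional z
  base <- mobility_z(0.5)
  s0 <- mobility_score(base)
  for (m in names(base)) {
    up <- base; up[m] <- up[m] + 0.7
    expect_lte(mobility_score(up), s0)
  }
})

test_that("tremor severity combines percent and squared normalized amplitude", {
  const <- scoring_constants()
  expect_equal(tremor_severity(0, numeric(0), const), 0)
  # pct 20, all amplitudes AmpMax/2: 20 + 100 * 0.25 = 45 (no suppression)
  expect_equal(tremor_severity(20, rep(const$amp_max_mm / 2, 5), const), 45)
  # pct 18, uniform 5.7 mm, AmpMax 12.5: 18 + 100*(5.7/12.5)^2 = 38.79
  expect_equal(tremor_severity(18, rep(5.7, 10), const),
               18 + 100 * (5.7 / 12.5)^2, tolerance = 1e-9)
  # low-tremor suppression: factor 4^(0.05*pct - 1) on the amplitude part
  pct <- 4
  comp <- 100 * (5.7 / 12.5)^2
  expect_equal(tremor_severity(pct, rep(5.7, 3), const),
               pct + comp * 4^(0.05 * pct - 1))
  # suppression modes
  expect_equal(tremor_severity(pct, rep(5.7, 3), const, mode = "none"),
               pct + comp)
  expect_equal(tremor_severity(pct, rep(5.7, 3), const, mode = "replace"),
               pct + 100 * 4^(0.05 * pct - 1))
  # no tremor strikes: score equals pct
  expect_equal(tremor_severity(7, numeric(0), const), 7)
  expect_error(tremor_severity(120, numeric(0), const), "0, 100")
  expect_error(tremor_severity(10, 13, const), "amp_max")

  # monotone in pct and in each amplitude
  s0 <- tremor_severity(15, c(3, 4), const)
  expect_gte(tremor_severity(16, c(3, 4), const), s0)
  expect_gte(tremor_severity(15, c(3.5, 4), const), s0)
})

test_that("reference building stores adjusted means, SDs and percentile thresholds", {
  cohort <- simulate_control_metrics(400, seed = 17)
  ref <- build_reference(cohort)
  expect_s3_class(ref, "qdg_reference")
  # directions as specified
  expect_equal(ref$metrics$press_amplitude_mm$direction, "lower_worse")
  expect_equal(ref$metrics$isi_cv$direction, "higher_worse")
  expect_equal(ref$metrics$taps_per_minute$direction, "lower_worse")
  # thresholds sit at the stated percentile of adjusted control values
  for (m in c("press_amplitude_mm", "isi_cv")) {
    e <- ref$metrics[[m]]
    adj <- age_adjust(cohort[[m]], cohort$age_years, e$age_slope, 60)
    q <- if (e$direction == "lower_worse") 0.25 else 0.75
    expect_equal(e$threshold, unname(quantile(adj, q, type = 7)))
  }
  # the three age-affected metrics carry non-trivial slopes; others are 0
  expect_lt(ref$metrics$press_speed_mm_s$age_slope, 0)
  expect_equal(ref$metrics$isi_cv$age_slope, 0)
  # mobility reference exists with a 25th-percentile threshold
  expect_true(is.finite(ref$metrics$mobility_score$threshold))

  # degenerate inputs
  flat <- cohort; flat$isi_cv <- 0.05
  expect_error(build_reference(flat), "zero variance")
  expect_error(build_reference(cohort[cohort$subject_id == "HC00001", ]),
               "at least 2")
  same_age <- cohort; same_age$age_years <- 60
  ref2 <- build_reference(same_age)
  expect_equal(ref2$metrics$press_speed_mm_s$age_slope, 0)
})

test_that("metric flags mark values beyond the control quartiles", {
  cohort <- simulate_control_metrics(500, seed = 23)
  ref <- build_reference(cohort)
  thr <- ref$metrics$press_amplitude_mm$threshold
  expect_equal(flag_metric(thr, "press_amplitude_mm", ref), "normal") # tie rule
  expect_equal(flag_metric(2.0, "press_amplitude_mm", ref), "abnormal")
  expect_equal(flag_metric(9.5, "press_amplitude_mm", ref), "normal")
  med <- median(cohort$isi_cv)
  expect_equal(flag_metric(med, "isi_cv", ref), "normal")
  expect_equal(flag_metric(0.5, "isi_cv", ref), "abnormal")
  expect_error(flag_metric(1, "unknown_metric", ref), "reference")
})

test_that("about a quarter of the control cohort flags abnormal per metric", {
  cohort <- simulate_control_metrics(10000, seed = 31)
  ref <- build_reference(cohort)
  for (m in c("press_amplitude_mm", "press_amplitude_cv", "isi_s", "isi_cv",
              "press_speed_mm_s", "release_slope_mm_s", "taps_per_minute")) {
    e <- ref$metrics[[m]]
    adj <- age_adjust(cohort[[m]], cohort$age_years, e$age_slope, 60)
    rate <- mean(vapply(adj, flag_metric, character(1), metric = m,
                        reference = ref) == "abnormal")
    expect_gte(rate, 0.24)
    expect_lte(rate, 0.26)
  }
})

test_that("reference JSON round-trips", {
  ref <- build_reference(simulate_control_metrics(100, seed = 41))
  path <- withr::local_tempfile(fileext = ".json")
  write_reference(ref, path)
  back <- read_reference(path)
  expect_equal(back$n_subjects, ref$n_subjects)
  for (m in names(ref$metrics)) {
    expect_equal(back$metrics[[m]]$mean, ref$metrics[[m]]$mean, info = m)
    expect_equal(back$metrics[[m]]$threshold, ref$metrics[[m]]$threshold,
                 info = m)
  }
  expect_equal(unclass(back$constants), unclass(ref$constants))
  expect_error(read_reference(withr::local_tempfile()), "not found")
})
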