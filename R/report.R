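#' Monthly testing compliance ratio
#'
#' Number of distinct calendar days in the month with at least one completed
#' test, divided by the number of possible test days: the full month length
#' if the month has passed, or the days elapsed through `as_of` for an
#' in-progress month. Multiple tests on one day count once; the count is per
#' subject-day, not per hand. Also checks the remote-monitoring
#' reimbursement criterion: at least 16 distinct test days within some
#' 30-day window of the full testing record.
#'
#' @param test_times Test timestamps (`POSIXct` or `Date`).
#' @param month Month as `"YYYY-MM"`.
#' @param as_of Reference date for in-progress months (default: today).
#' @return A list: `ratio`, `test_days`, `possible_days`,
#'   `min16of30_met` (logical), `best_30day_days` (max distinct test days in
#'   any 30-day window).
#' @examples
#' days <- as.Date("2026-09-01") + seq(0, 29, by = 2)
#' compliance_ratio(days, "2026-09", as_of = as.Date("2026-09-30"))
#' @export
compliance_ratio <- function(test_times, month, as_of = Sys.Date()) {
  if (!is.character(month) || length(month) != 1L ||
      !grepl("^\\d{4}-\\d{2}$", month)) {
    stop("month must be a 'YYYY-MM' string", call. = FALSE)
  }
  first <- as.Date(paste0(month, "-01"))
  if (is.na(first)) stop("invalid month: ", month, call. = FALSE)
  last <- seq(first, by = "1 month", length.out = 2L)[2L] - 1L
  as_of <- as.Date(as_of)
  if (as_of < first) stop("month has not started as of ", as_of, call. = FALSE)
  possible <- if (as_of >= last) as.integer(last - first + 1L)
              else as.integer(as_of - first + 1L)

  dates <- unique(as.Date(test_times))
  dates <- dates[!is.na(dates)]
  in_month <- dates[dates >= first & dates <= last]
  test_days <- length(in_month)

  best <- 0L
  if (length(dates)) {
    dates <- sort(dates)
    for (i in seq_along(dates)) {
      best <- max(best, sum(dates >= dates[i] & dates < dates[i] + 30L))
    }
  }
  list(ratio = test_days / possible,
       test_days = test_days,
       possible_days = possible,
       min16of30_met = best >= 16L,
       best_30day_days = as.integer(best))
}

#' Analyze one RAFT session end to end
#'
#' Composes the pipeline stages — [detect_strikes()], [classify_strikes()],
#' [hand_metrics()], z-scoring against the reference, the Mobility and
#' Tremor Severity Scores, and normal/abnormal flags — into a session
#' score panel plus a machine-readable dashboard record. The composition is
#' stateless: calling the stages independently with the same inputs yields
#' the same numbers.
#'
#' A session whose detection yields fewer than 2 voluntary strikes on
#' either finger is returned with `status = "insufficient_performance"`
#' and no metrics or scores (the at-home workflow would prompt a redo).
#'
#' @param trace A [raft_trace]; its `meta$age_years`, when present, drives
#'   age adjustment (otherwise values are compared unadjusted, i.e. at the
#'   reference age).
#' @param reference A `qdg_reference` ([build_reference()] or
#'   [default_reference()]).
#' @param classifier A [tremor_classifier()].
#' @param detection A [detection_config()].
#' @param tremor_mode Low-tremor suppression mode for [tremor_severity()].
#' @return An object of class `qdg_score_panel`: `status`, `hand_metrics`,
#'   `strikes`, per-metric table `panel` (raw, adjusted, raw z, directional
#'   z, transformed z, flag), `mobility_score`, `tremor_severity`,
#'   `dashboard` (named record mirroring the session dashboard fields).
#' @export
analyze_session <- function(trace, reference = default_reference(),
                            classifier = tremor_classifier(),
                            detection = detection_config(),
                            tremor_mode = "multiplicative") {
  stopifnot(inherits(trace, "raft_trace"), inherits(reference, "qdg_reference"))
  const <- reference$constants
  strikes <- detect_strikes(trace, detection)
  strikes <- classify_strikes(strikes, trace, classifier)
  dur <- trace_duration(trace)

  vol <- strikes[!strikes$is_tremor, , drop = FALSE]
  enough <- sum(vol$lever == "index") >= 2L && sum(vol$lever == "middle") >= 2L
  if (!enough) {
    return(structure(list(status = "insufficient_performance",
                          hand_metrics = NULL, strikes = strikes,
                          panel = NULL, mobility_score = NA_real_,
                          tremor_severity = NA_real_, dashboard = NULL),
                     class = "qdg_score_panel"))
  }

  hm <- hand_metrics(strikes, dur)
  age <- trace$meta$age_years
  if (is.null(age)) age <- const$reference_age_years

  rows <- lapply(setdiff(.qdg_reference_metrics, "mobility_score"), function(m) {
    e <- reference$metrics[[m]]
    raw <- hm[[m]]
    adj <- age_adjust(raw, age, e$age_slope, const$reference_age_years)
    rawz <- (adj - e$mean) / e$sd
    dz <- directional_z(adj, e$mean, e$sd, e$direction)
    tz <- if (m == "press_amplitude_mm") transform_press_amp_z(dz, const)
          else NA_real_
    data.frame(metric = m, raw = raw, adjusted = adj, raw_z = rawz,
               directional_z = dz, transformed_z = tz,
               flag = flag_metric(adj, m, reference),
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)

  z <- stats::setNames(panel$directional_z, panel$metric)[.qdg_mobility_metrics]
  z[["press_amplitude_mm"]] <-
    panel$transformed_z[panel$metric == "press_amplitude_mm"]
  mob <- mobility_score(z, const)

  ts <- tremor_summary(strikes, dur)
  sev <- tremor_severity(ts$rest_tremor_pct,
                         pmin(ts$tremor_amplitudes_mm, const$amp_max_mm),
                         const, mode = tremor_mode)

  mob_flag <- flag_metric(mob, "mobility_score", reference)
  pf <- function(m) panel$flag[panel$metric == m]
  pv <- function(m) panel$raw[panel$metric == m]
  dashboard <- list(
    subject_id = trace$meta$subject_id,
    session_time = trace$meta$session_time,
    therapy_state = trace$meta$therapy_state,
    hand = trace$hand,
    taps_per_minute = pv("taps_per_minute"),
    taps_per_minute_flag = pf("taps_per_minute"),
    press_amplitude_mm = pv("press_amplitude_mm"),
    press_amplitude_flag = pf("press_amplitude_mm"),
    press_speed_mm_s = pv("press_speed_mm_s"),
    press_speed_flag = pf("press_speed_mm_s"),
    press_amplitude_cv = pv("press_amplitude_cv"),
    press_amplitude_cv_flag = pf("press_amplitude_cv"),
    release_speed_mm_s = pv("release_slope_mm_s"),
    release_speed_flag = pf("release_slope_mm_s"),
    isi_s = pv("isi_s"),
    isi_flag = pf("isi_s"),
    arrhythmicity_pct = 100 * pv("isi_cv"),
    arrhythmicity_flag = pf("isi_cv"),
    dwell_time_s = hm$dwell_time_s,
    rest_tremor_pct = ts$rest_tremor_pct,
    mean_tremor_amplitude_mm = ts$mean_tremor_amplitude_mm,
    mobility_score = mob,
    mobility_flag = mob_flag,
    tremor_severity = sev
  )

  structure(list(status = "ok", hand_metrics = hm, strikes = strikes,
                 panel = panel, mobility_score = mob, tremor_severity = sev,
                 dashboard = dashboard),
            class = "qdg_score_panel")
}

#' @export
print.qdg_score_panel <- function(x, ...) {
  if (x$status != "ok") {
    cat("QDG session:", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("QDG session (%s hand): Mobility %.1f, Tremor Severity %.1f\n",
              x$dashboard$hand, x$mobility_score, x$tremor_severity))
  p <- x$panel
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-20s %9.3f  z %6.2f  [%s]\n", p$metric[i], p$raw[i],
                p$directional_z[i], p$flag[i]))
  }
  invisible(x)
}

#' Write a session score panel as versioned JSON
#'
#' @param panel A `qdg_score_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_report <- function(panel, path) {
  stopifnot(inherits(panel, "qdg_score_panel"))
  payload <- list(schema = "qdg-session/1",
                  status = panel$status,
                  dashboard = panel$dashboard,
                  panel = panel$panel,
                  mobility_score = panel$mobility_score,
                  tremor_severity = panel$tremor_severity)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Longitudinal time-series and medication-adherence report
#'
#' Collates analyzed sessions into a chronological per-day, per-hand series
#' of each dashboard metric with its normal/abnormal flag, and summarizes
#' medication adherence as the signed delta (minutes) between actual and
#' prescribed dose times, listing missed doses.
#'
#' @param sessions List of `qdg_score_panel` objects (each with
#'   `session_time` in its dashboard record).
#' @param medication_events Optional data.frame with columns `name`, `dose`,
#'   `prescribed_time`, `actual_time` (`POSIXct`; `actual_time` NA for a
#'   missed dose).
#' @param window_days Restrict the series to the most recent this-many days
#'   (default: no restriction).
#' @return A list: `metrics` (long data.frame: date, hand, metric, value,
#'   flag), `adherence` (per-dose deltas in minutes), `missed_doses`.
#' @export
timeseries_report <- function(sessions, medication_events = NULL,
                              window_days = Inf) {
  ok <- Filter(function(s) inherits(s, "qdg_score_panel") && s$status == "ok",
               sessions)
  if (!length(ok)) stop("no successfully analyzed sessions", call. = FALSE)
  series_fields <- c("mobility_score", "tremor_severity", "taps_per_minute",
                     "press_amplitude_mm", "press_speed_mm_s",
                     "press_amplitude_cv", "release_speed_mm_s",
                     "isi_s", "arrhythmicity_pct", "rest_tremor_pct")
  .qdg_flag_fields <- c(
    mobility_score = "mobility_flag", tremor_severity = NA,
    taps_per_minute = "taps_per_minute_flag",
    press_amplitude_mm = "press_amplitude_flag",
    press_speed_mm_s = "press_speed_flag",
    press_amplitude_cv = "press_amplitude_cv_flag",
    release_speed_mm_s = "release_speed_flag",
    isi_s = "isi_flag", arrhythmicity_pct = "arrhythmicity_flag",
    rest_tremor_pct = NA)
  rows <- lapply(ok, function(s) {
    d <- s$dashboard
    when <- as.Date(substr(as.character(d$session_time), 1, 10))
    data.frame(date = when, hand = d$hand, metric = series_fields,
               value = vapply(series_fields, function(f) {
                 v <- d[[f]]
                 if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
               }, numeric(1)),
               flag = vapply(series_fields, function(f) {
                 ff <- .qdg_flag_fields[[f]]
                 if (is.na(ff)) return(NA_character_)
                 fl <- d[[ff]]
                 if (is.null(fl)) NA_character_ else fl
               }, character(1)),
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  metrics <- metrics[order(metrics$date, metrics$hand), , drop = FALSE]
  if (is.finite(window_days)) {
    cutoff <- max(metrics$date, na.rm = TRUE) - window_days + 1L
    metrics <- metrics[metrics$date >= cutoff, , drop = FALSE]
  }
  rownames(metrics) <- NULL

  adherence <- data.frame(name = character(0), dose = character(0),
                          prescribed_time = character(0),
                          delta_min = numeric(0), stringsAsFactors = FALSE)
  missed <- adherence[0, c("name", "dose", "prescribed_time")]
  if (!is.null(medication_events) && nrow(medication_events)) {
    me <- medication_events
    taken <- !is.na(me$actual_time)
    adherence <- data.frame(
      name = me$name[taken], dose = as.character(me$dose[taken]),
      prescribed_time = format(me$prescribed_time[taken], "%Y-%m-%dT%H:%M:%S"),
      delta_min = as.numeric(difftime(me$actual_time[taken],
                                      me$prescribed_time[taken],
                                      units = "mins")),
      stringsAsFactors = FALSE)
    missed <- data.frame(
      name = me$name[!taken], dose = as.character(me$dose[!taken]),
      prescribed_time = format(me$prescribed_time[!taken], "%Y-%m-%dT%H:%M:%S"),
      stringsAsFactors = FALSE)
  }
  list(metrics = metrics, adherence = adherence, missed_doses = missed)
}

#' Read a session log JSON file
#'
#' A session log records the tests and medication events of one subject:
#' `subject_id`, `tests` (array of `timestamp`, `hand`, `trace_path`),
#' `medication_events` (array of `name`, `dose`, `prescribed_time`,
#' `actual_time`), and optional `dbs_settings` and `more_affected_hand`
#' annotations. Timestamps are ISO-8601.
#'
#' @param path JSON file path.
#' @return A list with the fields above; times parsed to `POSIXct` (UTC).
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  log <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  parse_time <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S",
                                       tz = "UTC")
  if (!is.null(log$tests) && length(log$tests)) {
    log$tests <- as.data.frame(log$tests, stringsAsFactors = FALSE)
    log$tests$timestamp <- parse_time(log$tests$timestamp)
  }
  if (!is.null(log$medication_events) && length(log$medication_events)) {
    me <- as.data.frame(log$medication_events, stringsAsFactors = FALSE)
    me$prescribed_time <- parse_time(me$prescribed_time)
    me$actual_time <- if (is.null(me$actual_time)) {
      as.POSIXct(rep(NA_real_, nrow(me)), tz = "UTC")
    } else parse_time(me$actual_time)
    log$medication_events <- me
  }
  log
}
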