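# metric columns shared by per-finger and per-hand records
.qdg_metric_columns <- c("press_amplitude_mm", "press_amplitude_cv",
                         "isi_s", "isi_cv", "press_speed_mm_s",
                         "release_slope_mm_s", "dwell_time_s",
                         "rest_tremor_pct", "taps_per_minute")

sample_cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' Kinematic metrics for one finger
#'
#' Averages each strike-level quantity over the voluntary strikes of a
#' single lever: press amplitude and its coefficient of variation (CV,
#' sample SD / mean — the sequence-effect proxy), inter-strike interval
#' (ISI: press-onset to press-onset of the same finger, one full movement
#' cycle) and its CV (arrhythmicity), press speed (press amplitude /
#' press duration), release slope (release amplitude / release duration,
#' the rigidity proxy), and dwell time. Tremor-flagged strikes are excluded
#' throughout. With fewer than 2 voluntary strikes all metrics are NA
#' (CVs need at least 2 values and 2 intervals).
#'
#' @param strikes Strike data.frame for one lever, time-ordered, with
#'   `is_tremor` assigned (NA flags are treated as voluntary).
#' @param tremor_intervals Optional two-column matrix of `[start, end)` times
#'   occupied by tremor strikes anywhere on the hand. Voluntary cycle
#'   intervals that contain tremor are excluded from the ISI statistics:
#'   the pause is involuntary movement, already captured by the tremor
#'   percent, and counting it would make the (voluntary) Mobility Score
#'   tremor-dependent. Defaults to the tremor strikes present in `strikes`.
#' @return A one-row data.frame with the per-finger metric columns plus
#'   `n_voluntary_strikes` and `n_tremor_strikes`.
#' @examples
#' sim <- simulate_trace(simulation_params(noise_sd_mm = 0, isi_cv = 0), seed = 1)
#' st <- sim$truth
#' per_finger_metrics(st[st$lever == "index", ])
#' @export
per_finger_metrics <- function(strikes, tremor_intervals = NULL) {
  if (nrow(strikes) && length(unique(strikes$lever)) > 1L) {
    stop("per_finger_metrics expects strikes from a single lever", call. = FALSE)
  }
  trem <- !is.na(strikes$is_tremor) & strikes$is_tremor
  if (is.null(tremor_intervals)) {
    tremor_intervals <- cbind(strikes$t_press_onset[trem],
                              strikes$t_release_end[trem])
  }
  vol <- strikes[!trem, , drop = FALSE]
  vol <- vol[order(vol$t_press_onset), , drop = FALSE]
  n_vol <- nrow(vol)
  out <- data.frame(press_amplitude_mm = NA_real_, press_amplitude_cv = NA_real_,
                    isi_s = NA_real_, isi_cv = NA_real_,
                    press_speed_mm_s = NA_real_, release_slope_mm_s = NA_real_,
                    dwell_time_s = NA_real_,
                    n_voluntary_strikes = n_vol,
                    n_tremor_strikes = sum(trem))
  if (n_vol < 2L) return(out)
  isi <- diff(vol$t_press_onset)
  if (length(isi) && nrow(tremor_intervals)) {
    lo <- vol$t_press_onset[-n_vol]
    hi <- vol$t_press_onset[-1L]
    interrupted <- vapply(seq_along(isi), function(i) {
      any(tremor_intervals[, 1L] < hi[i] & tremor_intervals[, 2L] > lo[i])
    }, logical(1))
    isi <- isi[!interrupted]
  }
  out$press_amplitude_mm <- mean(vol$press_amplitude_mm)
  out$press_amplitude_cv <- sample_cv(vol$press_amplitude_mm)
  out$isi_s <- if (length(isi) >= 1L) mean(isi) else NA_real_
  out$isi_cv <- if (length(isi) >= 2L) sample_cv(isi) else NA_real_
  out$press_speed_mm_s <- mean(vol$press_amplitude_mm / vol$press_duration_s)
  out$release_slope_mm_s <- mean(vol$release_amplitude_mm / vol$release_duration_s)
  out$dwell_time_s <- mean(vol$dwell_time_s)
  out
}

#' Kinematic metrics for one hand
#'
#' Computes per-finger metrics for the index and middle levers and averages
#' them (unweighted) into the hand-level record; an absent finger value
#' (fewer than 2 voluntary strikes on that lever) makes the hand value
#' absent too. Two metrics are defined at the hand level directly:
#' rest tremor percent, `100 * sum(tremor strike durations) / trace
#' duration`, and taps per minute, `60 * n_voluntary / trace duration`.
#'
#' @param strikes Strike data.frame for the whole hand (both levers), with
#'   tremor flags assigned.
#' @param trace_duration_s Trace duration (s), positive.
#' @return An object of class `qdg_hand_metrics`: a named list with the
#'   metric columns, `n_voluntary_strikes`, `n_tremor_strikes`, and the
#'   two per-finger records under `finger`.
#' @export
hand_metrics <- function(strikes, trace_duration_s) {
  if (!is.numeric(trace_duration_s) || trace_duration_s <= 0) {
    stop("trace_duration_s must be positive", call. = FALSE)
  }
  trem <- !is.na(strikes$is_tremor) & strikes$is_tremor
  tw <- cbind(strikes$t_press_onset[trem], strikes$t_release_end[trem])
  fi <- per_finger_metrics(strikes[strikes$lever == "index", , drop = FALSE], tw)
  fm <- per_finger_metrics(strikes[strikes$lever == "middle", , drop = FALSE], tw)
  avg <- function(col) mean(c(fi[[col]], fm[[col]]))  # NA propagates
  trem_dur <- sum(strikes$t_release_end[trem] - strikes$t_press_onset[trem])
  n_vol <- fi$n_voluntary_strikes + fm$n_voluntary_strikes
  out <- list(
    press_amplitude_mm = avg("press_amplitude_mm"),
    press_amplitude_cv = avg("press_amplitude_cv"),
    isi_s = avg("isi_s"),
    isi_cv = avg("isi_cv"),
    press_speed_mm_s = avg("press_speed_mm_s"),
    release_slope_mm_s = avg("release_slope_mm_s"),
    dwell_time_s = avg("dwell_time_s"),
    rest_tremor_pct = 100 * trem_dur / trace_duration_s,
    taps_per_minute = 60 * n_vol / trace_duration_s,
    n_voluntary_strikes = n_vol,
    n_tremor_strikes = sum(trem),
    finger = list(index = fi, middle = fm)
  )
  structure(out, class = "qdg_hand_metrics")
}

#' @export
print.qdg_hand_metrics <- function(x, ...) {
  cat("QDG hand metrics\n")
  cat(sprintf("  taps/min: %.1f (%d voluntary, %d tremor strikes)\n",
              x$taps_per_minute, x$n_voluntary_strikes, x$n_tremor_strikes))
  cat(sprintf("  press amplitude: %.2f mm (CV %.3f)\n",
              x$press_amplitude_mm, x$press_amplitude_cv))
  cat(sprintf("  ISI: %.3f s (CV %.3f -> arrhythmicity %.1f%%)\n",
              x$isi_s, x$isi_cv, 100 * x$isi_cv))
  cat(sprintf("  press speed: %.1f mm/s, release slope: %.1f mm/s\n",
              x$press_speed_mm_s, x$release_slope_mm_s))
  cat(sprintf("  dwell: %.3f s, rest tremor: %.1f%%\n",
              x$dwell_time_s, x$rest_tremor_pct))
  invisible(x)
}
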