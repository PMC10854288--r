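#' Strike detection configuration
#'
#' Parameters of the press/release cycle detector. Presses are gated by
#' hysteresis thresholding on a smoothed copy of the displacement signal;
#' phase boundaries (onset, press bottom, release onset, release end) are
#' then refined on the raw signal.
#'
#' @param smoothing_window_s Width of the centered moving-average smoother
#'   (s); rounded to an odd sample count. Default 0.02.
#' @param press_onset_threshold_mm Displacement above which a press becomes
#'   active (mm). Default 0.3.
#' @param hysteresis_mm A press stays active until displacement falls below
#'   `press_onset_threshold_mm - hysteresis_mm`. Must be smaller than the
#'   onset threshold. Default 0.15.
#' @param min_cycle_duration_s Cycles shorter than this are discarded as
#'   chatter (s). Default 0.05.
#' @param bottom_velocity_epsilon_mm_s Velocity magnitude (mm/s) below which
#'   the lever counts as stationary at the bottom of the press. Default 2.
#' @param baseline_mm Displacement at or below which the lever counts as
#'   resting, used when extending press boundaries down to the true
#'   take-off/landing samples (mm). Default 0.05.
#' @param approach_fraction Fraction of a cycle's peak displacement defining
#'   the window in which bottom/release-onset are searched (the "maximum-
#'   displacement approach"). Default 0.9.
#' @return An object of class `qdg_detection_config`.
#' @export
detection_config <- function(smoothing_window_s = 0.02,
                             press_onset_threshold_mm = 0.3,
                             hysteresis_mm = 0.15,
                             min_cycle_duration_s = 0.05,
                             bottom_velocity_epsilon_mm_s = 2.0,
                             baseline_mm = 0.05,
                             approach_fraction = 0.9) {
  cfg <- list(smoothing_window_s = smoothing_window_s,
              press_onset_threshold_mm = press_onset_threshold_mm,
              hysteresis_mm = hysteresis_mm,
              min_cycle_duration_s = min_cycle_duration_s,
              bottom_velocity_epsilon_mm_s = bottom_velocity_epsilon_mm_s,
              baseline_mm = baseline_mm,
              approach_fraction = approach_fraction)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("detection parameter '", nm, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (cfg$hysteresis_mm >= cfg$press_onset_threshold_mm) {
    stop("hysteresis_mm must be smaller than press_onset_threshold_mm",
         call. = FALSE)
  }
  if (cfg$approach_fraction >= 1) {
    stop("approach_fraction must be below 1", call. = FALSE)
  }
  structure(cfg, class = "qdg_detection_config")
}

# centered moving average with odd window; edges use shrinking windows
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

empty_strikes <- function() {
  data.frame(lever = character(0),
             t_press_onset = numeric(0), t_press_bottom = numeric(0),
             t_release_onset = numeric(0), t_release_end = numeric(0),
             press_amplitude_mm = numeric(0), release_amplitude_mm = numeric(0),
             press_duration_s = numeric(0), release_duration_s = numeric(0),
             dwell_time_s = numeric(0), is_tremor = logical(0),
             stringsAsFactors = FALSE)
}

# detect strikes on one lever's raw series; returns a data.frame
detect_lever <- function(x, time_s, fs, lever, config) {
  n <- length(x)
  dt <- 1 / fs
  min_len <- max(2L, round(config$min_cycle_duration_s * fs))
  if (n < min_len + 2L) return(empty_strikes())

  w <- max(1L, round(config$smoothing_window_s * fs))
  if (w %% 2L == 0L) w <- w + 1L
  s <- moving_average(x, w)

  thr_on <- config$press_onset_threshold_mm
  thr_off <- thr_on - config$hysteresis_mm

  # noise level from the smoothing residual; resting-level statistics from
  # the smoothed below-hysteresis samples (robust to the clipped-at-zero
  # noise floor of a real device)
  sigma <- if (w > 1L) {
    1.4826 * stats::median(abs(x - s)) / sqrt(1 - 1 / w)
  } else 0
  sigma_s <- sigma / sqrt(w)
  rest <- s[s < thr_off]
  rest_mean <- if (length(rest)) stats::median(rest) else 0
  rest_sd <- if (length(rest)) 1.4826 * stats::median(abs(rest - rest_mean)) else 0
  base <- config$baseline_mm
  noisy <- sigma > base / 3
  cut <- max(base, rest_mean + 3.5 * rest_sd)
  walk_cap <- max(w, round(0.1 * fs))

  # hysteresis state machine on the smoothed signal
  above <- s >= thr_on
  below <- s <= thr_off
  regions <- list()
  i <- 1L
  while (i <= n) {
    # find next activation
    while (i <= n && !above[i]) i <- i + 1L
    if (i > n) break
    start <- i
    while (i <= n && !below[i]) i <- i + 1L
    if (i > n) break  # press not closed before trace end -> partial, dropped
    regions[[length(regions) + 1L]] <- c(start, i)
    i <- i + 1L
  }
  # trace begins mid-press iff the signal never rests before first activation
  if (length(regions) && min(s[1:regions[[1L]][1L]]) > cut) {
    regions <- regions[-1L]
  }
  if (!length(regions)) return(empty_strikes())

  # raw central-difference velocity (mm/s)
  v <- rep(NA_real_, n)
  if (n >= 3L) v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  eps <- config$bottom_velocity_epsilon_mm_s

  out <- vector("list", length(regions))
  prev_end <- 1L
  kept <- 0L
  for (r in regions) {
    i_on <- r[1L]; i_off <- r[2L]
    if (!noisy) {
      # clean signal: walk the raw series to the exact take-off / landing
      j <- i_on
      lo <- prev_end
      while (j > lo && x[j - 1L] > base && x[j - 1L] <= x[j] + base) j <- j - 1L
      onset <- if (j > 1L && x[j - 1L] <= base) j - 1L else j
      while (onset < i_on - 1L && x[onset + 1L] <= base) onset <- onset + 1L
      k <- i_off
      while (k < n && x[k + 1L] > base && x[k + 1L] <= x[k] + base) k <- k + 1L
      rel_end <- if (k < n && x[k + 1L] <= base) k + 1L else k
      while (rel_end > i_off && x[rel_end - 1L] <= base) rel_end <- rel_end - 1L
    } else {
      # noisy signal: walk the smoothed series to the resting band
      onset <- i_on
      lo <- max(prev_end + 1L, i_on - walk_cap)
      while (onset > lo && s[onset - 1L] > cut) onset <- onset - 1L
      if (s[onset] > cut) onset <- onset - 1L
      rel_end <- i_off
      hi <- min(n - 1L, i_off + walk_cap)
      while (rel_end < hi && s[rel_end + 1L] > cut) rel_end <- rel_end + 1L
      if (s[rel_end] > cut) rel_end <- rel_end + 1L
    }
    if (onset <= 1L) { next }  # partial cycle at trace start
    if (rel_end >= n) { next }  # partial cycle at trace end

    if (rel_end - onset + 1L < min_len) { prev_end <- rel_end; next }

    seg <- onset:rel_end
    pk <- max(s[seg])
    if (pk <= thr_on) { prev_end <- rel_end; next }
    approach <- config$approach_fraction * pk
    win <- seg[s[seg] >= approach]
    if (!length(win)) win <- seg[which.max(s[seg])]

    if (!noisy) {
      # press bottom: first stationary sample in the approach window,
      # corrected for the one-sample group delay of the central difference
      slow <- win[!is.na(v[win]) & abs(v[win]) < eps]
      if (length(slow)) {
        bottom <- max(onset + 1L, slow[1L] - 1L)
        rel_on <- min(rel_end - 1L, slow[length(slow)] + 1L)
      } else {
        apex <- seg[which.max(s[seg])]
        bottom <- max(onset + 1L, min(apex, rel_end - 1L))
        rel_on <- bottom
      }
    } else {
      # point velocities are noise-dominated: take the stationary bottom
      # phase as the samples statistically indistinguishable from the
      # plateau level
      L <- stats::quantile(s[win], 0.75, names = FALSE)
      guard <- 3 * sigma_s + 0.015 * L
      pl <- seg[s[seg] >= L - guard]
      bottom <- max(onset + 1L, pl[1L])
      rel_on <- min(rel_end - 1L, pl[length(pl)])
    }
    if (rel_on < bottom) rel_on <- bottom

    plateau <- x[bottom:rel_on]
    rest_level <- max(rest_mean, 0)
    press_amp <- mean(plateau) - rest_level
    # landing level: exact in the clean case, resting estimate under noise
    rel_amp <- if (noisy) press_amp else mean(plateau) - x[rel_end]
    if (press_amp <= 0) { prev_end <- rel_end; next }

    kept <- kept + 1L
    out[[kept]] <- data.frame(
      lever = lever,
      t_press_onset = time_s[onset],
      t_press_bottom = time_s[bottom],
      t_release_onset = time_s[rel_on],
      t_release_end = time_s[rel_end],
      press_amplitude_mm = press_amp,
      release_amplitude_mm = max(rel_amp, 0),
      press_duration_s = time_s[bottom] - time_s[onset],
      release_duration_s = time_s[rel_end] - time_s[rel_on],
      dwell_time_s = time_s[rel_on] - time_s[bottom],
      is_tremor = NA,
      stringsAsFactors = FALSE
    )
    prev_end <- rel_end
  }
  if (!kept) return(empty_strikes())
  do.call(rbind, out[seq_len(kept)])
}

#' Detect press/release strike cycles in a RAFT trace
#'
#' Segments each lever's displacement signal into press/release cycles
#' ("strikes") and estimates the four phase boundaries of each cycle: press
#' onset (lever leaves rest), press bottom (lever becomes stationary at the
#' bottom of the press), release onset (stationary phase ends) and release
#' end (lever back at rest). Press amplitude is the mean displacement over
#' the stationary bottom phase; press speed and release slope derive from
#' amplitude over phase duration downstream.
#'
#' Presses are gated by hysteresis thresholding of the smoothed signal;
#' boundaries are refined on the raw signal, with the press bottom and
#' release onset located by a velocity criterion
#' (`|v| < bottom_velocity_epsilon_mm_s`) inside the maximum-displacement
#' approach window. Incomplete cycles at either trace boundary are dropped.
#'
#' @param trace A [raft_trace].
#' @param config A [detection_config()].
#' @return A data.frame of strikes ordered by `t_press_onset` across levers,
#'   with columns `lever`, the four phase times (s), `press_amplitude_mm`,
#'   `release_amplitude_mm`, the three phase durations (s), and `is_tremor`
#'   (NA until [classify_strikes()] runs). A trace with no detectable
#'   cycles (flat, too short) yields zero rows, not an error.
#' @examples
#' sim <- simulate_trace(simulation_params(duration_s = 10, noise_sd_mm = 0), seed = 1)
#' st <- detect_strikes(sim$trace)
#' nrow(st) == nrow(sim$truth)
#' @export
detect_strikes <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "raft_trace"))
  if (!inherits(config, "qdg_detection_config")) {
    stop("config must come from detection_config()", call. = FALSE)
  }
  fs <- trace$sample_rate_hz
  res <- rbind(
    detect_lever(trace$data$index_mm, trace$data$time_s, fs, "index", config),
    detect_lever(trace$data$middle_mm, trace$data$time_s, fs, "middle", config)
  )
  res <- res[order(res$t_press_onset, res$lever), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize alternation violations in a strike sequence
#'
#' The RAFT task instructs alternating index/middle presses. This report
#' counts departures: consecutive strikes on the same lever, and pairs of
#' strikes on different levers whose press intervals (`[t_press_onset,
#' t_release_end)`) overlap.
#'
#' @param strikes Strike data.frame from [detect_strikes()] (tremor strikes,
#'   if flagged, are excluded from the alternation count since they are not
#'   voluntary taps).
#' @return A list: `n_strikes`, `n_same_lever` (consecutive same-lever
#'   pairs), `n_overlapping` (cross-lever press overlaps).
#' @export
alternation_report <- function(strikes) {
  vol <- strikes
  if (nrow(vol) && !all(is.na(vol$is_tremor))) {
    vol <- vol[is.na(vol$is_tremor) | !vol$is_tremor, , drop = FALSE]
  }
  vol <- vol[order(vol$t_press_onset), , drop = FALSE]
  n <- nrow(vol)
  same <- if (n >= 2L) sum(vol$lever[-1L] == vol$lever[-n]) else 0L
  overlap <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && vol$t_press_onset[j] < vol$t_release_end[i]) {
        if (vol$lever[j] != vol$lever[i]) overlap <- overlap + 1L
        j <- j + 1L
      }
    }
  }
  list(n_strikes = n, n_same_lever = as.integer(same),
       n_overlapping = as.integer(overlap))
}

#' Write detected strikes to a delimited annotation file
#'
#' One row per strike, tab-separated, for inspection alongside the trace.
#'
#' @param strikes Strike data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strikes <- function(strikes, path) {
  utils::write.table(strikes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
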