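# run expr with a private RNG stream; restores the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation parameters for synthetic RAFT traces
#'
#' Describes one hand's tapping behaviour: voluntary press geometry
#' (amplitude, phase durations, dwell), timing (per-finger cycle time and
#' its jitter), progressive amplitude decrement over repetitions (the
#' "sequence effect"), low-amplitude tremor bursts, and measurement noise.
#' Defaults emulate a healthy adult: ~8.7 mm presses at 2 Hz per finger
#' (4 taps/s across the alternating pair), brisk 0.1 s press and release,
#' a short dwell, 5% timing jitter, no sequence effect, and no tremor.
#'
#' @param duration_s Trace length (s), default 30 (the RAFT task length).
#' @param sample_rate_hz Sampling rate (Hz), default 100.
#' @param base_amplitude_mm First-press amplitude (mm), default 8.67.
#' @param amplitude_cv Within-trace multiplicative amplitude jitter
#'   (coefficient of variation), default 0.03.
#' @param amplitude_decay_per_tap Fractional amplitude loss per successive
#'   tap on the same finger (sequence effect), default 0.
#' @param press_duration_s,release_duration_s,dwell_s Phase durations (s).
#' @param isi_mean_s Mean inter-strike interval per finger — time for one
#'   full cycle of that finger (s), default 0.5 (2 Hz per finger). Must
#'   exceed press + dwell + release.
#' @param isi_cv Coefficient of variation of the log-normal ISI jitter.
#' @param tremor_pct_target Target percent of trace duration occupied by
#'   tremor strikes, 0-100.
#' @param tremor_amplitude_mm Mean amplitude of tremor strikes (mm).
#' @param tremor_rate_hz Tremor strike rate within a burst (Hz), default 5
#'   (the parkinsonian rest-tremor band).
#' @param noise_sd_mm Additive Gaussian measurement noise SD (mm).
#' @param amp_max_mm Device ceiling (mm); the signal is clipped to
#'   `[0, amp_max_mm]`.
#' @return An object of class `qdg_sim_params`.
#' @export
simulation_params <- function(duration_s = 30,
                              sample_rate_hz = 100,
                              base_amplitude_mm = 8.67,
                              amplitude_cv = 0.03,
                              amplitude_decay_per_tap = 0,
                              press_duration_s = 0.10,
                              release_duration_s = 0.10,
                              dwell_s = 0.06,
                              isi_mean_s = 0.5,
                              isi_cv = 0.05,
                              tremor_pct_target = 0,
                              tremor_amplitude_mm = 2.0,
                              tremor_rate_hz = 5,
                              noise_sd_mm = 0.05,
                              amp_max_mm = 12.5) {
  p <- list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
            base_amplitude_mm = base_amplitude_mm, amplitude_cv = amplitude_cv,
            amplitude_decay_per_tap = amplitude_decay_per_tap,
            press_duration_s = press_duration_s,
            release_duration_s = release_duration_s, dwell_s = dwell_s,
            isi_mean_s = isi_mean_s, isi_cv = isi_cv,
            tremor_pct_target = tremor_pct_target,
            tremor_amplitude_mm = tremor_amplitude_mm,
            tremor_rate_hz = tremor_rate_hz, noise_sd_mm = noise_sd_mm,
            amp_max_mm = amp_max_mm)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("simulation parameter '", nm, "' must be a non-negative number",
           call. = FALSE)
    }
  }
  if (p$duration_s < 1) stop("duration_s must be at least 1 s", call. = FALSE)
  span <- p$press_duration_s + p$dwell_s + p$release_duration_s
  if (p$isi_mean_s <= span) {
    stop("infeasible timing: isi_mean_s (", p$isi_mean_s,
         ") must exceed press + dwell + release (", span, ")", call. = FALSE)
  }
  if (p$tremor_pct_target > 100) {
    stop("tremor_pct_target must be in [0, 100]", call. = FALSE)
  }
  if (p$base_amplitude_mm > p$amp_max_mm) {
    stop("base_amplitude_mm exceeds amp_max_mm", call. = FALSE)
  }
  structure(p, class = "qdg_sim_params")
}

# raised-cosine press pulse evaluated at sample times; phase boundaries are
# grid-aligned so ground truth coincides with samples
pulse_values <- function(t, onset, bottom, rel_on, rel_end, amp) {
  y <- numeric(length(t))
  rise <- t >= onset & t < bottom
  y[rise] <- amp * (1 - cos(pi * (t[rise] - onset) / (bottom - onset))) / 2
  hold <- t >= bottom & t <= rel_on
  y[hold] <- amp
  fall <- t > rel_on & t <= rel_end
  y[fall] <- amp * (1 + cos(pi * (t[fall] - rel_on) / (rel_end - rel_on))) / 2
  y
}

snap <- function(t, fs) round(t * fs) / fs

# log-normal ISIs with given mean and CV
draw_isis <- function(n, mean_s, cv) {
  if (cv <= 0) return(rep(mean_s, n))
  sigma2 <- log(1 + cv^2)
  mu <- log(mean_s) - sigma2 / 2
  stats::rlnorm(n, mu, sqrt(sigma2))
}

#' Simulate a RAFT trace with ground-truth strike annotations
#'
#' Generates alternating raised-cosine press/release pulses on the two
#' levers (index leads, middle offset by half a cycle), with multiplicative
#' per-tap amplitude decay and jitter, log-normal ISI jitter, optional
#' tremor bursts (runs of rapid low-amplitude strikes on the index lever
#' that suspend voluntary tapping for their duration), and additive Gaussian
#' noise clipped to the device range. All phase boundaries are snapped to
#' the sample grid, so the ground-truth table is exact for the noise-free
#' signal. Output is bit-identical for identical `(params, seed)`.
#'
#' @param params A [simulation_params()].
#' @param seed Integer RNG seed.
#' @param hand,meta Passed to [raft_trace()].
#' @return A list: `trace` (a [raft_trace]) and `truth` (a strike data.frame
#'   in the [detect_strikes()] layout with `is_tremor` filled in).
#' @examples
#' sim <- simulate_trace(simulation_params(noise_sd_mm = 0), seed = 42)
#' range(sim$truth$press_amplitude_mm)
#' @export
simulate_trace <- function(params = simulation_params(), seed = 1L,
                           hand = "R", meta = list()) {
  stopifnot(inherits(params, "qdg_sim_params"))
  with_seed(seed, {
    p <- params
    fs <- p$sample_rate_hz
    dt <- 1 / fs
    n <- round(p$duration_s * fs)
    t <- (0:(n - 1L)) / fs
    span <- p$press_duration_s + p$dwell_s + p$release_duration_s

    # tremor burst windows: rapid strikes at tremor_rate_hz; per-strike active
    # duration is 80% of the tremor cycle, the rest is a short gap
    trem_cycle <- 1 / p$tremor_rate_hz
    trem_span <- 0.8 * trem_cycle
    trem <- NULL
    windows <- NULL
    if (p$tremor_pct_target > 0) {
      target_time <- p$tremor_pct_target / 100 * p$duration_s
      n_tr <- max(1L, round(target_time / trem_span))
      per_burst <- max(3L, min(n_tr, round(1.0 / trem_cycle)))
      n_burst <- max(1L, round(n_tr / per_burst))
      counts <- rep(n_tr %/% n_burst, n_burst)
      extra <- n_tr - sum(counts)
      if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
      margin <- 1.0
      usable <- p$duration_s - 2 * margin
      starts <- margin + (seq_len(n_burst) - 0.5) / n_burst * usable
      windows <- cbind(start = snap(starts, fs),
                       end = snap(starts + counts * trem_cycle, fs))
      rows <- vector("list", n_tr)
      ri <- 0L
      for (b in seq_len(n_burst)) {
        for (k in seq_len(counts[b])) {
          onset <- snap(windows[b, "start"] + (k - 1L) * trem_cycle, fs)
          amp <- p$tremor_amplitude_mm *
            max(0.3, 1 + stats::rnorm(1L, 0, 0.1))
          bottom <- snap(onset + 0.35 * trem_cycle, fs)
          rel_on <- snap(bottom + 0.10 * trem_cycle, fs)
          rel_end <- snap(rel_on + 0.35 * trem_cycle, fs)
          ri <- ri + 1L
          rows[[ri]] <- c(onset, bottom, rel_on, rel_end, amp)
        }
      }
      trem <- do.call(rbind, rows)
    }

    in_window <- function(t0, t1) {
      if (is.null(windows)) return(rep(FALSE, length(t0)))
      hit <- rep(FALSE, length(t0))
      for (b in seq_len(nrow(windows))) {
        hit <- hit | (t0 < windows[b, "end"] + trem_cycle &
                        t1 > windows[b, "start"] - trem_cycle)
      }
      hit
    }

    # voluntary schedule per lever; middle offset by half a cycle
    lever_rows <- function(lever, t_start) {
      n_max <- ceiling(p$duration_s / max(p$isi_mean_s * 0.2, span)) + 4L
      isis <- draw_isis(n_max, p$isi_mean_s, p$isi_cv)
      onsets <- snap(t_start + cumsum(c(0, isis)), fs)
      # complete cycles need a short rest margin before the trace ends
      end_guard <- max(2 * dt, 0.05)
      onsets <- onsets[onsets + span < p$duration_s - end_guard]
      if (!length(onsets)) return(NULL)
      # enforce non-overlap on this lever after jitter
      for (i in seq_along(onsets)[-1L]) {
        lim <- onsets[i - 1L] + span + 2 * dt
        if (onsets[i] < lim) onsets[i] <- snap(lim, fs)
      }
      onsets <- onsets[onsets + span < p$duration_s - end_guard]
      k <- seq_along(onsets)
      amps <- p$base_amplitude_mm * (1 - p$amplitude_decay_per_tap)^(k - 1L)
      if (p$amplitude_cv > 0) {
        amps <- amps * pmax(0.2, 1 + stats::rnorm(length(amps), 0, p$amplitude_cv))
      }
      amps <- pmin(amps, p$amp_max_mm)
      keep <- !in_window(onsets, onsets + span) & onsets > dt
      if (!any(keep)) return(NULL)
      onsets <- onsets[keep]; amps <- amps[keep]
      data.frame(lever = lever,
                 t_press_onset = onsets,
                 t_press_bottom = snap(onsets + p$press_duration_s, fs),
                 t_release_onset = snap(onsets + p$press_duration_s + p$dwell_s, fs),
                 t_release_end = snap(onsets + span, fs),
                 press_amplitude_mm = amps,
                 is_tremor = FALSE,
                 stringsAsFactors = FALSE)
    }
    vol <- rbind(lever_rows("index", snap(0.25, fs)),
                 lever_rows("middle", snap(0.25 + p$isi_mean_s / 2, fs)))

    if (!is.null(trem)) {
      trem_df <- data.frame(lever = "index",
                            t_press_onset = trem[, 1L],
                            t_press_bottom = trem[, 2L],
                            t_release_onset = trem[, 3L],
                            t_release_end = trem[, 4L],
                            press_amplitude_mm = trem[, 5L],
                            is_tremor = TRUE,
                            stringsAsFactors = FALSE)
      vol <- rbind(vol, trem_df)
    }
    if (is.null(vol) || !nrow(vol)) {
      stop("no strikes fit in the requested duration", call. = FALSE)
    }
    vol <- vol[order(vol$t_press_onset, vol$lever), , drop = FALSE]
    vol$release_amplitude_mm <- vol$press_amplitude_mm
    vol$press_duration_s <- vol$t_press_bottom - vol$t_press_onset
    vol$release_duration_s <- vol$t_release_end - vol$t_release_onset
    vol$dwell_time_s <- vol$t_release_onset - vol$t_press_bottom
    vol <- vol[, c("lever", "t_press_onset", "t_press_bottom",
                   "t_release_onset", "t_release_end", "press_amplitude_mm",
                   "release_amplitude_mm", "press_duration_s",
                   "release_duration_s", "dwell_time_s", "is_tremor")]
    rownames(vol) <- NULL

    sig <- list(index = numeric(n), middle = numeric(n))
    for (i in seq_len(nrow(vol))) {
      lv <- vol$lever[i]
      sig[[lv]] <- sig[[lv]] + pulse_values(
        t, vol$t_press_onset[i], vol$t_press_bottom[i],
        vol$t_release_onset[i], vol$t_release_end[i],
        vol$press_amplitude_mm[i])
    }
    if (p$noise_sd_mm > 0) {
      sig$index <- sig$index + stats::rnorm(n, 0, p$noise_sd_mm)
      sig$middle <- sig$middle + stats::rnorm(n, 0, p$noise_sd_mm)
    }
    sig$index <- pmin(pmax(sig$index, 0), p$amp_max_mm)
    sig$middle <- pmin(pmax(sig$middle, 0), p$amp_max_mm)

    trace <- raft_trace(t, sig$index, sig$middle, fs, hand = hand,
                        amp_max_mm = p$amp_max_mm, meta = meta)
    list(trace = trace, truth = vol)
  })
}

#' Distribution targets the control simulator is calibrated to
#'
#' Between-subject distribution parameters used by
#' [simulate_control_cohort()]. Only the press-amplitude mean and SD
#' (8.67 +/- 0.12 mm) reproduce a published healthy-control calibration;
#' every other entry is a synthetic choice emulating brisk, regular healthy
#' tapping (2 Hz per finger), including mild slowing of press/release speed
#' and increased amplitude variability with age.
#'
#' @return Named list of calibration parameters.
#' @export
control_calibration <- function() {
  list(
    amplitude_mean_mm = 8.67, amplitude_sd_mm = 0.12,
    isi_mean_s = 0.50, isi_sd_s = 0.02,
    isi_cv_mean = 0.05, isi_cv_sd = 0.012,
    amplitude_cv_mean = 0.03, amplitude_cv_sd = 0.008,
    press_duration_mean_s = 0.10, press_duration_sd_s = 0.006,
    release_duration_mean_s = 0.10, release_duration_sd_s = 0.006,
    dwell_mean_s = 0.06, dwell_sd_s = 0.008,
    # synthetic aging effects (fractional change per year past 60)
    age_speed_slope = 0.004,   # press/release slow down with age
    age_isi_slope = 0.001,     # cycles lengthen slightly
    age_ampcv_slope = 0.008,   # amplitude variability grows
    reference_age_years = 60
  )
}

#' Simulate a healthy-control cohort and extract its metric table
#'
#' Draws per-subject tapping parameters from [control_calibration()],
#' simulates one 30-s RAFT trace per subject, and runs the full pipeline
#' (strike detection, tremor classification, per-finger and per-hand
#' metrics) so the returned table contains pipeline-extracted — not
#' nominal — metric values, plus subject age. This is the table
#' [build_reference()] consumes.
#'
#' @param n_subjects Number of control subjects (>= 2).
#' @param age_range Length-2 numeric; ages drawn uniformly in this range.
#' @param seed Integer RNG seed; output is deterministic per seed.
#' @param return_traces If TRUE, also return the simulated traces.
#' @return A data.frame with columns `subject_id`, `age_years` and the
#'   metric columns of [hand_metrics()]; if `return_traces`, a list
#'   `(metrics, traces)`.
#' @export
simulate_control_cohort <- function(n_subjects = 42, age_range = c(45, 75),
                                    seed = 1L, return_traces = FALSE) {
  if (n_subjects < 2) stop("n_subjects must be at least 2", call. = FALSE)
  if (length(age_range) != 2L || diff(range(age_range)) <= 0) {
    stop("age_range must span a positive interval", call. = FALSE)
  }
  cal <- control_calibration()
  with_seed(seed, {
    ages <- stats::runif(n_subjects, age_range[1L], age_range[2L])
    sub_seeds <- sample.int(2^30, n_subjects)
    rows <- vector("list", n_subjects)
    traces <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      a <- ages[i] - cal$reference_age_years
      slow <- 1 + cal$age_speed_slope * a
      pars <- simulation_params(
        base_amplitude_mm = stats::rnorm(1, cal$amplitude_mean_mm,
                                         cal$amplitude_sd_mm),
        amplitude_cv = max(0.005, stats::rnorm(1, cal$amplitude_cv_mean *
                                                 (1 + cal$age_ampcv_slope * a),
                                               cal$amplitude_cv_sd)),
        press_duration_s = max(0.05, stats::rnorm(1, cal$press_duration_mean_s,
                                                  cal$press_duration_sd_s) * slow),
        release_duration_s = max(0.05, stats::rnorm(1, cal$release_duration_mean_s,
                                                    cal$release_duration_sd_s) * slow),
        dwell_s = max(0.02, stats::rnorm(1, cal$dwell_mean_s, cal$dwell_sd_s)),
        isi_mean_s = max(0.35, stats::rnorm(1, cal$isi_mean_s *
                                              (1 + cal$age_isi_slope * a),
                                            cal$isi_sd_s)),
        isi_cv = max(0.01, stats::rnorm(1, cal$isi_cv_mean, cal$isi_cv_sd)),
        noise_sd_mm = 0.05
      )
      sim <- simulate_trace(pars, seed = sub_seeds[i],
                            meta = list(subject_id = sprintf("HC%03d", i),
                                        age_years = ages[i]))
      strikes <- detect_strikes(sim$trace)
      strikes <- classify_strikes(strikes, sim$trace)
      hm <- hand_metrics(strikes, trace_duration(sim$trace))
      rows[[i]] <- cbind(data.frame(subject_id = sprintf("HC%03d", i),
                                    age_years = ages[i],
                                    stringsAsFactors = FALSE),
                         as.data.frame(hm[.qdg_metric_columns]))
      if (return_traces) traces[[i]] <- sim$trace
    }
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL
    if (return_traces) list(metrics = metrics, traces = traces) else metrics
  })
}

#' Draw a parametric control metric table (no trace simulation)
#'
#' Samples per-subject metric values directly from the between-subject
#' distributions of [control_calibration()], including the synthetic age
#' effects, without simulating or re-analyzing traces. Intended for large-n
#' distributional checks (e.g. threshold flag rates) where simulating tens
#' of thousands of full traces would add nothing; [simulate_control_cohort()]
#' remains the end-to-end route.
#'
#' @param n Number of subjects.
#' @param age_range Length-2 numeric; ages uniform in this range.
#' @param seed Integer RNG seed.
#' @return Same layout as [simulate_control_cohort()].
#' @export
simulate_control_metrics <- function(n, age_range = c(45, 75), seed = 1L) {
  cal <- control_calibration()
  with_seed(seed, {
    ages <- stats::runif(n, age_range[1L], age_range[2L])
    a <- ages - cal$reference_age_years
    slow <- 1 + cal$age_speed_slope * a
    amp <- stats::rnorm(n, cal$amplitude_mean_mm, cal$amplitude_sd_mm)
    press_dur <- pmax(0.05, stats::rnorm(n, cal$press_duration_mean_s,
                                         cal$press_duration_sd_s) * slow)
    rel_dur <- pmax(0.05, stats::rnorm(n, cal$release_duration_mean_s,
                                       cal$release_duration_sd_s) * slow)
    isi <- pmax(0.35, stats::rnorm(n, cal$isi_mean_s * (1 + cal$age_isi_slope * a),
                                   cal$isi_sd_s))
    data.frame(
      subject_id = sprintf("HC%05d", seq_len(n)),
      age_years = ages,
      press_amplitude_mm = amp,
      press_amplitude_cv = pmax(0.005, stats::rnorm(n, cal$amplitude_cv_mean *
                                                      (1 + cal$age_ampcv_slope * a),
                                                    cal$amplitude_cv_sd)),
      isi_s = isi,
      isi_cv = pmax(0.01, stats::rnorm(n, cal$isi_cv_mean, cal$isi_cv_sd)),
      press_speed_mm_s = amp / press_dur,
      release_slope_mm_s = amp / rel_dur,
      dwell_time_s = pmax(0.02, stats::rnorm(n, cal$dwell_mean_s, cal$dwell_sd_s)),
      rest_tremor_pct = 0,
      taps_per_minute = 2 * 60 / isi,
      stringsAsFactors = FALSE
    )
  })
}
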