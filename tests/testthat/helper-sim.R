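# shared fixtures built in code

# align detected strikes to ground truth by order within lever; errors if the
# per-lever counts differ
align_strikes <- function(truth, detected) {
  out <- list()
  for (lv in c("index", "middle")) {
    a <- truth[truth$lever == lv, ]
    b <- detected[detected$lever == lv, ]
    stopifnot(nrow(a) == nrow(b))
    a <- a[order(a$t_press_onset), ]
    b <- b[order(b$t_press_onset), ]
    out[[lv]] <- list(truth = a, detected = b)
  }
  out
}

max_phase_error_s <- function(truth, detected) {
  al <- align_strikes(truth, detected)
  m <- 0
  for (lv in names(al)) {
    a <- al[[lv]]$truth; b <- al[[lv]]$detected
    m <- max(m,
             abs(a$t_press_onset - b$t_press_onset),
             abs(a$t_press_bottom - b$t_press_bottom),
             abs(a$t_release_onset - b$t_release_onset),
             abs(a$t_release_end - b$t_release_end))
  }
  m
}

phase_errors_s <- function(truth, detected) {
  al <- align_strikes(truth, detected)
  unlist(lapply(al, function(p) {
    a <- p$truth; b <- p$detected
    c(abs(a$t_press_onset - b$t_press_onset),
      abs(a$t_press_bottom - b$t_press_bottom),
      abs(a$t_release_onset - b$t_release_onset),
      abs(a$t_release_end - b$t_release_end))
  }), use.names = FALSE)
}

# strike table from explicit phase times (for hand-built cases)
make_strikes <- function(lever, onsets, press_dur = 0.1, dwell = 0.05,
                         release_dur = 0.1, amp = 8, is_tremor = FALSE) {
  n <- length(onsets)
  data.frame(lever = rep(lever, length.out = n),
             t_press_onset = onsets,
             t_press_bottom = onsets + press_dur,
             t_release_onset = onsets + press_dur + dwell,
             t_release_end = onsets + press_dur + dwell + release_dur,
             press_amplitude_mm = rep(amp, length.out = n),
             release_amplitude_mm = rep(amp, length.out = n),
             press_duration_s = rep(press_dur, length.out = n),
             release_duration_s = rep(release_dur, length.out = n),
             dwell_time_s = rep(dwell, length.out = n),
             is_tremor = rep(is_tremor, length.out = n),
             stringsAsFactors = FALSE)
}

mobility_z <- function(val) {
  stats::setNames(rep(val, length.out = 6),
                  c("isi_s", "isi_cv", "press_speed_mm_s",
                    "press_amplitude_mm", "press_amplitude_cv",
                    "release_slope_mm_s"))
}
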