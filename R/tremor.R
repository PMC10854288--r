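#' Tremor classifier specification
#'
#' Tremor is identified on a per-strike basis. The default heuristic flags a
#' strike as tremor when its press amplitude falls below a fraction of the
#' hand's median voluntary amplitude AND its local same-lever cycle rate
#' lies in the parkinsonian tremor band. The interface also accepts any
#' external per-strike predictor (e.g. a trained gradient-boosted model),
#' so a validated classifier can be dropped in; the heuristic is a
#' documented stand-in, not a reproduction of any published model.
#'
#' @param kind `"heuristic"` or `"external"`.
#' @param amplitude_fraction_threshold Tremor amplitude cutoff as a fraction
#'   of the median voluntary amplitude (default 0.45).
#' @param cycle_rate_band_hz Length-2 numeric; local cycle-rate band (Hz)
#'   in which tremor strikes live (default `c(3, 8)`).
#' @param predict For `kind = "external"`: a function
#'   `(strikes, trace) -> logical vector` of per-strike tremor flags.
#' @return An object of class `qdg_tremor_spec`.
#' @export
tremor_classifier <- function(kind = c("heuristic", "external"),
                              amplitude_fraction_threshold = 0.45,
                              cycle_rate_band_hz = c(3, 8),
                              predict = NULL) {
  kind <- match.arg(kind)
  if (kind == "heuristic") {
    if (!is.numeric(amplitude_fraction_threshold) ||
        amplitude_fraction_threshold <= 0 || amplitude_fraction_threshold >= 1) {
      stop("amplitude_fraction_threshold must be in (0, 1)", call. = FALSE)
    }
    if (length(cycle_rate_band_hz) != 2L ||
        cycle_rate_band_hz[1L] >= cycle_rate_band_hz[2L]) {
      stop("cycle_rate_band_hz must be an increasing pair", call. = FALSE)
    }
  } else if (!is.function(predict)) {
    stop("external classifier requires a predict function", call. = FALSE)
  }
  structure(list(kind = kind,
                 amplitude_fraction_threshold = amplitude_fraction_threshold,
                 cycle_rate_band_hz = cycle_rate_band_hz,
                 predict = predict),
            class = "qdg_tremor_spec")
}

# local same-lever cycle rate: reciprocal of the smaller adjacent
# onset-to-onset gap (a strike inside a rapid burst has a short gap on at
# least one side)
local_cycle_rate <- function(onsets) {
  n <- length(onsets)
  if (n < 2L) return(rep(NA_real_, n))
  gaps <- diff(onsets)
  prev_gap <- c(NA_real_, gaps)
  next_gap <- c(gaps, NA_real_)
  g <- pmin(prev_gap, next_gap, na.rm = TRUE)
  1 / g
}

#' Assign per-strike tremor flags
#'
#' Applies the classifier in `spec` to every detected strike and fills the
#' `is_tremor` column. The heuristic iterates to a fixed point: starting
#' from all strikes, the voluntary median amplitude is recomputed after each
#' reclassification so that abundant low-amplitude tremor strikes cannot
#' drag the reference median down. Deterministic given its inputs.
#'
#' @param strikes Strike data.frame from [detect_strikes()].
#' @param trace The source [raft_trace] (passed to external predictors;
#'   unused by the heuristic beyond strike timings).
#' @param spec A [tremor_classifier()].
#' @return `strikes` with `is_tremor` set to TRUE/FALSE for every row.
#' @export
classify_strikes <- function(strikes, trace = NULL,
                             spec = tremor_classifier()) {
  stopifnot(inherits(spec, "qdg_tremor_spec"))
  if (!nrow(strikes)) {
    strikes$is_tremor <- logical(0)
    return(strikes)
  }
  if (spec$kind == "external") {
    flags <- tryCatch(spec$predict(strikes, trace),
                      error = function(e) {
                        stop("external tremor classifier failed: ",
                             conditionMessage(e), call. = FALSE)
                      })
    if (!is.logical(flags) || length(flags) != nrow(strikes) || anyNA(flags)) {
      stop("external tremor classifier must return one TRUE/FALSE per strike",
           call. = FALSE)
    }
    strikes$is_tremor <- flags
    return(strikes)
  }
  band <- spec$cycle_rate_band_hz
  rate <- rep(NA_real_, nrow(strikes))
  for (lv in unique(strikes$lever)) {
    sel <- which(strikes$lever == lv)
    ord <- sel[order(strikes$t_press_onset[sel])]
    rate[ord] <- local_cycle_rate(strikes$t_press_onset[ord])
  }
  in_band <- !is.na(rate) & rate >= band[1L] & rate <= band[2L]
  amp <- strikes$press_amplitude_mm
  flags <- rep(FALSE, nrow(strikes))
  for (iter in 1:10) {
    med <- stats::median(amp[!flags])
    if (!is.finite(med)) break
    new_flags <- in_band & amp < spec$amplitude_fraction_threshold * med
    if (identical(new_flags, flags)) break
    flags <- new_flags
    if (all(flags)) break  # degenerate: keep last consistent state
  }
  strikes$is_tremor <- flags
  strikes
}

#' Summarize tremor burden of a classified strike sequence
#'
#' @param strikes Strike data.frame with `is_tremor` assigned.
#' @param trace_duration_s Trace duration (s).
#' @return A list: `rest_tremor_pct` (percent of the trace occupied by
#'   tremor strikes), `tremor_amplitudes_mm` (press amplitudes of flagged
#'   strikes), `mean_tremor_amplitude_mm` (NA when no strike is flagged),
#'   `n_tremor_strikes`.
#' @export
tremor_summary <- function(strikes, trace_duration_s) {
  if (!is.numeric(trace_duration_s) || trace_duration_s <= 0) {
    stop("trace_duration_s must be positive", call. = FALSE)
  }
  trem <- !is.na(strikes$is_tremor) & strikes$is_tremor
  amps <- strikes$press_amplitude_mm[trem]
  dur <- sum(strikes$t_release_end[trem] - strikes$t_press_onset[trem])
  list(rest_tremor_pct = 100 * dur / trace_duration_s,
       tremor_amplitudes_mm = amps,
       mean_tremor_amplitude_mm = if (length(amps)) mean(amps) else NA_real_,
       n_tremor_strikes = sum(trem))
}
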