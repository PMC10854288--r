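#' Scoring constants for the QDG Mobility and Tremor Severity Scores
#'
#' Bundles every fixed parameter entering the composite scores: the device
#' displacement ceiling, the normative reference age, the Mobility Score
#' scale factor, the press-amplitude power-law transform, and the low-tremor
#' amplitude suppression.
#'
#' @param amp_max_mm Maximum possible lever displacement of the device (mm).
#'   Normalizer for tremor amplitudes. The default of 12.5 mm is a documented
#'   package choice (the device ceiling is not fixed by the scoring model);
#'   override it to match a specific device.
#' @param reference_age_years Age (years) to which all metrics are adjusted
#'   before z-scoring; healthy-control cohort mean age, 60.
#' @param mobility_scale Multiplier on the mean directional z-score in the
#'   Mobility Score (default 14).
#' @param mobility_n Number of metrics entering the Mobility Score (6: ISI,
#'   ISI CV, press speed, press amplitude, press amplitude CV, release speed).
#' @param pa_transform_A,pa_transform_k Power-law coefficients of the
#'   press-amplitude z transform, `A * z^k` (defaults 3.2, 0.495).
#' @param pa_z_transition Directional press-amplitude z above which the power
#'   law applies (default 10; `A * 10^k` is within 0.005 of 10, so the
#'   transform is continuous there).
#' @param pa_z_cap Ceiling on the transformed press-amplitude z (default 20).
#' @param rt_A,rt_k,rt_b Low-tremor suppression constants: the amplitude
#'   component of the Tremor Severity Score is scaled by
#'   `rt_A^(rt_k * pct + rt_b)` when tremor percent is below
#'   `low_tremor_pct_threshold` (defaults 4, 0.05, -1).
#' @param low_tremor_pct_threshold Tremor percent below which the suppression
#'   applies (default 10).
#'
#' @return An object of class `qdg_constants` (a validated list).
#' @examples
#' const <- scoring_constants()
#' const$pa_transform_A * const$pa_z_transition^const$pa_transform_k # ~10
#' @export
scoring_constants <- function(amp_max_mm = 12.5,
                              reference_age_years = 60,
                              mobility_scale = 14,
                              mobility_n = 6,
                              pa_transform_A = 3.2,
                              pa_transform_k = 0.495,
                              pa_z_transition = 10,
                              pa_z_cap = 20,
                              rt_A = 4,
                              rt_k = 0.05,
                              rt_b = -1,
                              low_tremor_pct_threshold = 10) {
  const <- list(
    amp_max_mm = amp_max_mm,
    reference_age_years = reference_age_years,
    mobility_scale = mobility_scale,
    mobility_n = mobility_n,
    pa_transform_A = pa_transform_A,
    pa_transform_k = pa_transform_k,
    pa_z_transition = pa_z_transition,
    pa_z_cap = pa_z_cap,
    rt_A = rt_A,
    rt_k = rt_k,
    rt_b = rt_b,
    low_tremor_pct_threshold = low_tremor_pct_threshold
  )
  for (nm in names(const)) {
    v <- const[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("scoring constant '", nm, "' must be a finite number", call. = FALSE)
    }
    if (nm != "rt_b" && v <= 0) {
      stop("scoring constant '", nm, "' must be positive", call. = FALSE)
    }
  }
  structure(const, class = "qdg_constants")
}

#' @export
print.qdg_constants <- function(x, ...) {
  cat("QDG scoring constants\n")
  cat(sprintf("  device ceiling (AmpMax): %.2f mm; reference age: %g y\n",
              x$amp_max_mm, x$reference_age_years))
  cat(sprintf("  Mobility: 100 - %g * mean(z) over %d metrics\n",
              x$mobility_scale, x$mobility_n))
  cat(sprintf("  press-amp transform: %.3g * z^%.3g for z > %g, capped at %g\n",
              x$pa_transform_A, x$pa_transform_k, x$pa_z_transition, x$pa_z_cap))
  cat(sprintf("  low-tremor suppression: %g^(%g*pct%+g) below %g%%\n",
              x$rt_A, x$rt_k, x$rt_b, x$low_tremor_pct_threshold))
  invisible(x)
}

# Metric direction sets used for z-score flipping and percentile thresholds.
# lower_worse metrics flag/flip when below the control distribution;
# higher_worse when above.
.qdg_lower_worse <- c("press_amplitude_mm", "press_speed_mm_s",
                      "release_slope_mm_s", "taps_per_minute", "mobility_score")
.qdg_higher_worse <- c("isi_s", "isi_cv", "press_amplitude_cv")

# The six metrics entering the Mobility Score.
.qdg_mobility_metrics <- c("isi_s", "isi_cv", "press_speed_mm_s",
                           "press_amplitude_mm", "press_amplitude_cv",
                           "release_slope_mm_s")

# Metrics with a fitted age slope (age-adjusted before z-scoring).
.qdg_age_adjusted_metrics <- c("press_amplitude_cv", "release_slope_mm_s",
                               "press_speed_mm_s")

# All metrics carrying a normative distribution and threshold.
.qdg_reference_metrics <- c("press_amplitude_mm", "press_amplitude_cv",
                            "isi_s", "isi_cv", "press_speed_mm_s",
                            "release_slope_mm_s", "taps_per_minute",
                            "mobility_score")

metric_direction <- function(metric) {
  if (metric %in% .qdg_lower_worse) "lower_worse"
  else if (metric %in% .qdg_higher_worse) "higher_worse"
  else stop("unknown metric '", metric, "'", call. = FALSE)
}
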