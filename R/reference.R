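#' Fixed-effect age slope from a random-intercept model
#'
#' Fits `value ~ age + (1 | subject)` by REML and returns the fixed age
#' slope. With one observation per subject (or a singular random-effect
#' fit, e.g. noiseless data) the model reduces to ordinary least squares,
#' which is used directly.
#'
#' @param values Numeric metric values, one per observation.
#' @param ages Ages (years) per observation.
#' @param subject_ids Subject identifier per observation.
#' @return Slope (metric units per year).
#' @examples
#' fit_age_slope(0.01 * (50:70), 50:70, paste0("s", 1:21)) # 0.01
#' @export
fit_age_slope <- function(values, ages, subject_ids) {
  n <- length(values)
  if (length(ages) != n || length(subject_ids) != n) {
    stop("values, ages and subject_ids must have equal length", call. = FALSE)
  }
  keep <- stats::complete.cases(values, ages, subject_ids)
  values <- values[keep]; ages <- ages[keep]; subject_ids <- subject_ids[keep]
  if (length(unique(ages)) < 2L) {
    stop("degenerate design: at least 2 distinct ages required", call. = FALSE)
  }
  one_per_subject <- !any(duplicated(subject_ids))
  if (!one_per_subject) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(values ~ ages + (1 | subject_ids), REML = TRUE)
      )),
      error = function(e) NULL)
    if (!is.null(fit)) return(unname(lme4::fixef(fit)[["ages"]]))
  }
  unname(stats::coef(stats::lm(values ~ ages))[["ages"]])
}

#' Remove the expected age effect from a metric value
#'
#' Maps a value observed at `age_years` to its expected value at the
#' reference age: `value - slope * (age - reference_age)`. Metrics without
#' a fitted slope pass through unchanged (slope 0).
#'
#' @param value Metric value.
#' @param age_years Subject age (years), non-negative.
#' @param slope Age slope (units per year).
#' @param reference_age_years Reference age, default 60.
#' @return Adjusted value.
#' @export
age_adjust <- function(value, age_years, slope, reference_age_years = 60) {
  if (any(age_years < 0)) stop("age_years must be non-negative", call. = FALSE)
  value - slope * (age_years - reference_age_years)
}

#' Directional z-score of a metric
#'
#' Standardizes an (age-adjusted) value against the control distribution,
#' flips the sign for metrics where lower values mean worse performance
#' (press amplitude, press speed, release slope, taps/min), and caps
#' above-average performance at zero so it cannot offset deficits elsewhere.
#'
#' @param value_adjusted Age-adjusted metric value.
#' @param mean,sd Control distribution parameters (`sd > 0`).
#' @param direction `"lower_worse"` or `"higher_worse"`.
#' @return Directional z >= 0.
#' @export
directional_z <- function(value_adjusted, mean, sd,
                          direction = c("higher_worse", "lower_worse")) {
  direction <- match.arg(direction)
  if (!is.numeric(sd) || any(sd <= 0)) {
    stop("reference sd must be positive", call. = FALSE)
  }
  z <- (value_adjusted - mean) / sd
  if (direction == "lower_worse") z <- -z
  pmax(z, 0)
}

#' Power-law transform of the press-amplitude z-score
#'
#' Healthy press amplitudes cluster tightly, so low-amplitude trials
#' produce extreme z-scores that would dominate the Mobility Score. Above
#' the transition (z = 10) the z-score is compressed by `A * z^k`
#' (continuous at the transition since `A * 10^k ~ 10`) and capped at
#' `pa_z_cap` (20). Identity below the transition.
#'
#' @param z Directional press-amplitude z (>= 0), vectorized.
#' @param constants A [scoring_constants()].
#' @return Transformed z in `[0, pa_z_cap]`... identical to `z` on
#'   `[0, pa_z_transition]`.
#' @export
transform_press_amp_z <- function(z, constants = scoring_constants()) {
  if (any(z < 0)) stop("press-amplitude z must be non-negative", call. = FALSE)
  out <- z
  hi <- z > constants$pa_z_transition
  out[hi] <- pmin(constants$pa_transform_A * z[hi]^constants$pa_transform_k,
                  constants$pa_z_cap)
  out
}

#' QDG Mobility Score
#'
#' `100 - mobility_scale * mean(z)` over the six directional z-scores (ISI,
#' ISI CV, press speed, press amplitude, press amplitude CV, release
#' speed), clamped to `[0, 100]`. The press-amplitude z must already be
#' transformed ([transform_press_amp_z()]). 100 is perfect mobility: every
#' metric at or better than the control mean.
#'
#' @param z Named numeric of the six directional z-scores; names must cover
#'   `isi_s`, `isi_cv`, `press_speed_mm_s`, `press_amplitude_mm`,
#'   `press_amplitude_cv`, `release_slope_mm_s`.
#' @param constants A [scoring_constants()].
#' @return Score in `[0, 100]`.
#' @examples
#' z <- setNames(rep(1, 6), c("isi_s", "isi_cv", "press_speed_mm_s",
#'                            "press_amplitude_mm", "press_amplitude_cv",
#'                            "release_slope_mm_s"))
#' mobility_score(z) # 86
#' @export
mobility_score <- function(z, constants = scoring_constants()) {
  missing <- setdiff(.qdg_mobility_metrics, names(z))
  if (length(missing)) {
    stop("mobility_score: missing metric(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  z <- z[.qdg_mobility_metrics]
  if (anyNA(z)) {
    stop("mobility_score: NA z-score for ",
         paste(names(z)[is.na(z)], collapse = ", "), call. = FALSE)
  }
  if (any(z < 0)) stop("directional z-scores must be non-negative", call. = FALSE)
  raw <- 100 - constants$mobility_scale * mean(z)
  min(max(raw, 0), 100)
}

#' Tremor Severity Score
#'
#' `%RT + 100 * mean((Amp_i / AmpMax)^2)` over the tremor strikes, where
#' `%RT` is the percent of the trace occupied by tremor and `AmpMax` the
#' device ceiling. Below `low_tremor_pct_threshold` percent tremor, the
#' amplitude component is suppressed by the factor
#' `rt_A^(rt_k * pct + rt_b)` (default `4^(0.05 pct - 1)`, i.e. 0.25 at 0%
#' rising to 0.5 at 10%) so that scant tremor cannot inflate the score
#' through a few large strikes; `mode` selects how the suppression enters.
#' With no tremor strikes the score is the percent alone. The score has no
#' upper cap.
#'
#' @param rest_tremor_pct Percent of trace duration with tremor, 0-100.
#' @param tremor_amplitudes_mm Press amplitudes of tremor strikes (mm, each
#'   in `[0, amp_max_mm]`).
#' @param constants A [scoring_constants()].
#' @param mode `"multiplicative"` (suppression factor scales the amplitude
#'   component; default), `"replace"` (the factor replaces the component),
#'   or `"none"` (no low-tremor suppression).
#' @return Tremor severity score >= 0.
#' @examples
#' tremor_severity(20, rep(12.5 / 2, 4)) # 45
#' @export
tremor_severity <- function(rest_tremor_pct, tremor_amplitudes_mm = numeric(0),
                            constants = scoring_constants(),
                            mode = c("multiplicative", "replace", "none")) {
  mode <- match.arg(mode)
  if (rest_tremor_pct < 0 || rest_tremor_pct > 100) {
    stop("rest_tremor_pct must be in [0, 100]", call. = FALSE)
  }
  if (any(tremor_amplitudes_mm < 0)) {
    stop("tremor amplitudes must be non-negative", call. = FALSE)
  }
  if (any(tremor_amplitudes_mm > constants$amp_max_mm + 1e-9)) {
    stop("tremor amplitude exceeds amp_max_mm", call. = FALSE)
  }
  if (!length(tremor_amplitudes_mm)) return(rest_tremor_pct)
  comp <- 100 * mean((tremor_amplitudes_mm / constants$amp_max_mm)^2)
  if (rest_tremor_pct < constants$low_tremor_pct_threshold && mode != "none") {
    supp <- constants$rt_A^(constants$rt_k * rest_tremor_pct + constants$rt_b)
    comp <- if (mode == "multiplicative") comp * supp else 100 * supp
  }
  rest_tremor_pct + comp
}

#' Flag a metric value against its normative threshold
#'
#' Lower-worse metrics are abnormal below the control 25th percentile;
#' higher-worse metrics above the 75th. A value exactly at the threshold is
#' normal.
#'
#' @param value (Age-adjusted) metric value.
#' @param metric Metric name (a [build_reference()] metric).
#' @param reference A `qdg_reference`.
#' @return `"normal"` or `"abnormal"`.
#' @export
flag_metric <- function(value, metric, reference) {
  entry <- reference$metrics[[metric]]
  if (is.null(entry)) stop("no reference entry for metric '", metric, "'",
                           call. = FALSE)
  if (is.na(value)) return(NA_character_)
  abnormal <- if (entry$direction == "lower_worse") {
    value < entry$threshold
  } else {
    value > entry$threshold
  }
  if (abnormal) "abnormal" else "normal"
}

#' Build a normative reference from a healthy-control metric table
#'
#' Fits age slopes (random-intercept model, [fit_age_slope()]) for the
#' age-affected metrics (press amplitude CV, release slope, press speed),
#' adjusts every control value to the reference age, and stores per-metric
#' control means, SDs, directions and percentile thresholds (25th for
#' lower-worse metrics, 75th for higher-worse; linear interpolation between
#' order statistics). Control Mobility Scores are then computed against the
#' metric reference and summarized the same way, so the Mobility Score
#' itself carries a normative threshold.
#'
#' @param control_table Data.frame with columns `subject_id`, `age_years`
#'   and the metric columns of [hand_metrics()] (one row per session).
#' @param constants A [scoring_constants()].
#' @return An object of class `qdg_reference`: `metrics` (per-metric list
#'   of `mean`, `sd`, `direction`, `threshold`, `age_slope`), `constants`,
#'   `n_subjects`, `schema`.
#' @export
build_reference <- function(control_table, constants = scoring_constants()) {
  needed <- c("subject_id", "age_years", setdiff(.qdg_reference_metrics,
                                                 "mobility_score"))
  missing <- setdiff(needed, names(control_table))
  if (length(missing)) {
    stop("control table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_sub <- length(unique(control_table$subject_id))
  if (n_sub < 2L) stop("reference requires at least 2 control subjects",
                       call. = FALSE)
  if (n_sub < 10L) {
    warning("fewer than 10 control subjects; reference will be unstable",
            call. = FALSE)
  }
  ages <- control_table$age_years
  single_age <- length(unique(ages)) < 2L

  entries <- list()
  adjusted <- list()
  for (m in setdiff(.qdg_reference_metrics, "mobility_score")) {
    vals <- control_table[[m]]
    if (anyNA(vals)) stop("control table has missing values in '", m, "'",
                          call. = FALSE)
    slope <- 0
    if (m %in% .qdg_age_adjusted_metrics && !single_age) {
      slope <- fit_age_slope(vals, ages, control_table$subject_id)
    }
    adj <- age_adjust(vals, ages, slope, constants$reference_age_years)
    sdv <- stats::sd(adj)
    if (!is.finite(sdv) || sdv <= 0) {
      stop("control metric '", m, "' has zero variance; cannot build reference",
           call. = FALSE)
    }
    dir <- metric_direction(m)
    q <- if (dir == "lower_worse") 0.25 else 0.75
    entries[[m]] <- list(mean = mean(adj), sd = sdv, direction = dir,
                         age_slope = slope,
                         threshold = unname(stats::quantile(adj, q, type = 7)))
    adjusted[[m]] <- adj
  }

  ref <- structure(list(metrics = entries, constants = constants,
                        n_subjects = n_sub, schema = "qdg-reference/1"),
                   class = "qdg_reference")

  # control Mobility Scores against the metric reference just built
  mob <- vapply(seq_len(nrow(control_table)), function(i) {
    z <- vapply(.qdg_mobility_metrics, function(m) {
      e <- entries[[m]]
      directional_z(adjusted[[m]][i], e$mean, e$sd, e$direction)
    }, numeric(1))
    z[["press_amplitude_mm"]] <- transform_press_amp_z(z[["press_amplitude_mm"]],
                                                       constants)
    mobility_score(z, constants)
  }, numeric(1))
  sdm <- stats::sd(mob)
  ref$metrics$mobility_score <- list(
    mean = mean(mob), sd = if (sdm > 0) sdm else NA_real_,
    direction = "lower_worse", age_slope = 0,
    threshold = unname(stats::quantile(mob, 0.25, type = 7)))
  ref
}

#' @export
print.qdg_reference <- function(x, ...) {
  cat(sprintf("QDG normative reference (%d control subjects)\n", x$n_subjects))
  for (m in names(x$metrics)) {
    e <- x$metrics[[m]]
    cat(sprintf("  %-20s mean %8.3f  sd %7.3f  %s threshold %8.3f  age slope %+.4g\n",
                m, e$mean, e$sd,
                if (e$direction == "lower_worse") "25th" else "75th",
                e$threshold, e$age_slope))
  }
  invisible(x)
}

# --- JSON serialization -------------------------------------------------

#' Write / read a normative reference as schema-versioned JSON
#'
#' @param reference A `qdg_reference`.
#' @param path File path.
#' @return `write_reference` returns `path` invisibly; `read_reference` the
#'   restored `qdg_reference`.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "qdg_reference"))
  payload <- list(schema = reference$schema,
                  n_subjects = reference$n_subjects,
                  constants = unclass(reference$constants),
                  metrics = reference$metrics)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(payload$schema) || !startsWith(payload$schema, "qdg-reference/")) {
    stop("not a QDG reference file: ", path, call. = FALSE)
  }
  const <- do.call(scoring_constants, payload$constants)
  metrics <- lapply(payload$metrics, function(e) {
    list(mean = e$mean, sd = e$sd, direction = e$direction,
         age_slope = e$age_slope, threshold = e$threshold)
  })
  structure(list(metrics = metrics, constants = const,
                 n_subjects = payload$n_subjects, schema = payload$schema),
            class = "qdg_reference")
}

#' Packaged synthetic normative reference
#'
#' Loads the reference shipped with the package
#' (`inst/extdata/reference_synthetic.json`), built from a 42-subject
#' simulated control cohort run end-to-end through the pipeline
#' ([simulate_control_cohort()], seed 20240601). It is synthetic: only the
#' press-amplitude calibration follows published healthy-control statistics;
#' all other distributions are simulator choices.
#'
#' @return A `qdg_reference`.
#' @export
default_reference <- function() {
  path <- system.file("extdata", "reference_synthetic.json",
                      package = "qdgraft", mustWork = TRUE)
  read_reference(path)
}
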