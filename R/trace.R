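#' Construct a RAFT displacement trace
#'
#' A `raft_trace` holds the sampled displacement of the two tensioned levers
#' ("index" and "middle") pressed during a repetitive alternating finger
#' tapping (RAFT) session, for one hand. Displacement is measured in mm from
#' the resting (fully released) lever position; time in seconds from trace
#' start. All downstream stages (strike detection, kinematic metrics,
#' scoring) consume this container.
#'
#' @param time_s Numeric vector of sample times (seconds), 0-based, strictly
#'   increasing with spacing `1/sample_rate_hz` (checked to 1e-6 s).
#' @param index_mm,middle_mm Displacement of the index / middle lever at each
#'   sample (mm, in `[0, amp_max_mm]`).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param hand `"L"` or `"R"`.
#' @param amp_max_mm Device displacement ceiling (mm); samples above it are
#'   rejected.
#' @param meta Optional named list: `subject_id`, `session_time` (ISO-8601
#'   string), `therapy_state` (free text), `age_years` (non-negative).
#'   Unknown entries are kept verbatim.
#'
#' @return An object of class `raft_trace`: a list with elements
#'   `sample_rate_hz`, `hand`, `amp_max_mm`, `meta`, and `data` (a data.frame
#'   with columns `time_s`, `index_mm`, `middle_mm`).
#' @examples
#' t <- seq(0, 1 - 0.01, by = 0.01)
#' tr <- raft_trace(t, abs(sin(2 * pi * t)) * 8, abs(cos(2 * pi * t)) * 8, 100, "R")
#' tr
#' @export
raft_trace <- function(time_s, index_mm, middle_mm, sample_rate_hz,
                       hand = c("R", "L"), amp_max_mm = 12.5, meta = list()) {
  hand <- match.arg(hand)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a positive number", call. = FALSE)
  }
  n <- length(time_s)
  if (n < 1L) stop("trace has no samples", call. = FALSE)
  if (length(index_mm) != n || length(middle_mm) != n) {
    stop("lever series must have the same length as time_s", call. = FALSE)
  }
  if (anyNA(time_s) || anyNA(index_mm) || anyNA(middle_mm)) {
    stop("trace contains missing values", call. = FALSE)
  }
  dt <- diff(time_s)
  if (n > 1L) {
    if (any(dt <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
    if (any(abs(dt - 1 / sample_rate_hz) > 1e-6)) {
      stop("sample spacing deviates from 1/sample_rate_hz by more than 1e-6 s",
           call. = FALSE)
    }
  }
  for (lv in list(index = index_mm, middle = middle_mm)) {
    if (any(lv < 0)) stop("negative displacement in trace", call. = FALSE)
    if (any(lv > amp_max_mm + 1e-9)) {
      stop("displacement exceeds amp_max_mm (", amp_max_mm, " mm)", call. = FALSE)
    }
  }
  dur <- n / sample_rate_hz
  if (dur < 1) stop("trace shorter than 1 s", call. = FALSE)
  if (!is.null(meta$age_years)) {
    if (!is.numeric(meta$age_years) || meta$age_years < 0) {
      stop("meta$age_years must be non-negative", call. = FALSE)
    }
  }
  structure(
    list(sample_rate_hz = sample_rate_hz, hand = hand, amp_max_mm = amp_max_mm,
         meta = meta,
         data = data.frame(time_s = as.numeric(time_s),
                           index_mm = as.numeric(index_mm),
                           middle_mm = as.numeric(middle_mm))),
    class = "raft_trace"
  )
}

#' @export
print.raft_trace <- function(x, ...) {
  cat(sprintf("RAFT trace: hand %s, %.1f s at %g Hz (%d samples/lever)\n",
              x$hand, nrow(x$data) / x$sample_rate_hz, x$sample_rate_hz,
              nrow(x$data)))
  if (!is.null(x$meta$subject_id)) cat("  subject:", x$meta$subject_id, "\n")
  if (!is.null(x$meta$age_years)) cat("  age:", x$meta$age_years, "y\n")
  cat(sprintf("  displacement range: index [%.2f, %.2f] mm, middle [%.2f, %.2f] mm\n",
              min(x$data$index_mm), max(x$data$index_mm),
              min(x$data$middle_mm), max(x$data$middle_mm)))
  invisible(x)
}

#' Trace duration in seconds
#'
#' Duration of the sampled interval, counting each sample as one period
#' (so a 3000-sample trace at 100 Hz is 30 s).
#'
#' @param trace A [raft_trace].
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "raft_trace"))
  nrow(trace$data) / trace$sample_rate_hz
}

# --- file I/O -----------------------------------------------------------
# Dialect: first line is a JSON header (schema, sample rate, hand, units,
# ceiling, metadata); remainder is long-format CSV with columns
# time_s, lever, displacement_mm. Times to 1e-6 s, displacement to 1e-5 mm.

#' Write a RAFT trace to a text file
#'
#' Serializes a trace as a one-line JSON header followed by long-format CSV
#' (`time_s, lever, displacement_mm`). [read_trace()] restores the trace with
#' numerically identical fields at the written precision (microsecond times,
#' 1e-5 mm displacement).
#'
#' @param trace A [raft_trace].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_trace()]
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raft_trace"))
  header <- list(
    schema = "qdg-trace/1",
    sample_rate_hz = trace$sample_rate_hz,
    hand = trace$hand,
    amp_max_mm = trace$amp_max_mm,
    units = list(time = "s", displacement = "mm"),
    meta = trace$meta
  )
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  writeLines("time_s,lever,displacement_mm", con)
  d <- trace$data
  lines <- c(sprintf("%.6f,index,%.5f", d$time_s, d$index_mm),
             sprintf("%.6f,middle,%.5f", d$time_s, d$middle_mm))
  # interleave by time so the file reads chronologically
  ord <- order(rep(d$time_s, 2L), rep(c(0L, 1L), each = nrow(d)))
  writeLines(lines[ord], con)
  invisible(path)
}

#' Read a RAFT trace from a text file
#'
#' Parses the dialect written by [write_trace()]: JSON header line, then
#' long-format CSV with columns `time_s`, `lever`, `displacement_mm`. The
#' file is validated, never repaired: missing columns, non-monotone time,
#' unequal lever series, out-of-range displacement, or unknown lever labels
#' are errors.
#'
#' @param path Input file path.
#' @return A validated [raft_trace].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("trace file too short: ", path, call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[[1L]], simplifyVector = TRUE),
                     error = function(e) stop("malformed trace header: ",
                                              conditionMessage(e), call. = FALSE))
  if (is.null(header$sample_rate_hz)) {
    stop("trace header lacks sample_rate_hz", call. = FALSE)
  }
  body <- utils::read.csv(textConnection(lines[-1L]),
                          stringsAsFactors = FALSE)
  required <- c("time_s", "lever", "displacement_mm")
  missing <- setdiff(required, names(body))
  if (length(missing)) {
    stop("trace file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  levers <- unique(body$lever)
  if (!setequal(levers, c("index", "middle"))) {
    stop("trace must contain exactly the levers 'index' and 'middle', got: ",
         paste(levers, collapse = ", "), call. = FALSE)
  }
  idx <- body[body$lever == "index", ]
  mid <- body[body$lever == "middle", ]
  if (nrow(idx) != nrow(mid)) {
    stop("lever series have unequal length", call. = FALSE)
  }
  idx <- idx[order(idx$time_s), ]
  mid <- mid[order(mid$time_s), ]
  if (max(abs(idx$time_s - mid$time_s)) > 1e-9) {
    stop("lever series are sampled at different times", call. = FALSE)
  }
  meta <- header$meta
  if (is.null(meta)) meta <- list()
  raft_trace(time_s = idx$time_s,
             index_mm = idx$displacement_mm,
             middle_mm = mid$displacement_mm,
             sample_rate_hz = header$sample_rate_hz,
             hand = if (is.null(header$hand)) "R" else header$hand,
             amp_max_mm = if (is.null(header$amp_max_mm)) 12.5 else header$amp_max_mm,
             meta = as.list(meta))
}
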