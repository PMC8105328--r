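#' @keywords internal
"_PACKAGE"

# Recognised channel labels: right/left, horizontal/vertical.
.CHANNELS <- c("R_H", "R_V", "L_H", "L_V")

#' Sampling specification
#'
#' Metadata describing how an eye-position trace was sampled: the rate in Hz
#' and the angular unit of the position values. Clinical trackers in this
#' domain sample at 200 or 400 Hz and report position in degrees.
#'
#' @param rate Sampling rate in samples per second (Hz). Must be positive.
#' @param units Angular unit tag; only `"deg"` (degrees) is recognised.
#' @return An object of class `sampling_spec` with fields `rate` and `units`.
#' @export
sampling_spec <- function(rate, units = "deg") {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  units <- match.arg(units, "deg")
  structure(list(rate = as.numeric(rate), units = units),
            class = "sampling_spec")
}

#' Single-channel eye-position trace
#'
#' One channel of an eye movement recording: an ordered sequence of angular
#' positions (degrees) with its sampling metadata. Time is implicit: sample
#' `i` (1-based) occurred at `(i - 1) / rate` seconds, which avoids the
#' clock-drift ambiguity of storing per-sample timestamps.
#'
#' @param samples Numeric vector of eye positions in degrees (length >= 1).
#'   Non-finite values are permitted at construction (they mark blinks or
#'   dropouts) but must be removed by [preprocess_trace()] before analysis.
#' @param rate Sampling rate (Hz) or a [sampling_spec()].
#' @param channel Channel label, one of `"R_H"`, `"R_V"`, `"L_H"`, `"L_V"`.
#' @return An object of class `eye_trace`.
#' @seealso [preprocess_trace()], [eye_recording()]
#' @export
eye_trace <- function(samples, rate, channel = "R_V") {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a numeric vector of length >= 1")
  spec <- if (inherits(rate, "sampling_spec")) rate else sampling_spec(rate)
  channel <- match.arg(channel, .CHANNELS)
  structure(list(channel = channel, samples = as.numeric(samples),
                 sampling = spec),
            class = "eye_trace")
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("<eye_trace> channel %s: %d samples @ %g Hz (%.2f s)\n",
              x$channel, length(x$samples), x$sampling$rate,
              trace_duration(x)))
  invisible(x)
}

#' @export
length.eye_trace <- function(x) length(x$samples)

#' Trace duration in seconds
#' @param trace An [eye_trace()].
#' @return Duration `length(samples) / rate` in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "eye_trace"))
  length(trace$samples) / trace$sampling$rate
}

#' Multi-channel eye movement recording
#'
#' A recording session for one subject: one to four [eye_trace()] channels
#' sharing a single sampling specification, with no duplicated channel label.
#'
#' @param traces A list of [eye_trace()] objects (1-4), distinct channels.
#' @param subject_id Opaque subject label.
#' @param notes Free-text notes.
#' @return An object of class `eye_recording`.
#' @export
eye_recording <- function(traces, subject_id = "subject", notes = "") {
  if (inherits(traces, "eye_trace")) traces <- list(traces)
  if (!length(traces) || length(traces) > 4L ||
      !all(vapply(traces, inherits, logical(1), "eye_trace")))
    stop("`traces` must be a list of 1-4 eye_trace objects")
  chans <- vapply(traces, function(tr) tr$channel, character(1))
  if (anyDuplicated(chans)) stop("duplicate channel labels in recording")
  rates <- vapply(traces, function(tr) tr$sampling$rate, numeric(1))
  if (length(unique(rates)) != 1L)
    stop("all traces in a recording must share one sampling rate")
  names(traces) <- chans
  structure(list(subject_id = as.character(subject_id), traces = traces,
                 notes = as.character(notes)),
            class = "eye_recording")
}

#' @export
print.eye_recording <- function(x, ...) {
  cat(sprintf("<eye_recording> subject %s: channels %s, %g Hz, %.1f s\n",
              x$subject_id, paste(names(x$traces), collapse = "/"),
              x$traces[[1]]$sampling$rate, trace_duration(x$traces[[1]])))
  invisible(x)
}

#' Extract one channel from a recording
#' @param recording An [eye_recording()].
#' @param channel Channel label.
#' @return The requested [eye_trace()].
#' @export
get_channel <- function(recording, channel) {
  stopifnot(inherits(recording, "eye_recording"))
  channel <- match.arg(channel, .CHANNELS)
  tr <- recording$traces[[channel]]
  if (is.null(tr)) stop(sprintf("channel %s not present in recording", channel))
  tr
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
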