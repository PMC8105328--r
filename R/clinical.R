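#' Per-channel position statistics
#'
#' Mean and standard deviation of an eye-position trace in degrees. The SD
#' uses the sample convention (n - 1 denominator) unless `population = TRUE`.
#'
#' @param trace An [eye_trace()] with finite samples.
#' @param population Use the population (n denominator) SD convention.
#' @return A list with `mean` and `sd` (degrees).
#' @export
position_summary <- function(trace, population = FALSE) {
  stopifnot(inherits(trace, "eye_trace"))
  x <- trace$samples
  if (!length(x)) stop("empty trace")
  if (!all(is.finite(x))) stop("trace contains non-finite samples; preprocess first")
  s <- stats::sd(x)
  if (population) s <- s * sqrt((length(x) - 1) / length(x))
  if (length(x) == 1L) s <- 0
  list(mean = mean(x), sd = s)
}

# Local maxima of `x` with at least the given prominence.
# A peak's prominence is its height minus the higher of the two minimal
# values encountered walking left and right until a strictly higher sample
# (or the series end) is met -- the usual topographic definition.
# Plateaus count once, at their midpoint. Returns integer indices.
find_peaks <- function(x, prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # candidate peaks: up-move followed (possibly after a flat run) by down-move
  rises <- which(d > 0)
  cand <- integer(0)
  for (i in rises) {
    j <- i + 1L
    while (j <= n - 1L && d[j] == 0) j <- j + 1L
    if (j <= n - 1L && d[j] < 0) cand <- c(cand, as.integer(floor((i + 1 + j) / 2)))
  }
  cand <- unique(cand)
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    p <- cand[k]; h <- x[p]
    lmin <- h; i <- p
    while (i > 1L) { i <- i - 1L; if (x[i] > h) break; lmin <- min(lmin, x[i]) }
    rmin <- h; i <- p
    while (i < n) { i <- i + 1L; if (x[i] > h) break; rmin <- min(rmin, x[i]) }
    keep[k] <- (h - max(lmin, rmin)) >= prominence
  }
  cand[keep]
}

#' Per-cycle amplitude, period and frequency
#'
#' Locates oscillation maxima with a topographic-prominence criterion and
#' reports, for each cycle spanning successive maxima, the peak-to-peak
#' amplitude (max - min within the cycle, degrees), the period (spacing of
#' the bounding maxima, seconds) and the frequency (1/period, Hz). The
#' amplitude of a nystagmus is the magnitude of the change in eye position
#' with each oscillation, and its frequency comes from the timing of the
#' peak-to-peak excursions, so both are defined cycle by cycle.
#'
#' @param trace An [eye_trace()]; detrend first (see
#'   [detrend_moving_average()]) or set `detrend = TRUE` when baseline drift
#'   is present.
#' @param prominence Peak prominence threshold in degrees. Default: 25% of
#'   the trace's interquartile range, an explicit stand-in for the by-eye
#'   peak marking of chart-recording practice.
#' @param detrend Subtract a centred moving average (window `detrend_window`
#'   seconds) before peak finding. Amplitudes are still measured on the
#'   series handed in (detrended if requested).
#' @param detrend_window Detrending window in seconds.
#' @return A data.frame with columns `cycle_index`, `amplitude`, `period`,
#'   `frequency`.
#' @export
cycle_metrics <- function(trace, prominence = NULL, detrend = FALSE,
                          detrend_window = 4) {
  stopifnot(inherits(trace, "eye_trace"))
  x <- trace$samples
  rate <- trace$sampling$rate
  if (detrend) {
    w <- odd_window(detrend_window * rate, length(x))
    x <- detrend_moving_average(x, w)
  }
  if (is.null(prominence)) prominence <- 0.25 * stats::IQR(x)
  if (prominence <= 0) prominence <- .Machine$double.eps
  pk <- find_peaks(x, prominence)
  if (length(pk) < 2L) stop("fewer than two maxima found at this prominence")
  ncyc <- length(pk) - 1L
  amp <- per <- numeric(ncyc)
  for (k in seq_len(ncyc)) {
    seg <- x[pk[k]:pk[k + 1L]]
    amp[k] <- max(seg) - min(seg)
    per[k] <- (pk[k + 1L] - pk[k]) / rate
  }
  data.frame(cycle_index = seq_len(ncyc), amplitude = amp, period = per,
             frequency = 1 / per)
}

#' Standard clinical assessment of a recording
#'
#' Aggregates [position_summary()] over all channels, [cycle_metrics()] over
#' the oscillating channel, and the fixation-stability criterion: a channel
#' is stable when its mean position magnitude is within 10 minutes of arc of
#' straight ahead and its SD does not exceed `sd_bound`. Nystagmus intensity
#' is the product of mean amplitude and mean frequency (degrees x Hz).
#'
#' @param recording An [eye_recording()].
#' @param oscillating_channel Channel carrying the nystagmus.
#' @param fixation_bound Mean-position bound in degrees (default 10 arcmin).
#' @param sd_bound SD bound in degrees for stability (default 10 arcmin;
#'   only the mean criterion is standard, the SD guard is ours).
#' @param ... Passed to [cycle_metrics()] (e.g. `detrend = TRUE`).
#' @return A list of class `clinical_summary`: per-channel `position`
#'   data.frame (`channel`, `mean`, `sd`, `fixation_stable`), `cycles`
#'   data.frame, and scalars `mean_amplitude`, `mean_frequency`,
#'   `intensity`.
#' @export
clinical_summary <- function(recording, oscillating_channel,
                             fixation_bound = 10 / 60, sd_bound = 10 / 60,
                             ...) {
  stopifnot(inherits(recording, "eye_recording"))
  osc <- get_channel(recording, oscillating_channel)
  pos <- do.call(rbind, lapply(recording$traces, function(tr) {
    ps <- position_summary(tr)
    data.frame(channel = tr$channel, mean = ps$mean, sd = ps$sd,
               fixation_stable = abs(ps$mean) <= fixation_bound &&
                 ps$sd <= sd_bound)
  }))
  rownames(pos) <- NULL
  cyc <- cycle_metrics(osc, ...)
  ma <- mean(cyc$amplitude)
  mf <- mean(cyc$frequency)
  structure(list(subject_id = recording$subject_id, position = pos,
                 cycles = cyc, oscillating_channel = oscillating_channel,
                 mean_amplitude = ma, mean_frequency = mf,
                 intensity = ma * mf),
            class = "clinical_summary")
}

#' @export
print.clinical_summary <- function(x, ...) {
  cat(sprintf("<clinical_summary> subject %s (oscillating %s)\n",
              x$subject_id, x$oscillating_channel))
  print(x$position, row.names = FALSE)
  cat(sprintf("mean amplitude %.2f deg, mean frequency %.2f Hz, intensity %.2f deg.Hz (%d cycles)\n",
              x$mean_amplitude, x$mean_frequency, x$intensity,
              nrow(x$cycles)))
  invisible(x)
}

#' Detect saccadic intrusions
#'
#' Finds small step-like fixation interruptions: runs where the smoothed eye
#' velocity exceeds `velocity_threshold` and whose net position step falls
#' inside `amplitude_band`. Pendular nystagmus below 1.5 Hz has peak
#' velocities well under the default 20 deg/s, so the velocity gate separates
#' saccadic steps from the underlying oscillation. Opposite-direction events
#' closer together than `pair_gap` are flagged as back-to-back (monophasic)
#' pairs.
#'
#' @param trace An [eye_trace()].
#' @param velocity_threshold Velocity gate in deg/s.
#' @param amplitude_band Two-element numeric, accepted step magnitudes (deg).
#' @param smooth Velocity smoothing window in seconds.
#' @param pair_gap Maximum onset gap (seconds) for pairing.
#' @return A data.frame with columns `onset` (s), `amplitude` (deg, signed
#'   magnitude given by `direction`), `direction` (+1/-1), `paired`.
#'   Zero rows when nothing qualifies.
#' @export
detect_saccadic_intrusions <- function(trace, velocity_threshold = 20,
                                       amplitude_band = c(0.3, 1.0),
                                       smooth = 0.015, pair_gap = 0.4) {
  stopifnot(inherits(trace, "eye_trace"),
            velocity_threshold > 0, all(amplitude_band > 0))
  x <- trace$samples
  rate <- trace$sampling$rate
  empty <- data.frame(onset = numeric(0), amplitude = numeric(0),
                      direction = numeric(0), paired = logical(0))
  if (length(x) < 5L) return(empty)
  v <- c(NA, (x[-1] - x[-length(x)]) * rate)  # backward difference, deg/s
  k <- odd_window(smooth * rate, length(x))
  if (k >= 3) {
    vs <- stats::filter(v, rep(1 / k, k), sides = 2)
    v[!is.na(vs)] <- vs[!is.na(vs)]
  }
  fast <- is.finite(v) & abs(v) > velocity_threshold
  if (!any(fast)) return(empty)
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  pad <- max(1L, round(0.005 * rate))  # measure the step just outside the run
  onset <- amp <- numeric(0)
  for (i in seq_along(starts)) {
    a <- max(1L, starts[i] - pad); b <- min(length(x), ends[i] + pad)
    step <- x[b] - x[a]
    if (abs(step) >= amplitude_band[1] && abs(step) <= amplitude_band[2]) {
      onset <- c(onset, (starts[i] - 1) / rate)
      amp <- c(amp, step)
    }
  }
  if (!length(onset)) return(empty)
  paired <- rep(FALSE, length(onset))
  if (length(onset) > 1L) {
    gaps <- diff(onset)
    flips <- sign(amp[-1]) != sign(amp[-length(amp)])
    hit <- which(gaps <= pair_gap & flips)
    paired[hit] <- TRUE; paired[hit + 1L] <- TRUE
  }
  data.frame(onset = onset, amplitude = abs(amp), direction = sign(amp),
             paired = paired)
}

# Clamp a window length to an odd integer >= 3 not exceeding n (or n-1 if n even).
odd_window <- function(w, n) {
  w <- max(3L, round(w))
  if (w %% 2L == 0L) w <- w + 1L
  while (w > n) w <- w - 2L
  max(w, 3L)
}
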