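#' Fourier amplitude spectrum of one segment
#'
#' Computes the one-sided relative amplitude spectrum of a recording
#' segment: the mean is removed, the segment is weighted by a symmetric
#' triangular (Bartlett) taper that is 1 at the centre and falls to 0 at the
#' endpoints, padded at either end by `pad` zeros to refine the frequency
#' grid, and Fourier transformed. With the defaults (window 4000 samples,
#' pad 1000) at 200 Hz the padded length is 6000 samples and the frequency
#' resolution is 200/6000 = 0.0333 Hz, fine enough to resolve oscillations
#' down to 0.25 Hz. Amplitudes are normalised so the maximum is 1.
#'
#' @param segment Numeric vector of eye positions (degrees); its length must
#'   equal `window_len`.
#' @param rate Sampling rate in Hz.
#' @param window_len Segment length in samples (default 4000).
#' @param pad Number of zeros added at each end (default 1000).
#' @param segment_start Start time of the segment (seconds), carried through
#'   for bookkeeping.
#' @return An object of class `amplitude_spectrum` with fields
#'   `frequencies` (Hz, uniform from 0 to `rate/2`), `relative_amplitudes`
#'   (max-normalised, >= 0), `resolution` (Hz, = `rate / (window_len + 2*pad)`)
#'   and `segment_start`.
#' @export
amplitude_spectrum <- function(segment, rate, window_len = 4000, pad = 1000,
                               segment_start = 0) {
  if (length(segment) != window_len)
    stop(sprintf("segment length %d != window_len %d", length(segment),
                 window_len))
  if (!all(is.finite(segment))) stop("segment contains non-finite values")
  n <- window_len
  x <- segment - mean(segment)
  # Bartlett taper: zero at both endpoints, one at the centre
  taper <- 1 - abs(2 * (seq_len(n) - 1) / (n - 1) - 1)
  x <- c(rep(0, pad), x * taper, rep(0, pad))
  m <- length(x)
  amp <- Mod(stats::fft(x))[seq_len(floor(m / 2) + 1L)]
  if (max(amp) > 0) amp <- amp / max(amp)
  structure(list(frequencies = (seq_along(amp) - 1) * rate / m,
                 relative_amplitudes = amp,
                 resolution = rate / m,
                 segment_start = segment_start),
            class = "amplitude_spectrum")
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf("<amplitude_spectrum> %d bins, resolution %.4f Hz, start %.1f s\n",
              length(x$frequencies), x$resolution, x$segment_start))
  invisible(x)
}

#' Spectra of successive recording segments
#'
#' Slides a window of `window_len` samples across the trace in steps of
#' `hop` samples (default: non-overlapping) and computes
#' [amplitude_spectrum()] for each complete segment.
#'
#' @param trace An [eye_trace()].
#' @inheritParams amplitude_spectrum
#' @param hop Hop between segment starts, in samples.
#' @return A list of `amplitude_spectrum` objects, one per complete segment
#'   (`floor((N - window_len)/hop) + 1` of them).
#' @export
successive_spectra <- function(trace, window_len = 4000, hop = window_len,
                               pad = 1000) {
  stopifnot(inherits(trace, "eye_trace"), hop >= 1)
  x <- trace$samples
  rate <- trace$sampling$rate
  if (length(x) < window_len)
    stop("trace shorter than one spectral window")
  starts <- seq(1L, length(x) - window_len + 1L, by = hop)
  lapply(starts, function(s)
    amplitude_spectrum(x[s:(s + window_len - 1L)], rate,
                       window_len = window_len, pad = pad,
                       segment_start = (s - 1) / rate))
}

#' Average of several amplitude spectra
#'
#' Bin-wise mean of the relative amplitudes of spectra sharing one grid,
#' renormalised to a maximum of 1. Useful as a stationary summary next to
#' the per-segment spectra.
#'
#' @param spectra A list of `amplitude_spectrum` objects on a common grid.
#' @return An `amplitude_spectrum`.
#' @export
mean_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  amp <- rowMeans(vapply(spectra, function(s) s$relative_amplitudes,
                         numeric(length(spectra[[1]]$frequencies))))
  if (max(amp) > 0) amp <- amp / max(amp)
  out <- spectra[[1]]
  out$relative_amplitudes <- amp
  out$segment_start <- NA_real_
  out
}

#' Dominant frequency of a spectrum
#'
#' Frequency of the largest relative amplitude at or above `min_freq`. The
#' default `min_freq` of one bin excludes the 0 Hz bin, which baseline drift
#' would otherwise dominate. Ties break toward the lower frequency.
#'
#' @param spectrum An `amplitude_spectrum`.
#' @param min_freq Lowest admissible frequency (Hz); default one resolution
#'   bin.
#' @return The dominant frequency in Hz.
#' @export
dominant_frequency <- function(spectrum, min_freq = spectrum$resolution) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  sel <- spectrum$frequencies >= min_freq
  if (!any(sel)) stop("no spectral bins at or above min_freq")
  f <- spectrum$frequencies[sel]
  a <- spectrum$relative_amplitudes[sel]
  f[which.max(a)]  # which.max returns the first (lowest-frequency) maximum
}
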