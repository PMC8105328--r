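#' Delay embedding of a scalar time series
#'
#' Slides a window of length `d` (the embedding dimension) across the
#' series, producing delay vectors `X_i = [x(i), x(i+lag), ...,
#' x(i+(d-1)*lag)]` that reconstruct the trajectory of the underlying
#' dynamical system in a d-dimensional space.
#'
#' @param series Numeric vector, length >= `(d-1)*lag + 1`, all finite.
#' @param d Embedding dimension (default 7, sufficient for oculomotor time
#'   series).
#' @param lag Delay in samples (default 1: consecutive samples).
#' @return An object of class `delay_embedding`: `vectors` (an
#'   `(N-(d-1)*lag) x d` matrix, row i = the delay vector starting at i),
#'   `d`, `lag`.
#' @export
delay_embed <- function(series, d = 7, lag = 1) {
  stopifnot(is.numeric(series), d >= 2, lag >= 1)
  n <- length(series)
  rows <- n - (d - 1L) * lag
  if (rows < 1L) stop("series too short for this embedding")
  if (!all(is.finite(series))) stop("series contains non-finite values")
  m <- vapply(0:(d - 1L), function(k) series[(1L + k * lag):(rows + k * lag)],
              numeric(rows))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  structure(list(vectors = m, d = d, lag = lag), class = "delay_embedding")
}

#' Principal-component projection of a delay embedding
#'
#' Centres the delay vectors column-wise and projects them onto their
#' leading principal components (default three) to visualise the
#' reconstructed attractor. Components are the eigenvectors of the
#' covariance matrix in decreasing eigenvalue order.
#'
#' @param embedding A `delay_embedding`.
#' @param n_components Number of components to keep (<= `d`, default 3).
#' @return An object of class `projected_trajectory`: `coordinates`
#'   (rows x n_components score matrix), `explained_variance`
#'   (non-increasing eigenvalue fractions), `component_vectors`
#'   (d x n_components, orthonormal columns).
#' @export
project_principal <- function(embedding, n_components = 3) {
  stopifnot(inherits(embedding, "delay_embedding"),
            n_components >= 1, n_components <= embedding$d)
  m <- embedding$vectors
  if (nrow(m) < embedding$d) stop("need at least d delay vectors")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev^2) <= 0) stop("rank-0 embedding (constant series)")
  k <- seq_len(n_components)
  structure(list(coordinates = pc$x[, k, drop = FALSE],
                 explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[k],
                 component_vectors = pc$rotation[, k, drop = FALSE]),
            class = "projected_trajectory")
}

#' Classify the attractor underlying an oscillation segment
#'
#' A quantitative stand-in for the visual attractor categorisation of phase
#' portraits. The decision works on the amplitude spectrum of the
#' (detrended) segment:
#' \itemize{
#'   \item near-zero oscillation power (SD below `still_sd`) -> `fixed_point`
#'     (stable gaze);
#'   \item one fundamental whose prominent peaks are all at integer
#'     multiples of it (within `harmonic_tol`), with little off-peak
#'     spectral power -> `limit_cycle` (periodic);
#'   \item two prominent incommensurate fundamentals -- their ratio differs
#'     from every rational p/q with q <= 4 by more than 2 spectral bins --
#'     with little off-peak power -> `torus` (quasiperiodic);
#'   \item otherwise (broadband power or unresolvable peak structure) ->
#'     `higher_dimensional` (nonperiodic).
#' }
#' Peak structure alone cannot separate phase-coherent chaos from a limit
#' cycle (such oscillations have sharp, nearly harmonic spectral lines), so
#' a spectral-stationarity check runs first whenever the segment holds at
#' least two spectral windows: the mean pairwise correlation of the
#' amplitude spectra of successive half-overlapping segments. Periodic and
#' quasiperiodic oscillations keep the same line spectrum in every segment
#' (correlation ~1); a nonperiodic oscillation's spectral content wanders,
#' and a correlation below `consistency_min` classifies it as
#' `higher_dimensional` directly.
#'
#' @param trace_segment Numeric vector of eye positions (degrees), already
#'   detrended; must span at least 3 putative oscillation cycles.
#' @param rate Sampling rate in Hz.
#' @param upo Optional `upo_result`; when given, the segment must span at
#'   least 3 cycles of its period.
#' @param peak_frac Relative-amplitude threshold for a prominent peak.
#' @param harmonic_tol Harmonic tolerance as a fraction of the fundamental.
#' @param broadband_frac Off-peak fraction of spectral energy above which
#'   the spectrum counts as broadband.
#' @param still_sd Segment SD (degrees) below which gaze counts as stable.
#' @param min_freq Lowest frequency (Hz) considered for peaks.
#' @param consistency_min Smallest mean inter-segment spectral correlation
#'   compatible with a stationary (periodic or quasiperiodic) spectrum.
#' @param seg_window Window length in samples for the stationarity check
#'   (shrunk to half the segment when the segment is shorter than two
#'   windows; the check is skipped when fewer than two windows fit).
#' @return An object of class `attractor_class`: `label` (one of
#'   `fixed_point`, `limit_cycle`, `torus`, `higher_dimensional`) and
#'   `evidence` (a list with the peak table, fundamentals, ratio tests and
#'   off-peak energy fraction backing the label).
#' @export
classify_attractor <- function(trace_segment, rate, upo = NULL,
                               peak_frac = 0.1, harmonic_tol = 0.05,
                               broadband_frac = 0.2, still_sd = 0.1,
                               min_freq = 0.1, consistency_min = 0.995,
                               seg_window = 4000) {
  stopifnot(is.numeric(trace_segment), rate > 0)
  x <- trace_segment
  n <- length(x)
  if (!is.null(upo) && n / rate < 3 * upo$period)
    stop("segment spans fewer than 3 cycles of the orbit period")
  if (n < 64L) stop("segment too short to classify")
  if (stats::sd(x) < still_sd)
    return(structure(list(label = "fixed_point",
                          evidence = list(sd = stats::sd(x))),
                     class = "attractor_class"))
  consistency <- spectral_consistency(x, rate, seg_window, min_freq)
  spec <- amplitude_spectrum(x, rate, window_len = n, pad = 1000)
  res <- spec$resolution
  f <- spec$frequencies
  a <- spec$relative_amplitudes
  sel <- f >= min_freq & f <= min(rate / 2, 25)
  pk_idx <- find_peaks(a, prominence = peak_frac)
  pk_idx <- pk_idx[f[pk_idx] >= min_freq & a[pk_idx] >= peak_frac]
  peaks <- data.frame(frequency = f[pk_idx], amplitude = a[pk_idx])
  peaks <- peaks[order(-peaks$amplitude), , drop = FALSE]
  evid <- list(peaks = peaks, resolution = res,
               spectral_consistency = consistency)
  if (!is.na(consistency) && consistency < consistency_min)
    return(structure(list(label = "higher_dimensional", evidence = evid),
                     class = "attractor_class"))
  if (!nrow(peaks))
    return(structure(list(label = "higher_dimensional", evidence = evid),
                     class = "attractor_class"))
  # group peaks under fundamentals: lowest unexplained peak starts a group
  fund <- c()
  remaining <- sort(peaks$frequency)
  while (length(remaining)) {
    f0 <- remaining[1]
    fund <- c(fund, f0)
    mult <- round(remaining / f0)
    harm <- mult >= 1 & abs(remaining - mult * f0) <= harmonic_tol * f0
    remaining <- remaining[!harm]
    if (length(fund) > 3) break
  }
  evid$fundamentals <- fund
  # off-peak (broadband) energy: amplitude^2 outside neighbourhoods of the
  # detected peaks, as a fraction of total in-band energy
  nbhd <- rep(FALSE, length(f))
  for (fp in peaks$frequency) {
    hw <- max(4 * res, harmonic_tol * fp)
    nbhd <- nbhd | abs(f - fp) <= hw
  }
  e_tot <- sum(a[sel]^2)
  off <- sum(a[sel & !nbhd]^2) / e_tot
  evid$offpeak_energy_fraction <- off
  broadband <- off > broadband_frac
  label <- if (length(fund) == 1 && !broadband) {
    "limit_cycle"
  } else if (length(fund) == 2 && !broadband) {
    ratio <- fund[2] / fund[1]
    pq <- expand.grid(p = 1:12, q = 1:4)
    pq <- pq[pq$p / pq$q > 1, ]
    commensurate <- any(abs(ratio - pq$p / pq$q) * fund[1] <= 2 * res)
    evid$ratio <- ratio
    evid$commensurate <- commensurate
    if (commensurate) "limit_cycle" else "torus"
  } else "higher_dimensional"
  structure(list(label = label, evidence = evid), class = "attractor_class")
}

# Mean pairwise Pearson correlation of the amplitude spectra of
# half-overlapping segments, over the 0.1-5 Hz oscillation band.
# NA when fewer than two windows fit.
spectral_consistency <- function(x, rate, seg_window, min_freq,
                                 band_max = 5) {
  w <- min(seg_window, floor(length(x) / 2))
  if (w < 64L) return(NA_real_)
  starts <- seq(1L, length(x) - w + 1L, by = max(1L, floor(w / 2)))
  if (length(starts) < 2L) return(NA_real_)
  amps <- vapply(starts, function(s) {
    sp <- amplitude_spectrum(x[s:(s + w - 1L)], rate, window_len = w,
                             pad = 1000)
    sel <- sp$frequencies >= min_freq & sp$frequencies <= band_max
    sp$relative_amplitudes[sel]
  }, numeric(sum({
    m <- w + 2000
    fr <- (0:floor(m / 2)) * rate / m
    fr >= min_freq & fr <= band_max
  })))
  cm <- stats::cor(amps)
  mean(cm[lower.tri(cm)])
}

#' @export
print.attractor_class <- function(x, ...) {
  cat(sprintf("<attractor_class> %s", x$label))
  if (!is.null(x$evidence$fundamentals))
    cat(sprintf(" (fundamentals %s Hz, off-peak energy %.2f)",
                paste(sprintf("%.2f", x$evidence$fundamentals),
                      collapse = ", "),
                x$evidence$offpeak_energy_fraction))
  cat("\n")
  invisible(x)
}
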