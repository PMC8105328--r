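# Mean cycle period of the Rossler flow (a = b = 0.2, c = 5.7) in model
# time units, measured from long integrations (FFT peak and mean
# zero-crossing interval agree to 3 decimals).
.ROSSLER_PERIOD <- 5.856

#' Specification of a synthetic nystagmus waveform
#'
#' Describes one synthetic vertical oscillation in the terms the analyses
#' assume: dynamical regime, peak-to-peak amplitude, (mean) frequency,
#' upward/downward asymmetry, baseline drift, saccadic intrusions and
#' measurement noise. The amplitude and frequency defaults span the bands
#' reported clinically for uniocular vertical nystagmus (2.0-4.0 degrees,
#' 0.25-1.5 Hz).
#'
#' @param regime `"periodic"`, `"quasiperiodic"` or `"nonperiodic"`.
#' @param amplitude Peak-to-peak amplitude in degrees.
#' @param frequency Fundamental / mean cycle frequency in Hz.
#' @param asymmetry Ratio of the fastest to slowest phase speed within a
#'   cycle (> 1 makes the downward phase slower than the upward one, as
#'   observed clinically). Periodic regime only.
#' @param secondary_freq_ratio Ratio of the second tone's frequency to the
#'   fundamental (quasiperiodic only); the golden ratio by default, the
#'   canonical irrational.
#' @param secondary_amp_frac Second tone's amplitude as a fraction of the
#'   fundamental's (quasiperiodic only).
#' @param chaos_params Named list of flow constants for the nonperiodic
#'   regime (Rossler `a`, `b`, `c`; classic spiral-chaos values by default).
#' @param drift_rate Baseline drift scale in degrees/s (linear component;
#'   the random-walk component uses the same scale).
#' @param intrusion_rate Poisson rate of saccadic intrusions, events/s.
#' @param intrusion_amplitude_band Intrusion amplitude band in degrees.
#' @param noise_sd White measurement-noise SD in degrees.
#' @param duration Recording length in seconds. With the defaults,
#'   `duration * rate` comfortably exceeds 7! so entropy windows are valid.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed; the same spec and seed give bitwise-identical
#'   traces.
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(regime = c("periodic", "quasiperiodic",
                                     "nonperiodic"),
                          amplitude = 3.0, frequency = 0.5, asymmetry = 1.5,
                          secondary_freq_ratio = (1 + sqrt(5)) / 2,
                          secondary_amp_frac = 0.8,
                          chaos_params = list(a = 0.2, b = 0.2, c = 5.7),
                          drift_rate = 0.02, intrusion_rate = 0.2,
                          intrusion_amplitude_band = c(0.3, 1.0),
                          noise_sd = 0.05, duration = 60, rate = 200,
                          seed = 1) {
  regime <- match.arg(regime)
  stopifnot(amplitude > 0, frequency > 0, asymmetry >= 1, duration > 0,
            rate > 0, noise_sd >= 0, drift_rate >= 0, intrusion_rate >= 0)
  if (duration * rate < factorial(7))
    stop("duration * rate must be at least 7! = 5040 for entropy analysis")
  structure(list(regime = regime, amplitude = amplitude,
                 frequency = frequency, asymmetry = asymmetry,
                 secondary_freq_ratio = secondary_freq_ratio,
                 secondary_amp_frac = secondary_amp_frac,
                 chaos_params = chaos_params, drift_rate = drift_rate,
                 intrusion_rate = intrusion_rate,
                 intrusion_amplitude_band = intrusion_amplitude_band,
                 noise_sd = noise_sd, duration = duration, rate = rate,
                 seed = seed),
            class = "waveform_spec")
}

# One RK4 step of the Rossler flow.
rossler_step <- function(y, h, a, b, c) {
  f <- function(y) c(-y[2] - y[3], y[1] + a * y[2], b + y[3] * (y[1] - c))
  k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
  k4 <- f(y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# x-component of the Rossler flow, time-scaled so the mean cycle frequency
# is `frequency` Hz, one RK4 step per output sample after a discarded
# transient.
rossler_series <- function(n, rate, frequency, pars, y0) {
  h <- frequency * .ROSSLER_PERIOD / rate
  y <- y0
  # transient: 100 model time units
  for (i in seq_len(ceiling(100 / max(h, 1e-6)))) {
    y <- rossler_step(y, min(h, 0.05), pars$a, pars$b, pars$c)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    y <- rossler_step(y, h, pars$a, pars$b, pars$c)
    out[i] <- y[1]
  }
  out
}

#' Generate a synthetic nystagmus trace
#'
#' Realises a [waveform_spec()] as an [eye_trace()]:
#' \itemize{
#'   \item periodic: an asymmetric pendular cycle, a sinusoid whose phase is
#'     warped within each cycle so the descending limb is slower than the
#'     ascending one by the requested speed ratio (this phase warp is what
#'     puts phase-locked harmonics into the spectrum);
#'   \item quasiperiodic: the sum of two tones whose frequency ratio is the
#'     requested irrational (golden ratio by default);
#'   \item nonperiodic: the x-component of the Rossler flow with classic
#'     spiral-chaos constants, integrated with a fixed-step 4th-order
#'     Runge-Kutta scheme from a seed-perturbed initial condition and
#'     rescaled in time and amplitude to the requested band.
#' }
#' On top of the oscillation: linear-plus-random-walk baseline drift,
#' Poisson step-like saccadic intrusions with a 20 ms raised-cosine rise and
#' a return saccade ~150 ms later (back-to-back pairs), and white
#' measurement noise. Everything is reproducible from `spec$seed`.
#'
#' @param spec A [waveform_spec()].
#' @param channel Channel label for the returned trace.
#' @return An [eye_trace()] of `duration * rate` samples.
#' @export
generate_waveform <- function(spec, channel = "R_V") {
  stopifnot(inherits(spec, "waveform_spec"))
  n <- round(spec$duration * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  half <- spec$amplitude / 2
  with_seed(spec$seed, {
    core <- switch(spec$regime,
      periodic = {
        m <- (spec$asymmetry - 1) / (spec$asymmetry + 1)
        u <- 2 * pi * spec$frequency * t + stats::runif(1, 0, 2 * pi)
        half * sin(u + m * sin(u))
      },
      quasiperiodic = {
        a1 <- half / (1 + spec$secondary_amp_frac)
        a2 <- a1 * spec$secondary_amp_frac
        ph <- stats::runif(2, 0, 2 * pi)
        a1 * sin(2 * pi * spec$frequency * t + ph[1]) +
          a2 * sin(2 * pi * spec$frequency * spec$secondary_freq_ratio * t +
                     ph[2])
      },
      nonperiodic = {
        y0 <- c(1, 1, 0) + stats::rnorm(3, 0, 0.5)
        x <- rossler_series(n, spec$rate, spec$frequency, spec$chaos_params,
                            y0)
        rng <- range(x)
        (x - mean(rng)) * spec$amplitude / diff(rng)
      })
    drift <- spec$drift_rate * (t - spec$duration / 2) *
      sample(c(-1, 1), 1) +
      cumsum(stats::rnorm(n, 0, spec$drift_rate / sqrt(spec$rate)))
    x <- core + drift
    if (spec$intrusion_rate > 0)
      x <- x + intrusion_train(n, spec$rate, spec$intrusion_rate,
                               spec$intrusion_amplitude_band)
    if (spec$noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd)
    eye_trace(x, rate = spec$rate, channel = channel)
  })
}

# Additive saccadic-intrusion signal: Poisson onsets, raised-cosine 20 ms
# steps out and back (monophasic back-to-back pairs), uniform amplitudes in
# the band, random direction. Consumes the current RNG stream.
intrusion_train <- function(n, rate, events_per_s, band, rise = 0.02,
                            hold = 0.15) {
  sig <- numeric(n)
  k <- stats::rpois(1, events_per_s * n / rate)
  if (k == 0) return(sig)
  onsets <- sort(stats::runif(k, 0, n / rate - (rise * 2 + hold)))
  amps <- stats::runif(k, band[1], band[2]) * sample(c(-1, 1), k,
                                                    replace = TRUE)
  ramp_n <- max(2L, round(rise * rate))
  ramp <- (1 - cos(pi * seq(0, 1, length.out = ramp_n))) / 2
  for (i in seq_len(k)) {
    s <- round(onsets[i] * rate) + 1L
    r <- round((onsets[i] + rise + hold) * rate) + 1L
    step <- function(at, sgn) {
      idx <- at:(at + ramp_n - 1L)
      ok <- idx <= n
      sig[idx[ok]] <<- sig[idx[ok]] + sgn * ramp[ok]
      if (at + ramp_n <= n)
        sig[(at + ramp_n):n] <<- sig[(at + ramp_n):n] + sgn
    }
    step(s, amps[i])
    step(r, -amps[i])
  }
  sig
}

#' Generate a synthetic five-member cohort
#'
#' Builds five labelled recordings mirroring the clinical layout the
#' analyses target: one periodic member (1.5 Hz, 2.6 degrees), one
#' quasiperiodic member (1.2 Hz fundamental, 3.5 degrees) and three
#' nonperiodic members (0.25-0.5 Hz, 2.0-4.0 degrees). Each member has one
#' oscillating vertical channel in the affected eye, a quiet fellow
#' vertical channel holding central gaze within 10 arcmin, and two
#' horizontal channels carrying conjugate saccadic intrusions.
#'
#' @param seed Integer master seed; per-member seeds are derived from it.
#' @param duration Member recording length in seconds (default 60).
#' @return An object of class `synthetic_cohort`: `members` (named list of
#'   [eye_recording()]s), `specs` (the ground-truth [waveform_spec()]s),
#'   `oscillating` (named channel labels).
#' @export
generate_cohort <- function(seed = 1, duration = 60) {
  layout <- data.frame(
    id = c("S1", "S2", "S3", "S4", "S5"),
    regime = c("nonperiodic", "periodic", "nonperiodic", "nonperiodic",
               "quasiperiodic"),
    amplitude = c(4.0, 2.6, 2.5, 2.0, 3.5),
    frequency = c(0.5, 1.5, 0.5, 0.25, 1.2),
    eye = c("R", "L", "L", "R", "R"),
    stringsAsFactors = FALSE)
  members <- list(); specs <- list(); osc <- character(0)
  for (i in seq_len(nrow(layout))) {
    sd_i <- (seed * 131L + i * 17L) %% .Machine$integer.max
    spec <- waveform_spec(regime = layout$regime[i],
                          amplitude = layout$amplitude[i],
                          frequency = layout$frequency[i],
                          intrusion_rate = 0,  # intrusions live on the
                          duration = duration, # horizontal channels
                          seed = sd_i)
    vert <- paste0(layout$eye[i], "_V")
    fellow <- paste0(setdiff(c("R", "L"), layout$eye[i]), "_V")
    affected <- generate_waveform(spec, channel = vert)
    n <- length(affected$samples)
    rest <- with_seed(sd_i + 1L, {
      quiet <- stats::rnorm(n, mean = stats::runif(1, -0.08, 0.08),
                            sd = spec$noise_sd)
      sacc <- intrusion_train(n, spec$rate, 0.2, c(0.3, 1.0))
      list(
        quiet = eye_trace(quiet, spec$rate, channel = fellow),
        rh = eye_trace(sacc + stats::rnorm(n, 0, spec$noise_sd), spec$rate,
                       channel = "R_H"),
        lh = eye_trace(sacc + stats::rnorm(n, 0, spec$noise_sd), spec$rate,
                       channel = "L_H"))
    })
    members[[layout$id[i]]] <- eye_recording(
      list(affected, rest$quiet, rest$rh, rest$lh),
      subject_id = layout$id[i])
    specs[[layout$id[i]]] <- spec
    osc[layout$id[i]] <- vert
  }
  structure(list(members = members, specs = specs, oscillating = osc),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  for (id in names(x$members)) {
    sp <- x$specs[[id]]
    cat(sprintf("  %s: %-13s %.1f deg, %.2f Hz, %s oscillating\n", id,
                sp$regime, sp$amplitude, sp$frequency, x$oscillating[[id]]))
  }
  invisible(x)
}
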