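# Shared fixture builders. All fixtures are generated in code; tests that
# need randomness set their own seeds.

# Pure sine trace: peak amplitude `amp` (degrees, half of peak-to-peak).
sine_trace <- function(freq, amp = 1, duration = 60, rate = 200,
                       noise_sd = 0, channel = "R_V", phase = 0) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- amp * sin(2 * pi * freq * t + phase)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  eye_trace(x, rate = rate, channel = channel)
}

# Independent ordinal-pattern oracle: a literal selection sort per window
# with the stable tie rule (earlier index ranks first). Returns a character
# key per window, e.g. "1-3-2".
oracle_patterns <- function(x, d) {
  n <- length(x) - d + 1L
  out <- character(n)
  for (i in seq_len(n)) {
    w <- x[i:(i + d - 1L)]
    idx <- seq_len(d)
    perm <- integer(d)
    for (k in seq_len(d)) {
      best <- 1L
      for (j in seq_along(idx)) {
        if (w[idx[j]] < w[idx[best]]) best <- j  # strict: ties keep earlier
      }
      perm[k] <- idx[best]
      idx <- idx[-best]
    }
    out[i] <- paste(perm, collapse = "-")
  }
  out
}

# Pattern keys of a pattern_distribution, matching oracle_patterns format.
dist_keys <- function(dist) {
  apply(dist$patterns, 1L, paste, collapse = "-")
}

# Crossing-interval oracle: brute-force scan for sign changes with linear
# interpolation, no vectorisation shared with the implementation.
oracle_crossings <- function(x, rate, threshold = 0) {
  times <- numeric(0)
  for (i in seq_len(length(x) - 1L)) {
    if (x[i] < threshold && x[i + 1L] >= threshold) {
      frac <- (threshold - x[i]) / (x[i + 1L] - x[i])
      times <- c(times, (i - 1 + frac) / rate)
    }
  }
  diff(times)
}

expect_trace_equal <- function(a, b, tol = 1e-9) {
  testthat::expect_equal(a$samples, b$samples, tolerance = tol)
  testthat::expect_equal(a$sampling$rate, b$sampling$rate)
}
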