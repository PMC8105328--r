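test_that("sine crossings give 2 s intervals and match the brute-force oracle", {
  tr <- sine_trace(0.5, amp = 2, duration = 30)
  iv <- crossing_intervals(tr, 0, "rising")
  expect_true(all(abs(iv$intervals - 2.0) <= 1 / 200))
  expect_error(crossing_intervals(eye_trace(rep(1, 1000), 200)),
               "fewer than 3")
  set.seed(31)
  noisy <- sine_trace(0.5, amp = 2, duration = 30, noise_sd = 0.1)
  iv2 <- crossing_intervals(noisy, 0, "rising")
  expect_equal(iv2$intervals, oracle_crossings(noisy$samples, 200))
})

test_that("hysteresis suppresses noise re-crossings without biasing the period", {
  set.seed(32)
  noisy <- sine_trace(0.5, amp = 1, duration = 60, noise_sd = 0.1)
  det <- detrend_moving_average(noisy, 4)
  plain <- crossing_intervals(det, 0, "rising")
  schmitt <- crossing_intervals(det, 0, "rising", hysteresis = "auto")
  expect_lt(length(schmitt$intervals), length(plain$intervals))
  expect_lt(abs(median(schmitt$intervals) - 2.0), 0.05)
  # falling direction works symmetrically
  fall <- crossing_intervals(det, 0, "falling", hysteresis = "auto")
  expect_lt(abs(median(fall$intervals) - 2.0), 0.05)
})

test_that("interval transform follows the local linear map fixed point", {
  # identical intervals: every triple degenerate, fallback returns T
  tp <- transform_intervals(interval_sequence(rep(2, 10)))
  expect_equal(tp$estimates, rep(2, 8))
  expect_equal(tp$excluded_count, 8)
  # geometric approach I_{n+1} = 0.5 I_n + 1 -> fixed point 2 everywhere
  iv <- numeric(8); iv[1] <- 4
  for (i in 2:8) iv[i] <- 0.5 * iv[i - 1] + 1
  tp2 <- transform_intervals(interval_sequence(iv))
  expect_equal(tp2$estimates, rep(2, 6), tolerance = 1e-9)
  expect_equal(tp2$excluded_count, 0)
  expect_error(transform_intervals(interval_sequence(c(1, 2))), "fewer than 3")
})

test_that("transform matches an independent per-triple recomputation", {
  set.seed(33)
  iv <- 2 + rnorm(40, 0, 0.2)
  tp <- transform_intervals(interval_sequence(abs(iv), dt = 0.005))
  iv <- abs(iv)
  for (n in 2:(length(iv) - 1)) {
    k <- (iv[n + 1] - iv[n]) / (iv[n] - iv[n - 1])
    expected <- if (abs(iv[n] - iv[n - 1]) < 0.005 || abs(1 - k) < 1e-6)
      iv[n] else (iv[n + 1] - k * iv[n]) / (1 - k)
    expect_equal(tp$estimates[n - 1], expected)
  }
})

test_that("histograms use 0.05 s bins aligned to zero and sum to one", {
  h <- upo_histogram(rep(2.0, 5))
  expect_equal(sum(h$relative_frequency), 1)
  expect_equal(h$relative_frequency[h$mids == 2.025], 1)
  expect_true(all(abs(h$breaks / 0.05 - round(h$breaks / 0.05)) < 1e-9))
  set.seed(34)
  # modes placed at bin centres so the generating bins are unambiguous
  bimodal <- c(rnorm(300, 1.025, 0.005), rnorm(200, 2.475, 0.005))
  h2 <- upo_histogram(bimodal)
  expect_equal(sum(h2$relative_frequency), 1)
  top2 <- order(h2$relative_frequency, decreasing = TRUE)[1:2]
  expect_setequal(round(sort(h2$mids[top2]), 3), c(1.025, 2.475))
  expect_error(upo_histogram(NaN), "no finite")
})

test_that("surrogate testing is reproducible, permutation-sane and degenerate-safe", {
  set.seed(35)
  e <- rnorm(81, 0, 0.07)
  iv <- interval_sequence(2 + diff(e), dt = 0.005)
  r1 <- surrogate_significance(iv, n_surrogates = 99, seed = 5)
  r2 <- surrogate_significance(iv, n_surrogates = 99, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$histogram$surrogate_mean, r2$histogram$surrogate_mean)
  expect_equal(r1$frequency, 1 / r1$period)
  expect_gte(r1$p_value, 1 / 100)
  expect_lte(r1$p_value, 1)
  # peak bin sits at the true period
  expect_lt(abs(r1$period - 2.0), 0.05)
  # identical intervals: surrogates are permutations of identical values,
  # so every surrogate ties the observed peak and the plus-one rule gives 1
  same <- surrogate_significance(interval_sequence(rep(1.5, 30)),
                                 n_surrogates = 19, seed = 1)
  expect_equal(same$p_value, 1)
  expect_error(surrogate_significance(iv, n_surrogates = 10), "at least 19")
})

test_that("the orbit-following segment is the best qualifying run", {
  tr <- sine_trace(0.5, amp = 2, duration = 30)
  iv <- interval_sequence(c(2.0, 2.0, 2.0, 3.1, 2.8), dt = 0.005)
  seg <- locate_upo_segment(tr, iv, period = 2.0)
  expect_equal(seg$n_cycles, 3)
  expect_equal(seg$start_time, 0)
  expect_equal(seg$end_time, 6.0)
  # all intervals within tolerance: the whole span qualifies
  iv2 <- interval_sequence(c(2.0, 1.95, 2.05, 2.0), dt = 0.005)
  seg2 <- locate_upo_segment(tr, iv2, period = 2.0)
  expect_equal(seg2$n_cycles, 4)
  expect_error(locate_upo_segment(tr, iv, period = 10), "within tolerance")
})

test_that("segment choice beats any same-length run (exhaustive check)", {
  set.seed(36)
  period <- 2
  # drifting-period data: qualifying intervals come in runs
  iv <- period + c(rnorm(5, 0, 0.03), rep(0.8, 3), rnorm(7, 0, 0.03),
                   rep(-0.9, 2), rnorm(4, 0, 0.03))
  seq_iv <- interval_sequence(abs(iv), dt = 0.005)
  tr <- sine_trace(0.5, amp = 2, duration = 60)
  seg <- locate_upo_segment(tr, seq_iv, period, tolerance = 0.1)
  len <- seg$n_cycles
  x <- seq_iv$intervals
  devs <- vapply(seq_len(length(x) - len + 1L), function(s) {
    run <- x[s:(s + len - 1L)]
    if (all(abs(run - period) <= 0.1 * period)) mean(abs(run - period))
    else Inf
  }, numeric(1))
  expect_equal(seg$mean_abs_dev, min(devs))
})

test_that("noise SD estimation recovers white noise on a smooth carrier", {
  set.seed(37)
  x <- sine_trace(0.4, amp = 1.5, duration = 60, noise_sd = 0.05)$samples
  expect_lt(abs(estimate_noise_sd(x) - 0.05), 0.01)
})
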