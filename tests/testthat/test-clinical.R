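test_that("position_summary matches closed forms and a two-pass oracle", {
  expect_equal(position_summary(eye_trace(rep(1.5, 100), 200)),
               list(mean = 1.5, sd = 0))
  tr <- sine_trace(0.5, amp = 2, duration = 10)  # whole periods: mean 0
  expect_lt(abs(position_summary(tr)$mean), 1e-9)
  set.seed(11)
  x <- rnorm(1000, 0.3, 0.7)
  ps <- position_summary(eye_trace(x, 200))
  m <- sum(x) / length(x)
  expect_equal(ps$mean, m)
  expect_equal(ps$sd, sqrt(sum((x - m)^2) / (length(x) - 1)))
  expect_error(position_summary(eye_trace(c(1, NA), 200)), "non-finite")
})

test_that("cycle metrics recover a pure sine's closed-form values", {
  tr <- sine_trace(0.5, amp = 2, duration = 20)
  cyc <- cycle_metrics(tr)
  expect_gte(nrow(cyc), 8)
  # period quantised to the sample grid: one sample spacing tolerance
  expect_true(all(abs(cyc$period - 2.0) <= 1 / 200 + 1e-12))
  expect_true(all(abs(cyc$frequency - 0.5) <= 0.5 - 1 / (2 + 1 / 200)))
  expect_true(all(abs(cyc$amplitude - 4.0) <= 0.01))
  expect_equal(cyc$frequency, 1 / cyc$period)
  expect_error(cycle_metrics(eye_trace(rep(1, 1000), 200)),
               "fewer than two maxima")
})

test_that("cycle metrics recover asymmetric pendular generator parameters", {
  spec <- waveform_spec("periodic", amplitude = 4.0, frequency = 0.5,
                        drift_rate = 0, intrusion_rate = 0, noise_sd = 0,
                        seed = 21)
  cyc <- cycle_metrics(generate_waveform(spec))
  expect_lt(abs(mean(cyc$amplitude) - 4.0) / 4.0, 0.05)
  expect_lt(abs(mean(cyc$frequency) - 0.5) / 0.5, 0.05)
})

test_that("clinical_summary composes the pieces and applies the 10 arcmin rule", {
  # oscillation matching a clinical amplitude/frequency pair: 2.6 deg, 1.5 Hz
  spec <- waveform_spec("periodic", amplitude = 2.6, frequency = 1.5,
                        drift_rate = 0, intrusion_rate = 0, noise_sd = 0,
                        seed = 3)
  osc <- generate_waveform(spec, channel = "L_V")
  stable <- eye_trace(rep(5 / 60, length(osc$samples)), 200, "R_V")
  unstable <- eye_trace(rep(15 / 60, length(osc$samples)), 200, "R_H")
  cs <- clinical_summary(eye_recording(list(osc, stable, unstable), "t"),
                         "L_V")
  expect_equal(cs$intensity, cs$mean_amplitude * cs$mean_frequency)
  expect_lt(abs(cs$intensity - 2.6 * 1.5), 0.2)  # 3.9 deg.Hz
  pos <- cs$position
  expect_true(pos$fixation_stable[pos$channel == "R_V"])   # 5 arcmin
  expect_false(pos$fixation_stable[pos$channel == "R_H"])  # 15 arcmin
  expect_false(pos$fixation_stable[pos$channel == "L_V"])
})

test_that("injected saccadic steps are recovered; smooth oscillations are not", {
  rate <- 200
  n <- 2000
  x <- numeric(n)
  onset <- 1000
  ramp <- seq(0, 0.5, length.out = 4)  # 0.5 deg over 20 ms = 25 deg/s
  x[onset:(onset + 3)] <- ramp
  x[(onset + 4):n] <- 0.5
  ev <- detect_saccadic_intrusions(eye_trace(x, rate))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$amplitude - 0.5), 0.05)
  expect_equal(ev$direction, 1)
  expect_lt(abs(ev$onset - (onset - 1) / rate), 0.05)
  # pure pendular motion: peak velocity 2*pi deg/s, far below the 20 deg/s gate
  expect_equal(nrow(detect_saccadic_intrusions(sine_trace(0.5, amp = 2))), 0)
  expect_equal(nrow(detect_saccadic_intrusions(eye_trace(rep(1, n), rate))),
               0)
})

test_that("back-to-back intrusion pairs are flagged as paired", {
  rate <- 200
  x <- numeric(3000)
  # out at 5 s, back at 5.17 s
  x[1001:1004] <- seq(0, 0.6, length.out = 4)
  x[1005:1034] <- 0.6
  x[1035:1038] <- seq(0.6, 0, length.out = 4)
  ev <- detect_saccadic_intrusions(eye_trace(x, rate))
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$paired))
  expect_equal(ev$direction, c(1, -1))
})
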