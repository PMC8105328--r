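test_that("constructors enforce their invariants", {
  expect_error(sampling_spec(-1), "positive")
  expect_error(eye_trace(numeric(0), 200), "length >= 1")
  tr <- eye_trace(c(1, 2, 3), 200, channel = "L_V")
  expect_s3_class(tr, "eye_trace")
  expect_equal(trace_duration(tr), 3 / 200)
  expect_error(eye_recording(list(tr, tr)), "duplicate channel")
  expect_error(eye_recording(list(tr, eye_trace(1:3, 400, "R_V"))),
               "one sampling rate")
  rec <- eye_recording(list(tr, eye_trace(1:3, 200, "R_V")), "s1")
  expect_named(rec$traces, c("L_V", "R_V"))
  expect_error(get_channel(rec, "L_H"), "not present")
})

test_that("a 4-column CSV at 200 Hz loads with all channels and inferred rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  n <- 100
  df <- data.frame(time_s = (0:(n - 1)) * 0.005,
                   r_h_deg = sin(1:n), r_v_deg = cos(1:n),
                   l_h_deg = (1:n) / n, l_v_deg = rep(0.5, n))
  write.csv(df, path, row.names = FALSE)
  rec <- load_recording(path)
  expect_length(rec$traces, 4)
  expect_equal(rec$traces[[1]]$sampling$rate, 200)  # inferred from 5 ms steps
  expect_equal(rec$traces$R_V$samples, df$r_v_deg)
})

test_that("seeded round trip write -> load preserves samples", {
  set.seed(41)
  rec <- eye_recording(list(eye_trace(rnorm(500, 0, 2), 200, "R_V"),
                            eye_trace(rnorm(500, 0, 0.1), 200, "L_V")),
                       subject_id = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- load_recording(path, mapping = list(rate = 200))
  expect_trace_equal(back$traces$R_V, rec$traces$R_V)
  expect_trace_equal(back$traces$L_V, rec$traces$L_V)
})

test_that("rate inference matches the generating rate exactly and rejects bad time", {
  for (rate in c(200, 400, 250)) {
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(time_s = (0:199) / rate, r_v_deg = rnorm(200)),
              path, row.names = FALSE)
    expect_identical(load_recording(path)$traces$R_V$sampling$rate, rate)
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 0.005, 0.004, 0.02),
                       r_v_deg = rnorm(4)), path, row.names = FALSE)
  expect_error(load_recording(path), "not strictly increasing")
  write.csv(data.frame(time_s = c(0, 0.005, 0.02, 0.03), r_v_deg = rnorm(4)),
            path, row.names = FALSE)
  expect_error(load_recording(path), "varies")
})

test_that("load errors on missing files and unmappable columns", {
  expect_error(load_recording("no/such/file.csv"), "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = (0:9) / 200, pos = rnorm(10)), path,
            row.names = FALSE)
  expect_error(load_recording(path), "no position columns")
  expect_error(load_recording(path, mapping = list(
    channels = c(R_V = "absent"))), "absent")
})

test_that("preprocess interpolates interior gaps linearly and trims edges", {
  tr <- eye_trace(c(NA, 1, NA, 3, 2, NA), 200)
  out <- preprocess_trace(tr)
  expect_equal(out$samples, c(1, 2, 3, 2))  # midpoint of 1 and 3 is 2
  expect_error(preprocess_trace(tr, gap_policy = "drop_edges"), "interior")
  expect_error(preprocess_trace(eye_trace(rep(NA_real_, 5), 200)),
               "entirely non-finite")
  long_gap <- eye_trace(c(1, rep(NA, 150), 2), 200)
  expect_error(preprocess_trace(long_gap), "max_gap")
})

test_that("preprocess is the identity without gaps or resampling", {
  set.seed(7)
  tr <- eye_trace(rnorm(400), 200)
  expect_trace_equal(preprocess_trace(tr), tr, tol = 0)
})

test_that("downsampling 400 -> 200 Hz halves the length after anti-aliasing", {
  set.seed(8)
  tr <- eye_trace(sin(2 * pi * 0.5 * (0:799) / 400) + rnorm(800, 0, 0.01),
                  400)
  out <- preprocess_trace(tr, target_rate = 200)
  expect_equal(out$sampling$rate, 200)
  expect_equal(length(out$samples), 400)
  expect_error(preprocess_trace(tr, target_rate = 300), "integer multiple")
})

test_that("flat key=value config files parse numbers and strings", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("n_surrogates = 99  # fewer for speed", "direction = falling",
               "", "threshold=0.5"), path)
  cfg <- read_config(path)
  expect_identical(cfg$n_surrogates, 99)
  expect_identical(cfg$direction, "falling")
  expect_identical(cfg$threshold, 0.5)
})
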