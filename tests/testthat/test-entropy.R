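test_that("moving-average detrend removes constants, ramps and slow drift", {
  expect_equal(detrend_moving_average(rep(3.2, 50), 5), rep(0, 50))
  ramp <- 0.1 * (1:100)
  out <- detrend_moving_average(ramp, 11)
  expect_true(all(abs(out[6:95]) < 1e-9))   # interior of a centred mean
  expect_true(any(abs(out[c(1:5, 96:100)]) > 1e-9))
  expect_error(detrend_moving_average(1:10, 4), "odd")
  expect_error(detrend_moving_average(1:10, 11), "odd integer")
  # sine + 0.05 deg/s drift, ~4 s window: residual slope < 5% of original
  set.seed(61)
  rate <- 200
  t <- (0:11999) / rate
  x <- sin(2 * pi * 0.5 * t) + 0.05 * t + rnorm(12000, 0, 0.02)
  det <- detrend_moving_average(x, 801)
  slope <- unname(coef(lm(det ~ t))[2])
  expect_lt(abs(slope), 0.05 * 0.05)
})

test_that("ordinal mapping reproduces the worked examples and handles ties", {
  d1 <- ordinal_distribution(c(0.1, 3, 10.5), d = 3)
  expect_equal(unname(d1$patterns[1, ]), c(1L, 2L, 3L))
  d2 <- ordinal_distribution(c(1.2, -4, 3), d = 3)
  expect_equal(unname(d2$patterns[1, ]), c(2L, 1L, 3L))
  # stable tie rule: earlier index ranks first
  d3 <- ordinal_distribution(c(2, 2, 1), d = 3)
  expect_equal(unname(d3$patterns[1, ]), c(3L, 1L, 2L))
  expect_error(ordinal_distribution(c(1, 2), d = 3), "shorter")
})

test_that("pattern distributions match the brute-force oracle", {
  set.seed(62)
  for (rep in 1:4) {
    d <- sample(3:5, 1)
    x <- rnorm(500)
    dist <- ordinal_distribution(x, d)
    oracle <- table(oracle_patterns(x, d))
    expect_equal(dist$total_vectors, length(x) - d + 1L)
    expect_setequal(dist_keys(dist), names(oracle))
    expect_equal(dist$probabilities[match(names(oracle), dist_keys(dist))],
                 as.numeric(oracle) / dist$total_vectors)
    expect_equal(sum(dist$probabilities), 1, tolerance = 1e-12)
  }
})

test_that("entropy attains its closed-form values", {
  x <- c(1, 2, 3, 4, 5, 6)  # strictly increasing: one pattern
  er <- permutation_entropy(ordinal_distribution(x, 3))
  expect_identical(er$H_p, 0)
  expect_identical(er$h_p, 0)
  # two equiprobable patterns at d = 3: up-up and down-down alternation
  zig <- rep(c(0, 1), 50)
  er2 <- permutation_entropy(ordinal_distribution(zig, 3))
  expect_equal(er2$H_p, log(2))
  expect_equal(er2$h_p, log(2) / log(6))
  # uniform over all d! patterns -> h_p = 1
  uni <- structure(list(patterns = matrix(0L, 6, 3),
                        probabilities = rep(1 / 6, 6), d = 3,
                        total_vectors = 600),
                   class = "pattern_distribution")
  expect_equal(permutation_entropy(uni)$h_p, 1)
})

test_that("h_p is invariant under strictly increasing transforms", {
  set.seed(63)
  for (rep in 1:5) {
    x <- rnorm(800)
    h0 <- permutation_entropy(ordinal_distribution(x, 4))$h_p
    for (f in list(exp, function(v) v^3 + 2, function(v) 1 / (1 + exp(-v)),
                   function(v) 100 * v - 7)) {
      expect_identical(permutation_entropy(ordinal_distribution(f(x), 4))$h_p,
                       h0)
    }
  }
  # monotone series of any length has h_p = 0
  for (n in c(10, 100, 6000))
    expect_identical(
      permutation_entropy(ordinal_distribution(cumsum(runif(n) + 0.01), 7 ))$h_p,
      0)
})

test_that("sliding windows honour the 7! sample arithmetic", {
  expect_equal(round(25.2 * 200), factorial(7))
  x <- rnorm(5040)
  es <- sliding_entropy(x, rate = 200, detrend_window = NULL)
  expect_length(es$h_p_values, 1)  # series exactly one window long
  expect_error(sliding_entropy(rnorm(5000), rate = 200), "shorter")
  expect_warning(sliding_entropy(rnorm(2000), rate = 200, T_w = 5,
                                 detrend_window = NULL),
                 "cannot realise")
  # hop arithmetic: 60 s at 200 Hz, 0.5 s hop -> 70 windows
  set.seed(64)
  es2 <- sliding_entropy(rnorm(12000), rate = 200)
  expect_length(es2$h_p_values, 70)
  expect_true(all(es2$h_p_values >= 0 & es2$h_p_values <= 1))
  # white noise fills the pattern space almost uniformly; the finite-sample
  # ceiling is h_p ~ 1 - (K-1)/(2N ln K) ~ 0.94 for N = 5034 draws over
  # K = 5040 patterns (Miller-Madow), slightly lower still because
  # overlapping windows correlate the draws; measured median 0.932
  expect_gte(median(es2$h_p_values), 0.92)
})

test_that("entropy comparison does Bonferroni arithmetic and ranks by median", {
  mk <- function(vals, id) structure(
    list(window_starts = seq_along(vals), h_p_values = vals, T_w = 25.2,
         d = 7, subject_id = id), class = "entropy_window_series")
  a <- mk(rep(0.5, 10), "a")
  cmp2 <- compare_entropies(list(a, mk(rep(0.5, 10), "b")), alpha = 0.01)
  expect_equal(cmp2$pairs$p_adjusted, 1)
  expect_false(any(cmp2$pairs$significant))
  set.seed(65)
  five <- lapply(1:5, function(i) mk(runif(8, i / 10, i / 10 + 0.05),
                                     paste0("s", i)))
  cmp5 <- compare_entropies(five)
  expect_equal(nrow(cmp5$pairs), 10)
  expect_equal(cmp5$pairs$p_adjusted, pmin(1, cmp5$pairs$p_raw * 10))
  expect_equal(cmp5$ranking,
               cmp5$summary$series[order(cmp5$summary$median_h_p)])
  expect_error(compare_entropies(list(a)), "at least 2")
  expect_error(compare_entropies(list(mk(1:3 / 10, "x"), a)), "5 windows")
})
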