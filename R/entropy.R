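# Centred running mean with shrinking (truncated) windows at the edges.
# O(n) via prefix sums. `w` must be odd.
running_mean <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving-average detrend
#'
#' Subtracts the centred moving average of the signal to eliminate baseline
#' drift before the nonlinear analyses. Edge samples use shrinking
#' (truncated) windows, so the output has the same length as the input.
#'
#' @param series Numeric vector (or an [eye_trace()], in which case the
#'   window is given in seconds and a detrended trace is returned).
#' @param window Moving-average window in samples (odd, >= 3) for numeric
#'   input, or in seconds for an `eye_trace`. The 4 s default for traces
#'   covers at least one full period of the slowest (0.25 Hz) oscillations
#'   of interest.
#' @return Detrended numeric vector, or detrended `eye_trace`.
#' @export
detrend_moving_average <- function(series, window) {
  if (inherits(series, "eye_trace")) {
    if (missing(window)) window <- 4
    w <- odd_window(window * series$sampling$rate, length(series$samples))
    return(eye_trace(series$samples - running_mean(series$samples, w),
                     rate = series$sampling$rate, channel = series$channel))
  }
  w <- as.integer(window)
  if (is.na(w) || w < 3L || w %% 2L == 0L || w > length(series))
    stop("`window` must be an odd integer in [3, length(series)]")
  series - running_mean(series, w)
}

# Encode the ordinal pattern of each length-d window (lag 1) of `x` as an
# integer code in base d. Ties rank by original position (stable order),
# so the pattern is the permutation j with x[i+j[1]-1] <= ... <= x[i+j[d]-1].
ordinal_codes <- function(x, d) {
  n <- length(x)
  if (n < d) stop("series shorter than the embedding dimension")
  m <- vapply(0:(d - 1L), function(k) x[(1L + k):(n - d + 1L + k)],
              numeric(n - d + 1L))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  base <- d^(0:(d - 1L))
  apply(m, 1L, function(row) sum((order(row) - 1L) * base))
}

# Decode an integer code back to the permutation (for reporting).
decode_pattern <- function(code, d) {
  out <- integer(d)
  for (k in seq_len(d)) {
    out[k] <- as.integer(code %% d) + 1L
    code <- code %/% d
  }
  out
}

#' Ordinal pattern distribution of a time series
#'
#' Maps every consecutive delay vector `[x(i), x(i+1), ..., x(i+d-1)]` to
#' the symbol sequence `[j1, ..., jd]` that arranges it into increasing
#' order (so `x(i+j1-1) <= x(i+j2-1) <= ... <= x(i+jd-1)`) and tabulates the
#' empirical probabilities of the distinct symbol sequences. Ties rank by
#' original position (the earlier index ranks first), which keeps patterns
#' well defined on quantised data. For example, with `d = 3` the delay
#' vector `[0.1, 3, 10.5]` maps to `[1, 2, 3]` and `[1.2, -4, 3]` maps to
#' `[2, 1, 3]`.
#'
#' @param series Numeric vector, length >= `d`.
#' @param d Embedding dimension (>= 2; default 7, sufficient to capture the
#'   variance of oculomotor time series).
#' @return An object of class `pattern_distribution`: `patterns` (K x d
#'   integer matrix, one permutation per row), `probabilities` (sum to 1,
#'   all > 0), `d`, `total_vectors` (= `length(series) - d + 1`).
#' @export
ordinal_distribution <- function(series, d = 7) {
  stopifnot(is.numeric(series), d >= 2)
  if (length(series) < d) stop("series shorter than the embedding dimension")
  codes <- ordinal_codes(series, d)
  tab <- table(codes)
  patt <- t(vapply(as.numeric(names(tab)), decode_pattern, integer(d), d = d))
  structure(list(patterns = patt,
                 probabilities = as.numeric(tab) / length(codes),
                 d = d, total_vectors = length(codes)),
            class = "pattern_distribution")
}

#' Permutation entropy of an ordinal pattern distribution
#'
#' Shannon entropy of the symbol-sequence probabilities,
#' `H_p = -sum(P_j * ln(P_j))` in nats, together with its normalised form
#' `h_p = H_p / ln(d!)`, which lies in `[0, 1]`: 0 when a single pattern
#' occurs (a fully predictable, e.g. monotone, series) and 1 when all `d!`
#' patterns are equally probable (a maximally irregular series).
#'
#' @param distribution A `pattern_distribution` from [ordinal_distribution()].
#' @return A list with `H_p` (nats) and `h_p` (dimensionless).
#' @export
permutation_entropy <- function(distribution) {
  stopifnot(inherits(distribution, "pattern_distribution"))
  p <- distribution$probabilities
  if (!length(p)) stop("empty pattern distribution")
  H <- -sum(p * log(p)) + 0  # + 0 normalises the K = 1 case's -0 to 0
  list(H_p = H, h_p = H / lfactorial(distribution$d))
}

#' Sliding-window normalised permutation entropy
#'
#' Detrends the series once with a moving average, then computes the
#' normalised permutation entropy `h_p` in overlapping windows of length
#' `T_w` seconds advanced by `hop` seconds. The default window of 25.2 s
#' with `d = 7` spans 5040 samples at 200 Hz -- exactly 7! -- so every
#' possible symbol sequence can in principle be observed within a single
#' window; a warning is issued when `T_w * rate < d!`.
#'
#' @param trace An [eye_trace()] (or numeric vector with `rate` given).
#' @param rate Sampling rate in Hz (taken from the trace when given one).
#' @param d Embedding dimension (default 7).
#' @param T_w Window length in seconds (default 25.2).
#' @param hop Window advance in seconds (default 0.5; "all overlapping
#'   windows" at the per-sample level is statistically redundant at 200 Hz).
#' @param detrend_window Moving-average detrend window in seconds (default
#'   4; `NULL` skips detrending, e.g. for an already-detrended series).
#' @return An object of class `entropy_window_series`: `window_starts`
#'   (seconds), `h_p_values`, `T_w`, `d`, `subject_id`.
#' @export
sliding_entropy <- function(trace, rate = NULL, d = 7, T_w = 25.2, hop = 0.5,
                            detrend_window = 4) {
  if (inherits(trace, "eye_trace")) {
    x <- trace$samples
    rate <- trace$sampling$rate
    subject <- trace$channel
  } else {
    x <- trace
    if (is.null(rate)) stop("`rate` must be given for a plain numeric series")
    subject <- ""
  }
  win <- round(T_w * rate)
  hop_n <- max(1L, round(hop * rate))
  if (length(x) < win) stop("series shorter than one entropy window")
  if (win < factorial(d))
    warning(sprintf("window of %d samples cannot realise all %d patterns",
                    win, factorial(d)))
  if (!is.null(detrend_window)) {
    w <- odd_window(detrend_window * rate, length(x))
    x <- x - running_mean(x, w)
  }
  # patterns depend only on position, not the window, so code once
  codes <- ordinal_codes(x, d)
  starts <- seq(1L, length(x) - win + 1L, by = hop_n)
  npat <- win - d + 1L
  h <- vapply(starts, function(s) {
    p <- tabulate(factor(codes[s:(s + npat - 1L)]))
    p <- p / npat
    (-sum(p * log(p)) + 0) / lfactorial(d)
  }, numeric(1))
  structure(list(window_starts = (starts - 1) / rate, h_p_values = h,
                 T_w = T_w, d = d, subject_id = subject),
            class = "entropy_window_series")
}

#' @export
print.entropy_window_series <- function(x, ...) {
  cat(sprintf("<entropy_window_series> %s: %d windows of %.1f s (d = %d), median h_p %.4f\n",
              x$subject_id, length(x$h_p_values), x$T_w, x$d,
              stats::median(x$h_p_values)))
  invisible(x)
}

#' Compare permutation-entropy distributions across recordings
#'
#' All pairwise two-sided Wilcoxon rank-sum tests (normal approximation with
#' tie correction) on the window-wise `h_p` values of two or more
#' recordings, Bonferroni-corrected over the number of pairs, with medians,
#' median absolute deviations and the ranking by increasing median `h_p`
#' (i.e. increasing waveform complexity). The window counts of different
#' recordings generally differ, so the two-sample (unpaired) test is used.
#'
#' @param series_list A list of >= 2 `entropy_window_series`, ideally named;
#'   unnamed entries are labelled by their `subject_id` or position.
#' @param alpha Significance level applied to the adjusted p-values
#'   (default 0.01).
#' @return An object of class `entropy_comparison`: `summary` data.frame
#'   (`series`, `median_h_p`, `mad_h_p`, `n_windows`), `pairs` data.frame
#'   (`a`, `b`, `p_raw`, `p_adjusted`, `significant`), `ranking` (series
#'   labels by increasing median `h_p`), `alpha`.
#' @export
compare_entropies <- function(series_list, alpha = 0.01) {
  if (length(series_list) < 2L) stop("need at least 2 entropy series")
  stopifnot(all(vapply(series_list, inherits, logical(1),
                       "entropy_window_series")))
  nw <- vapply(series_list, function(s) length(s$h_p_values), integer(1))
  if (any(nw < 5L)) stop("every series needs at least 5 windows")
  labs <- names(series_list)
  if (is.null(labs)) labs <- rep("", length(series_list))
  fallback <- vapply(seq_along(series_list), function(i) {
    sid <- series_list[[i]]$subject_id
    if (nzchar(sid)) sid else sprintf("series%d", i)
  }, character(1))
  labs <- ifelse(nzchar(labs), labs, fallback)
  med <- vapply(series_list, function(s) stats::median(s$h_p_values),
                numeric(1))
  madv <- vapply(series_list, function(s)
    stats::mad(s$h_p_values, constant = 1), numeric(1))
  cmb <- utils::combn(length(series_list), 2)
  npairs <- ncol(cmb)
  p_raw <- vapply(seq_len(npairs), function(j) {
    a <- series_list[[cmb[1, j]]]$h_p_values
    b <- series_list[[cmb[2, j]]]$h_p_values
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    # complete ties make the normal approximation 0/0; no evidence at all
    if (is.nan(p)) 1 else p
  }, numeric(1))
  p_adj <- pmin(1, p_raw * npairs)
  structure(list(
    summary = data.frame(series = labs, median_h_p = med, mad_h_p = madv,
                         n_windows = nw, row.names = NULL),
    pairs = data.frame(a = labs[cmb[1, ]], b = labs[cmb[2, ]],
                       p_raw = p_raw, p_adjusted = p_adj,
                       significant = p_adj < alpha, row.names = NULL),
    ranking = labs[order(med)], alpha = alpha),
    class = "entropy_comparison")
}

#' @export
print.entropy_comparison <- function(x, ...) {
  cat("<entropy_comparison>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("ranking (increasing complexity): %s\n",
              paste(x$ranking, collapse = " -> ")))
  cat(sprintf("%d/%d pairs significant at adjusted p < %g\n",
              sum(x$pairs$significant), nrow(x$pairs), x$alpha))
  invisible(x)
}
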