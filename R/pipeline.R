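#' Default analysis configuration
#'
#' Central container for every tunable parameter of the framework, so one
#' object fully determines an analysis run. Any entry may be overridden via
#' `...` or a flat key=value file read with [read_config()].
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `framework_config`:
#' \describe{
#'   \item{oscillating_channel}{channel to analyse, or `"auto"` to pick the
#'     vertical channel with the largest SD.}
#'   \item{detrend_window}{moving-average detrend window, seconds (4).}
#'   \item{threshold, direction}{crossing threshold on the detrended trace
#'     (0 degrees, i.e. the local mean) and direction ("rising").}
#'   \item{hysteresis}{crossing dead band in degrees, or "auto" (3x the
#'     estimated noise SD); see [crossing_intervals()].}
#'   \item{min_separation}{crossing refractory, seconds (0, off).}
#'   \item{bin_width}{period histogram bin width, seconds (0.05).}
#'   \item{min_period}{smallest admissible orbit period, seconds (0.2).}
#'   \item{n_surrogates}{shuffled surrogates for the orbit test (500).}
#'   \item{alpha_upo}{orbit significance level (0.05).}
#'   \item{upo_tolerance}{relative tolerance for the orbit-following run
#'     (0.1).}
#'   \item{window_len, pad, hop_spec}{Fourier window, zero padding and hop,
#'     samples (4000, 1000, 4000).}
#'   \item{embed_d, embed_lag}{embedding dimension and lag (7, 1).}
#'   \item{embed_full_trace}{embed the whole detrended trace instead of the
#'     orbit-following segment (FALSE).}
#'   \item{T_w, hop_entropy}{entropy window and hop, seconds (25.2, 0.5).}
#'   \item{alpha_entropy}{comparison significance level (0.01).}
#'   \item{seed}{master seed for the stochastic stages (1).}
#' }
#' @export
framework_config <- function(...) {
  cfg <- list(oscillating_channel = "auto", detrend_window = 4,
              threshold = 0, direction = "rising", hysteresis = "auto",
              min_separation = 0, bin_width = 0.05, min_period = 0.2,
              n_surrogates = 500, alpha_upo = 0.05, upo_tolerance = 0.1,
              window_len = 4000, pad = 1000, hop_spec = 4000,
              embed_d = 7, embed_lag = 1, embed_full_trace = FALSE,
              T_w = 25.2, hop_entropy = 0.5, alpha_entropy = 0.01,
              seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config entries: %s", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "framework_config")
}

# Pick the oscillating channel: configured one, or the vertical channel
# with the largest position SD.
pick_oscillating <- function(recording, cfg) {
  if (cfg$oscillating_channel != "auto") return(cfg$oscillating_channel)
  vert <- intersect(c("R_V", "L_V"), names(recording$traces))
  if (!length(vert)) vert <- names(recording$traces)
  sds <- vapply(vert, function(ch) stats::sd(recording$traces[[ch]]$samples),
                numeric(1))
  vert[which.max(sds)]
}

# Analyse a single recording; returns a list of per-stage results.
analyse_recording <- function(recording, cfg, seed) {
  osc_ch <- pick_oscillating(recording, cfg)
  raw <- preprocess_trace(get_channel(recording, osc_ch))
  clin <- clinical_summary(recording, osc_ch, detrend = TRUE,
                           detrend_window = cfg$detrend_window)
  det <- detrend_moving_average(raw, cfg$detrend_window)
  wl <- min(cfg$window_len, length(det$samples))
  spectra <- successive_spectra(det, window_len = wl,
                                hop = min(cfg$hop_spec, wl), pad = cfg$pad)
  fourier_f <- dominant_frequency(mean_spectrum(spectra))
  iv <- crossing_intervals(det, threshold = cfg$threshold,
                           direction = cfg$direction,
                           hysteresis = cfg$hysteresis,
                           min_separation = cfg$min_separation)
  upo <- surrogate_significance(iv, n_surrogates = cfg$n_surrogates,
                                seed = seed, bin_width = cfg$bin_width,
                                min_period = cfg$min_period,
                                alpha = cfg$alpha_upo)
  seg <- tryCatch(locate_upo_segment(det, iv, upo$period,
                                     tolerance = cfg$upo_tolerance),
                  error = function(e) NULL)
  emb_series <- if (cfg$embed_full_trace || is.null(seg)) det$samples else
    det$samples[seg$start_index:seg$end_index]
  projection <- tryCatch(
    project_principal(delay_embed(emb_series, d = cfg$embed_d,
                                  lag = cfg$embed_lag)),
    error = function(e) NULL)
  # classification needs several beat/return cycles to tell quasiperiodic
  # and nonperiodic structure apart, so it always sees the full trace
  attractor <- classify_attractor(det$samples, det$sampling$rate, upo = NULL)
  entropy <- sliding_entropy(raw, d = cfg$embed_d, T_w = cfg$T_w,
                             hop = cfg$hop_entropy,
                             detrend_window = cfg$detrend_window)
  entropy$subject_id <- recording$subject_id
  list(subject_id = recording$subject_id, oscillating_channel = osc_ch,
       clinical = clin, spectra = spectra, fourier_frequency = fourier_f,
       intervals = iv, upo = upo, upo_segment = seg,
       projection = projection, attractor = attractor, entropy = entropy)
}

#' Run the full analysis framework over a cohort
#'
#' Executes, per recording: preprocessing, the standard clinical assessment,
#' segmented Fourier spectra with dominant-frequency extraction,
#' threshold-crossing UPO analysis with surrogate significance, location of
#' the orbit-following segment, delay embedding with principal-component
#' projection, attractor classification, and sliding-window permutation
#' entropy; then compares the entropy distributions across recordings and
#' ranks them by increasing median `h_p`. A failure in one subject is
#' recorded in its row without aborting the cohort. Deterministic for a
#' fixed `config$seed`.
#'
#' @param recordings A list of [eye_recording()]s, or a `synthetic_cohort`.
#' @param config A [framework_config()].
#' @return An object of class `framework_report`: `subjects` (per-subject
#'   stage results), `table` (one summary row per subject: amplitude,
#'   frequency, intensity, Fourier and UPO frequencies, orbit p-value,
#'   attractor class, median and MAD of `h_p`), `comparison` (an
#'   `entropy_comparison`, `NULL` for a single recording), `config`.
#' @export
run_framework <- function(recordings, config = framework_config()) {
  if (inherits(recordings, "synthetic_cohort")) recordings <- recordings$members
  if (!length(recordings)) stop("no recordings given")
  stopifnot(all(vapply(recordings, inherits, logical(1), "eye_recording")))
  results <- vector("list", length(recordings))
  rows <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    seed_i <- (config$seed * 1009L + i * 97L) %% .Machine$integer.max
    res <- tryCatch(analyse_recording(rec, config, seed_i),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(subject = rec$subject_id, channel = NA,
                              mean_amplitude = NA, mean_frequency = NA,
                              intensity = NA, fourier_hz = NA, upo_hz = NA,
                              upo_p = NA, attractor = NA, median_h_p = NA,
                              mad_h_p = NA,
                              note = conditionMessage(res))
      results[[i]] <- list(subject_id = rec$subject_id,
                           error = conditionMessage(res))
    } else {
      rows[[i]] <- data.frame(
        subject = res$subject_id, channel = res$oscillating_channel,
        mean_amplitude = res$clinical$mean_amplitude,
        mean_frequency = res$clinical$mean_frequency,
        intensity = res$clinical$intensity,
        fourier_hz = res$fourier_frequency,
        upo_hz = res$upo$frequency, upo_p = res$upo$p_value,
        attractor = res$attractor$label,
        median_h_p = stats::median(res$entropy$h_p_values),
        mad_h_p = stats::mad(res$entropy$h_p_values, constant = 1),
        note = "")
      results[[i]] <- res
    }
  }
  names(results) <- vapply(recordings, function(r) r$subject_id, character(1))
  ok <- !vapply(results, function(r) !is.null(r$error), logical(1))
  comparison <- NULL
  if (sum(ok) >= 2) {
    comparison <- compare_entropies(lapply(results[ok], `[[`, "entropy"),
                                    alpha = config$alpha_entropy)
  } else message("fewer than 2 analysable recordings: comparison skipped")
  structure(list(subjects = results, table = do.call(rbind, rows),
                 comparison = comparison, config = config),
            class = "framework_report")
}

#' @export
print.framework_report <- function(x, ...) {
  cat("<framework_report>\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(col) round(col, 4))
  print(tab, row.names = FALSE)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Write a framework report to CSV files
#'
#' Emits `summary.csv` (the per-subject table), `entropy_windows.csv`
#' (per-window `h_p` values), `upo_histograms.csv` (observed and surrogate
#' envelope per bin), `spectra.csv` (per-segment relative amplitudes) and,
#' when present, `comparison_pairs.csv` and `ranking.csv`. No timestamps
#' are written, so identical runs produce identical files.
#'
#' @param report A `framework_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_framework_report <- function(report, dir) {
  stopifnot(inherits(report, "framework_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$table, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  ew <- do.call(rbind, lapply(report$subjects, function(r) {
    if (!is.null(r$error)) return(NULL)
    data.frame(subject = r$subject_id,
               window_start_s = r$entropy$window_starts,
               h_p = r$entropy$h_p_values)
  }))
  if (!is.null(ew))
    utils::write.csv(ew, file.path(dir, "entropy_windows.csv"),
                     row.names = FALSE)
  uh <- do.call(rbind, lapply(report$subjects, function(r) {
    if (!is.null(r$error)) return(NULL)
    h <- r$upo$histogram
    data.frame(subject = r$subject_id, period_s = h$mids,
               relative_frequency = h$relative_frequency,
               surrogate_mean = h$surrogate_mean,
               surrogate_upper = h$surrogate_upper)
  }))
  if (!is.null(uh))
    utils::write.csv(uh, file.path(dir, "upo_histograms.csv"),
                     row.names = FALSE)
  sp <- do.call(rbind, lapply(report$subjects, function(r) {
    if (!is.null(r$error)) return(NULL)
    do.call(rbind, lapply(seq_along(r$spectra), function(k) {
      s <- r$spectra[[k]]
      data.frame(subject = r$subject_id, segment = k,
                 frequency_hz = s$frequencies,
                 relative_amplitude = s$relative_amplitudes)
    }))
  }))
  if (!is.null(sp))
    utils::write.csv(sp, file.path(dir, "spectra.csv"), row.names = FALSE)
  if (!is.null(report$comparison)) {
    utils::write.csv(report$comparison$pairs,
                     file.path(dir, "comparison_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(rank = seq_along(report$comparison$ranking),
                                subject = report$comparison$ranking),
                     file.path(dir, "ranking.csv"), row.names = FALSE)
  }
  invisible(dir)
}
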