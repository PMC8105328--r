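# Standard column names for the delimited-text recording format.
.STD_COLS <- c(R_H = "r_h_deg", R_V = "r_v_deg", L_H = "l_h_deg",
               L_V = "l_v_deg")

#' Load an eye movement recording from delimited text
#'
#' Reads a CSV/TSV file with a header row holding a time column (seconds)
#' and up to four position columns in degrees. The sampling rate is taken
#' from `mapping$rate` when given, otherwise inferred from the time column
#' as the reciprocal of the median sample spacing; inference fails when the
#' spacing varies by more than 1%.
#'
#' @param path Path to the delimited text file. The separator is `\t` for
#'   `.tsv` files and `,` otherwise.
#' @param mapping A list describing the columns:
#'   \describe{
#'     \item{time}{name of the time column (seconds); may be `NULL` when
#'       `rate` is supplied.}
#'     \item{rate}{sampling rate override in Hz (optional).}
#'     \item{channels}{named character vector mapping channel labels
#'       (`R_H`, `R_V`, `L_H`, `L_V`) to column names. Defaults to the
#'       standard names `r_h_deg`, `r_v_deg`, `l_h_deg`, `l_v_deg`,
#'       restricted to the columns actually present.}
#'     \item{subject_id}{subject label (optional, default the file name).}
#'   }
#' @return An [eye_recording()].
#' @seealso [write_recording()]
#' @export
load_recording <- function(path, mapping = list()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  chans <- mapping$channels
  if (is.null(chans)) chans <- .STD_COLS[.STD_COLS %in% names(df)]
  if (!length(chans)) stop("no position columns found or mapped")
  if (!all(chans %in% names(df)))
    stop(sprintf("mapped columns absent from file: %s",
                 paste(setdiff(chans, names(df)), collapse = ", ")))
  rate <- mapping$rate
  if (is.null(rate)) {
    tcol <- if (!is.null(mapping$time)) mapping$time else
      intersect(c("time_s", "time"), names(df))[1]
    if (is.na(tcol) || is.null(tcol) || !tcol %in% names(df))
      stop("no sampling rate given and no time column to infer it from")
    rate <- infer_rate(df[[tcol]])
  }
  subject <- if (!is.null(mapping$subject_id)) mapping$subject_id else
    sub("\\.[^.]*$", "", basename(path))
  traces <- lapply(names(chans), function(ch)
    eye_trace(df[[chans[[ch]]]], rate = rate, channel = ch))
  eye_recording(traces, subject_id = subject)
}

# Infer the sampling rate (Hz) from a time column in seconds.
infer_rate <- function(time_s, tol = 0.01) {
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time column is not strictly increasing")
  med <- stats::median(dt)
  if (any(abs(dt - med) / med > tol))
    stop("time column spacing varies by more than 1%; give `rate` explicitly")
  rate <- 1 / med
  # snap float noise from text round-tripping onto integer rates
  if (abs(rate - round(rate)) < 1e-6) rate <- round(rate)
  rate
}

#' Write a recording as delimited text
#'
#' Writes the standard column layout (`time_s` plus the per-channel degree
#' columns present in the recording) with enough precision that a
#' write-then-load round trip preserves samples to within 1e-9 degrees.
#'
#' @param recording An [eye_recording()].
#' @param path Output path; `.tsv` selects tab separation, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eye_recording"))
  rate <- recording$traces[[1]]$sampling$rate
  n <- length(recording$traces[[1]]$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / rate)
  for (ch in names(recording$traces))
    df[[.STD_COLS[[ch]]]] <- recording$traces[[ch]]$samples
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # %.12g keeps 12 significant digits: ample for degree-scale positions
  fmt <- vapply(df, function(col) sprintf("%.12g", col), character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, names(df)))
  lines <- c(paste(names(df), collapse = sep),
             apply(fmt, 1L, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Preprocess an eye-position trace
#'
#' Removes blink/dropout gaps (encoded as `NA`/`NaN`/`Inf`) and optionally
#' resamples to a new rate. Leading and trailing non-finite samples are
#' always trimmed; interior gaps are linearly interpolated under the
#' `"linear"` policy (the default) provided no gap exceeds `max_gap`
#' seconds, and are an error under the `"drop_edges"` policy.
#'
#' Resampling to a lower rate by an integer factor applies a moving-average
#' anti-alias filter of the decimation factor's width before taking every
#' k-th sample; resampling upward uses linear interpolation. Non-integer
#' rate ratios are not supported.
#'
#' @param trace An [eye_trace()].
#' @param gap_policy `"linear"` or `"drop_edges"`.
#' @param target_rate Desired output rate (Hz), or `NULL` to keep the rate.
#' @param max_gap Longest interior gap (seconds) that may be interpolated.
#' @return A finite-valued [eye_trace()] at the requested rate.
#' @export
preprocess_trace <- function(trace, gap_policy = c("linear", "drop_edges"),
                             target_rate = NULL, max_gap = 0.5) {
  stopifnot(inherits(trace, "eye_trace"))
  gap_policy <- match.arg(gap_policy)
  x <- trace$samples
  rate <- trace$sampling$rate
  ok <- is.finite(x)
  if (!any(ok)) stop("trace is entirely non-finite")
  # trim leading/trailing non-finite samples
  first <- which(ok)[1]; last <- max(which(ok))
  x <- x[first:last]; ok <- ok[first:last]
  if (any(!ok)) {
    if (gap_policy == "drop_edges")
      stop("interior non-finite samples present under drop_edges policy")
    runs <- rle(!ok)
    if (max(runs$lengths[runs$values]) > max_gap * rate)
      stop(sprintf("gap longer than max_gap = %g s", max_gap))
    idx <- seq_along(x)
    x[!ok] <- stats::approx(idx[ok], x[ok], xout = idx[!ok])$y
  }
  if (!is.null(target_rate) && target_rate != rate) {
    ratio <- rate / target_rate
    inv <- target_rate / rate
    if (abs(ratio - round(ratio)) < 1e-9 && round(ratio) >= 2) {
      k <- round(ratio)
      # anti-alias: centred moving average of width k, then decimate
      xf <- stats::filter(x, rep(1 / k, k), sides = 2)
      xf[is.na(xf)] <- x[is.na(xf)]
      x <- as.numeric(xf)[seq(1L, length(x), by = k)]
    } else if (abs(inv - round(inv)) < 1e-9 && round(inv) >= 2) {
      t_old <- (seq_along(x) - 1) / rate
      t_new <- seq(0, t_old[length(t_old)], by = 1 / target_rate)
      x <- stats::approx(t_old, x, xout = t_new)$y
    } else stop("target_rate must be an integer multiple or divisor of rate")
    rate <- target_rate
  }
  eye_trace(x, rate = rate, channel = trace$channel)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers when possible, otherwise kept as strings. Used to override
#' [framework_config()] defaults from disk.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
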