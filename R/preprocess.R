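#' Resample an irregular recording onto a uniform grid by cubic spline
#'
#' Batch mode interpolates with a natural cubic spline through all samples;
#' causal mode uses a local monotone cubic Hermite interpolant
#' (`stats::splinefun(method = "monoH.FC")`), whose value at `t` depends only
#' on the immediately neighbouring samples, so that streaming output is
#' unaffected by data far in the future. The grid is anchored at the first
#' timestamp and never extrapolates beyond the recorded span.
#'
#' @param record Tibble with columns `time_s`, `eda_uS` (>= 4 samples).
#' @param target_rate Output rate in Hz (> 0).
#' @param mode `"batch"` (natural spline) or `"causal"` (local Hermite).
#' @return Tibble with columns `time_s`, `eda` on a uniform grid.
#' @export
resample_cubic_spline <- function(record, target_rate = 4, mode = c("batch", "causal")) {
  mode <- match.arg(mode)
  stopifnot(target_rate > 0)
  t <- record$time_s
  y <- record$eda_uS %||% record$eda
  if (length(t) < 4L) stop("need at least 4 samples to spline-resample", call. = FALSE)
  grid <- seq(t[1], t[length(t)], by = 1 / target_rate)
  v <- if (mode == "batch") {
    spline(t, y, xout = grid, method = "natural")$y
  } else {
    splinefun(t, y, method = "monoH.FC")(grid)
  }
  tibble(time_s = grid, eda = v)
}

#' Running median filter with a 1-second window
#'
#' Centered running median over `window` samples (default 5 samples = 1.25 s
#' at 4 Hz: the narrowest odd, centered window that still spans at least one
#' second). Edges use a shrinking window. Causal mode uses a trailing window
#' of the same width instead, so output at `t` never looks ahead.
#'
#' @param series Tibble with columns `time_s`, `eda`, uniformly sampled.
#' @param window Odd window length in samples.
#' @param mode `"batch"` (centered) or `"causal"` (trailing).
#' @return Tibble of the same shape.
#' @export
median_filter_1s <- function(series, window = 5L, mode = c("batch", "causal")) {
  mode <- match.arg(mode)
  x <- series$eda
  n <- length(x)
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (n == 0L) return(series)
  out <- numeric(n)
  if (mode == "batch") {
    h <- window %/% 2L
    if (n > window) {
      out[(h + 1):(n - h)] <- stats::runmed(x, window, endrule = "keep")[(h + 1):(n - h)]
    } else {
      for (i in seq_len(n)) out[i] <- median(x[max(1, i - h):min(n, i + h)])
    }
    for (i in seq_len(min(h, n))) out[i] <- median(x[max(1, i - h):min(n, i + h)])
    for (i in seq.int(max(n - h + 1, 1), n)) out[i] <- median(x[max(1, i - h):min(n, i + h)])
  } else {
    for (i in seq_len(n)) out[i] <- median(x[max(1, i - window + 1L):i])
  }
  tibble(time_s = series$time_s, eda = out)
}

#' Downsample a uniform 4 Hz series to 2 Hz
#'
#' Plain decimation by two (every other sample is kept, starting from the
#' first); anti-alias smoothing is provided by the preceding median filter in
#' the standard chain.
#'
#' @param series Tibble with columns `time_s`, `eda` at 4 Hz.
#' @return Tibble at 2 Hz.
#' @export
downsample_to_2hz <- function(series) {
  keep <- seq(1, nrow(series), by = 2L)
  tibble(time_s = series$time_s[keep], eda = series$eda[keep])
}

# steady-state filter state for a unit step input (direct form II transposed),
# so filtering a constant gives no startup transient
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  compT <- rbind(-a[2:n], cbind(diag(1, n - 2, n - 2), numeric(n - 2)))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(compT), B)
}

# direct form II transposed IIR filter with initial state
iir_filter <- function(b, a, x, zi = numeric(max(length(a), length(b)) - 1)) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  y <- numeric(length(x))
  z <- zi
  for (i in seq_along(x)) {
    yi <- b[1] * x[i] + z[1]
    for (j in seq_len(n - 2)) z[j] <- b[j + 1] * x[i] - a[j + 1] * yi + z[j + 1]
    z[n - 1] <- b[n] * x[i] - a[n] * yi
    y[i] <- yi
  }
  y
}

# zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initial conditions (no startup transient on constants);
# the pad should span several filter time constants so edge transients die in it
filtfilt_zi <- function(b, a, x, pad = 3L * (max(length(a), length(b)) - 1L)) {
  n <- length(x)
  padlen <- min(pad, n - 1L)
  ext <- c(2 * x[1] - rev(x[2:(padlen + 1)]), x,
           2 * x[n] - rev(x[(n - padlen):(n - 1)]))
  zi <- lfilter_zi(b, a)
  yf <- iir_filter(b, a, ext, zi * ext[1])
  yb <- rev(iir_filter(b, a, rev(yf), zi * yf[length(yf)]))
  yb[(padlen + 1):(padlen + n)]
}

#' High-pass filter at 0.01 Hz
#'
#' Second-order Butterworth high-pass with 0.01 Hz cutoff. Batch mode applies
#' the filter forward-backward (zero phase, preserving SCR timing), with
#' odd-reflection padding and steady-state initial conditions so constants
#' are rejected without edge transients; causal mode applies a single forward
#' pass (also initialised at steady state) so the output at `t` depends only
#' on samples up to `t`.
#'
#' @param series Tibble with columns `time_s`, `eda`, uniformly sampled.
#' @param cutoff_hz Cutoff frequency in Hz (default 0.01).
#' @param mode `"batch"` (zero phase) or `"causal"` (single pass).
#' @return Tibble of the same shape; values are signed (DC removed).
#' @export
highpass_001 <- function(series, cutoff_hz = 0.01, mode = c("batch", "causal")) {
  mode <- match.arg(mode)
  rate <- series_rate(series$time_s)
  if (nrow(series) < 7L) stop("series too short for the high-pass filter", call. = FALSE)
  bf <- signal::butter(2, cutoff_hz / (rate / 2), type = "high")
  x <- series$eda
  y <- if (mode == "batch") {
    filtfilt_zi(bf$b, bf$a, x,
                pad = as.integer(ceiling(5 * rate / (2 * pi * cutoff_hz))))
  } else {
    iir_filter(bf$b, bf$a, x, lfilter_zi(bf$b, bf$a) * x[1])
  }
  tibble(time_s = series$time_s, eda = y)
}

#' Preprocess a raw EDA recording to the uniform 2 Hz analysis series
#'
#' The standard four-step chain: cubic-spline resampling to 4 Hz, 1-s running
#' median, decimation to 2 Hz, and a 0.01 Hz high-pass, in that order. Batch
#' mode is zero phase throughout; causal mode replaces each stage with its
#' causal counterpart and is what the streaming scheme uses.
#'
#' @param record Tibble with columns `time_s`, `eda_uS` spanning >= 60 s.
#' @param mode `"batch"` or `"causal"`.
#' @param intermediate_rate Rate of the first resampling stage, Hz (default 4).
#' @param cutoff_hz High-pass cutoff, Hz (default 0.01).
#' @return Tibble with columns `time_s`, `eda` at 2 Hz (signed, DC removed).
#' @export
#' @examples
#' rec <- generate_subject(sim_config(n_subjects = 1, seed = 1))$record
#' prep <- preprocess_eda(rec)
#' series_rate(prep$time_s)  # 2
preprocess_eda <- function(record, mode = c("batch", "causal"),
                           intermediate_rate = 4, cutoff_hz = 0.01) {
  mode <- match.arg(mode)
  validate_recording(if ("eda_uS" %in% names(record)) record
                     else dplyr::rename(record, eda_uS = "eda"))
  span <- diff(range(record$time_s))
  if (span < 60) stop("recording must span at least 60 s", call. = FALSE)
  record %>%
    resample_cubic_spline(target_rate = intermediate_rate, mode = mode) %>%
    median_filter_1s(mode = mode) %>%
    downsample_to_2hz() %>%
    highpass_001(cutoff_hz = cutoff_hz, mode = mode)
}
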