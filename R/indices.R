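#' Instantaneous amplitude and phase via the analytic signal
#'
#' Computes the discrete analytic signal `Z = x + i H(x)` (Hilbert transform
#' by the standard frequency-domain construction) and returns its modulus and
#' argument. The identity `amplitude^2 = x^2 + H(x)^2` holds exactly.
#'
#' @param x Real numeric vector, length >= 16.
#' @return A list with `amplitude` (>= 0), `phase` (radians) and
#'   `hilbert_pair` (the imaginary part, i.e. the Hilbert transform of `x`).
#' @export
hilbert_amplitude <- function(x) {
  n <- length(x)
  if (n < 16L) stop("need at least 16 samples for the analytic signal", call. = FALSE)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  list(amplitude = Mod(z), phase = Arg(z), hilbert_pair = Im(z))
}

#' Time-varying sympathetic index (TVSymp)
#'
#' Sums VFCDM components 2 and 3 (centers 0.12 and 0.20 Hz, jointly covering
#' roughly the 0.08-0.24 Hz band where sympathetically mediated EDA dynamics
#' concentrate), normalizes the sum to unit sample variance (the mean is not
#' removed: band-pass components are already zero-mean), and takes the
#' instantaneous amplitude of the result via the Hilbert transform.
#'
#' @param decomp A `vfcdm_decomp` from [vfcdm_decompose()].
#' @param components Indices of the components to sum (default `c(2, 3)`).
#' @return Tibble with columns `time_s`, `xprime` (normalized sum), `yprime`
#'   (Hilbert pair), `tvsymp` (instantaneous amplitude) and `phase`.
#' @export
tvsymp <- function(decomp, components = c(2L, 3L)) {
  stopifnot(inherits(decomp, "vfcdm_decomp"))
  if (nrow(decomp$components) < max(components)) {
    stop("decomposition has fewer components than requested", call. = FALSE)
  }
  s <- colSums(decomp$components[components, , drop = FALSE])
  sds <- sd(s)
  if (!is.finite(sds) || sds == 0) {
    stop("degenerate input: summed components have zero variance", call. = FALSE)
  }
  xp <- s / sds
  hb <- hilbert_amplitude(xp)
  tibble(time_s = decomp$time_s, xprime = xp, yprime = hb$hilbert_pair,
         tvsymp = hb$amplitude, phase = hb$phase)
}

#' Modified TVSymp (MTVSymp)
#'
#' Subtracts from each TVSymp sample the mean of the preceding `k` seconds
#' and floors the difference at zero, emphasising abrupt sympathetic surges
#' over sustained elevation. For the first `k` seconds the trailing mean is
#' taken over all available preceding samples; the first sample is 0.
#'
#' @param tv Tibble from [tvsymp()] (columns `time_s`, `tvsymp`) or a numeric
#'   vector of TVSymp values.
#' @param k Trailing-window length in seconds (default 5).
#' @param rate Sampling rate in Hz; inferred from `time_s` when `tv` is a
#'   tibble (default 2).
#' @return Tibble with columns `time_s` (if available) and `mtvsymp`.
#' @export
mtvsymp <- function(tv, k = 5, rate = 2) {
  if (is.data.frame(tv)) {
    a <- tv$tvsymp
    rate <- series_rate(tv$time_s)
    time_s <- tv$time_s
  } else {
    a <- as.numeric(tv)
    time_s <- (seq_along(a) - 1) / rate
  }
  w <- as.integer(round(k * rate))
  stopifnot(w >= 1L)
  if (length(a) <= w) stop("series must be longer than the trailing window", call. = FALSE)
  n <- length(a)
  cs <- cumsum(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L) { out[i] <- 0; next }
    lo <- max(1L, i - w)
    mu <- (cs[i - 1L] - if (lo > 1L) cs[lo - 1L] else 0) / (i - lo)
    out[i] <- if (mu <= a[i]) a[i] - mu else 0
  }
  tibble(time_s = time_s, mtvsymp = out)
}

#' Derivative of the phasic EDA component (dPhEDA)
#'
#' Five-point-stencil central finite difference of the phasic component,
#' `(x[n-2] - 8 x[n-1] + 8 x[n+1] - x[n+2]) / (12 / Fs)`, exact for
#' polynomials up to degree 4. The series is replicate-padded by two samples
#' at each end so the output has the input length.
#'
#' @param phasic Numeric vector (the phasic component, uS) or a tibble with
#'   columns `time_s` and `phasic`.
#' @param rate Sampling rate in Hz (default 2; inferred from `time_s` for
#'   tibble input).
#' @return Tibble with columns `time_s` and `dpheda` (uS/s).
#' @export
dpheda <- function(phasic, rate = 2) {
  if (is.data.frame(phasic)) {
    x <- phasic$phasic
    rate <- series_rate(phasic$time_s)
    time_s <- phasic$time_s
  } else {
    x <- as.numeric(phasic)
    time_s <- (seq_along(x) - 1) / rate
  }
  n <- length(x)
  if (n < 5L) stop("need at least 5 samples for the five-point stencil", call. = FALSE)
  xp <- c(x[1], x[1], x, x[n], x[n])
  i <- seq_len(n) + 2L
  d <- (xp[i - 2L] - 8 * xp[i - 1L] + 8 * xp[i + 1L] - xp[i + 2L]) / (12 * (1 / rate))
  tibble(time_s = time_s, dpheda = d)
}

#' Compute all three EDA indices from a preprocessed series
#'
#' Batch-mode convenience wrapper: VFCDM + TVSymp, MTVSymp, and the convex
#' decomposition + dPhEDA, aligned on the common 2 Hz grid.
#'
#' @param prep Tibble with columns `time_s`, `eda` at 2 Hz (from
#'   [preprocess_eda()]).
#' @param k MTVSymp trailing window, seconds (default 5).
#' @param ... Passed to [cvxeda_decompose()].
#' @return Tibble with columns `time_s`, `tvsymp`, `mtvsymp`, `dpheda`.
#' @export
#' @examples
#' rec <- generate_subject(sim_config(n_subjects = 1, seed = 2))$record
#' idx <- eda_indices(preprocess_eda(rec))
eda_indices <- function(prep, k = 5, ...) {
  dec <- vfcdm_decompose(prep)
  tv <- tvsymp(dec)
  mtv <- mtvsymp(tv, k = k)
  cd <- cvxeda_decompose(prep, ...)
  dp <- dpheda(tibble(time_s = cd$time_s, phasic = cd$phasic))
  tibble(time_s = prep$time_s, tvsymp = tv$tvsymp,
         mtvsymp = mtv$mtvsymp, dpheda = dp$dpheda)
}
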