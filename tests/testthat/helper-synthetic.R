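# Shared fixtures, built in code.

# uniform 2 Hz series tibble from a function of time
series_2hz <- function(f, duration = 300, rate = 2) {
  t <- seq(0, duration, by = 1 / rate)
  tibble::tibble(time_s = t, eda = f(t))
}

# a band-limited (< 0.9 Hz) multi-tone test signal
multitone <- function(t) {
  0.5 * sin(2 * pi * 0.05 * t) + 0.3 * sin(2 * pi * 0.13 * t + 1) +
    0.2 * sin(2 * pi * 0.31 * t) + 0.15 * sin(2 * pi * 0.55 * t + 2) +
    0.1 * sin(2 * pi * 0.82 * t)
}

# zero-mean EDA-like SCR train (band-limited, broadband at low frequency)
scr_train <- function(t, n_scr = 12, seed = 7) {
  set.seed(seed)
  y <- numeric(length(t))
  for (on in sort(runif(n_scr, 5, max(t) - 10))) {
    y <- y + runif(1, 0.2, 1) * scr_kernel(t - on)
  }
  y - mean(y)
}

# segment feature table for a synthetic dataset (full batch pipeline)
dataset_segments <- function(config, dataset = "synthetic") {
  ds <- generate_dataset(config)
  purrr::map_dfr(unique(ds$records$subject_id), function(sid) {
    rec <- dplyr::filter(ds$records, subject_id == sid)
    ev <- dplyr::filter(ds$events, subject_id == sid)
    idx <- eda_indices(preprocess_eda(rec))
    extract_segments(idx, ev, dataset = dataset)
  })
}

# literal brute-force evaluation of the MTVSymp definition (independent oracle)
mtvsymp_brute <- function(a, k = 5, rate = 2) {
  w <- as.integer(round(k * rate))
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    if (i == 1) { out[i] <- 0; next }
    prev <- a[max(1, i - w):(i - 1)]
    mu <- mean(prev)
    out[i] <- if (mu <= a[i]) a[i] - mu else 0
  }
  out
}

# brute-force AUROC by explicit pair counting (independent oracle)
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
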