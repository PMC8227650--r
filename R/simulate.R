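#' Configuration for the synthetic EDA generator
#'
#' Builds a validated configuration for [generate_subject()] /
#' [generate_dataset()]. The generator emulates the structure of a
#' stimulus-locked pain experiment: a slowly drifting tonic level, one evoked
#' skin-conductance response (SCR) per stimulus with a short latency,
#' spontaneous (non-specific) SCRs, white measurement noise, and irregular
#' raw-rate timestamps.
#'
#' @param n_subjects Number of subjects.
#' @param n_stimuli_per_subject Pain stimuli per subject (default 10).
#' @param isi_range Inter-stimulus interval range in seconds; each interval is
#'   drawn uniformly from this range (default 30-60 s).
#' @param raw_rate Nominal raw sampling rate in Hz (default 120).
#' @param jitter_frac Uniform timestamp jitter as a fraction of the nominal
#'   sampling interval (default 0.2, i.e. +/-20%).
#' @param tonic_level Baseline skin conductance in microsiemens (default 2).
#' @param tonic_drift_sd Gaussian random-walk drift scale, in uS per sqrt
#'   second (default 0.01).
#' @param scr_amplitude_pain Mean evoked SCR amplitude in uS (the effect size;
#'   default 0.5).
#' @param scr_amplitude_sd SD of evoked SCR amplitudes in uS (default 0.1);
#'   draws are floored at 0.
#' @param scr_latency Evoked-response latency after the stimulus, seconds
#'   (default 1.5).
#' @param tau0,tau1 Bateman kernel time constants in seconds, `tau0 > tau1`
#'   (defaults 2.0 and 0.7).
#' @param spontaneous_scr_rate Spontaneous SCR rate, events per minute
#'   (default 2).
#' @param spontaneous_scr_amplitude Mean spontaneous SCR amplitude in uS
#'   (default 0.15; spontaneous responses are physiologically smaller than
#'   strong evoked pain responses).
#' @param noise_sd White measurement-noise SD in uS (default 0.02).
#' @param pre_roll,post_roll Quiet lead-in/lead-out before the first and after
#'   the last stimulus, seconds (defaults 60 and 30).
#' @param seed Master integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10,
                       n_stimuli_per_subject = 10,
                       isi_range = c(30, 60),
                       raw_rate = 120,
                       jitter_frac = 0.2,
                       tonic_level = 2,
                       tonic_drift_sd = 0.01,
                       scr_amplitude_pain = 0.5,
                       scr_amplitude_sd = 0.1,
                       scr_latency = 1.5,
                       tau0 = 2.0,
                       tau1 = 0.7,
                       spontaneous_scr_rate = 2,
                       spontaneous_scr_amplitude = 0.15,
                       noise_sd = 0.02,
                       pre_roll = 60,
                       post_roll = 30,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 0, n_stimuli_per_subject >= 0,
            length(isi_range) == 2, isi_range[1] > 0, isi_range[2] >= isi_range[1],
            raw_rate > 0, jitter_frac >= 0, jitter_frac < 0.5,
            tonic_level >= 0, tonic_drift_sd >= 0,
            scr_amplitude_pain >= 0, scr_amplitude_sd >= 0, scr_latency >= 0,
            spontaneous_scr_rate >= 0, spontaneous_scr_amplitude >= 0,
            noise_sd >= 0, pre_roll >= 0, post_roll >= 0)
  if (!(tau0 > tau1 && tau1 > 0)) {
    stop("Bateman time constants require tau0 > tau1 > 0", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Bateman skin-conductance response kernel
#'
#' The bi-exponential impulse response `exp(-t/tau0) - exp(-t/tau1)` used to
#' model a single SCR: a fast rise governed by `tau1` and a slow recovery
#' governed by `tau0`. Zero for `t < 0`.
#'
#' @param t Time since driver impulse, seconds (vectorised).
#' @param tau0 Recovery time constant, seconds.
#' @param tau1 Rise time constant, seconds; must satisfy `tau0 > tau1 > 0`.
#' @param normalize If `TRUE`, scale so the kernel peak equals 1 (an SCR
#'   amplitude then has conductance units).
#' @return Numeric vector, unitless (or peak-normalised) response.
#' @export
#' @examples
#' scr_kernel(1, tau0 = 2, tau1 = 0.7)  # exp(-0.5) - exp(-1/0.7)
scr_kernel <- function(t, tau0 = 2.0, tau1 = 0.7, normalize = FALSE) {
  if (!(tau0 > tau1 && tau1 > 0)) {
    stop("Bateman time constants require tau0 > tau1 > 0", call. = FALSE)
  }
  out <- ifelse(t < 0, 0, exp(-t / tau0) - exp(-t / tau1))
  if (normalize) {
    tpk <- log(tau0 / tau1) * tau0 * tau1 / (tau0 - tau1)
    out <- out / (exp(-tpk / tau0) - exp(-tpk / tau1))
  }
  out
}

# Derive a reproducible 32-bit sub-seed from a master seed and an index.
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 1009L + 7919L * as.integer(index) %% 2147483L
}

#' Simulate one subject's EDA recording with ground truth
#'
#' Conductance is the sum of a clipped Gaussian random-walk tonic drift, one
#' evoked SCR per stimulus (onset at stimulus time + latency, amplitude drawn
#' from a floored normal), Poisson spontaneous SCRs, and white noise.
#' Timestamps run at the nominal raw rate with uniform jitter. All values are
#' clipped at 0. Fully deterministic given `(config, subject_index)`.
#'
#' @param config A [sim_config()].
#' @param subject_index 1-based subject number (also seeds the subject).
#' @return A list with `record` (tibble: subject_id, time_s, eda_uS),
#'   `events` (tibble: subject_id, time_s) and `truth` (tibble: time_s, tonic,
#'   phasic, noise) such that `tonic + phasic + noise` clipped at 0 equals
#'   `eda_uS` exactly.
#' @export
generate_subject <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  sid <- sprintf("sim%02d", subject_index)
  rs <- derive_seed(config$seed, subject_index)
  withr_seed <- .Random.seed_exists()
  set.seed(rs)

  # stimulus schedule
  n_stim <- config$n_stimuli_per_subject
  isi <- runif(max(n_stim - 1, 0), config$isi_range[1], config$isi_range[2])
  ev <- if (n_stim > 0) config$pre_roll + cumsum(c(0, isi)) else numeric()
  duration <- (if (n_stim > 0) max(ev) else config$pre_roll) + config$post_roll

  # jittered raw timestamps
  dt <- 1 / config$raw_rate
  tt <- seq(0, duration, by = dt)
  if (length(tt) > 2) {
    jit <- runif(length(tt) - 2, -config$jitter_frac * dt, config$jitter_frac * dt)
    tt[2:(length(tt) - 1)] <- tt[2:(length(tt) - 1)] + jit
  }
  tt <- sort(tt)
  n <- length(tt)

  # tonic: Gaussian random walk, variance proportional to elapsed time
  tonic <- config$tonic_level +
    c(0, cumsum(rnorm(n - 1, 0, config$tonic_drift_sd * sqrt(pmax(diff(tt), 0)))))
  tonic <- pmax(tonic, 0.05)

  # phasic: evoked + spontaneous SCRs
  phasic <- numeric(n)
  add_scr <- function(onset, amp) {
    if (amp <= 0) return()
    idx <- which(tt >= onset)
    phasic[idx] <<- phasic[idx] +
      amp * scr_kernel(tt[idx] - onset, config$tau0, config$tau1, normalize = TRUE)
  }
  if (n_stim > 0) {
    amps <- pmax(rnorm(n_stim, config$scr_amplitude_pain, config$scr_amplitude_sd), 0)
    for (k in seq_len(n_stim)) add_scr(ev[k] + config$scr_latency, amps[k])
  }
  n_spont <- rpois(1, config$spontaneous_scr_rate * duration / 60)
  if (n_spont > 0) {
    s_on <- sort(runif(n_spont, 0, duration))
    s_amp <- pmax(rnorm(n_spont, config$spontaneous_scr_amplitude,
                        config$spontaneous_scr_amplitude / 3), 0)
    for (k in seq_len(n_spont)) add_scr(s_on[k], s_amp[k])
  }

  noise <- rnorm(n, 0, config$noise_sd)
  eda <- pmax(tonic + phasic + noise, 0)
  # keep the additivity identity exact after clipping
  noise <- eda - tonic - phasic

  if (withr_seed$had) assign(".Random.seed", withr_seed$seed, envir = globalenv())

  list(
    record = tibble(subject_id = sid, time_s = tt, eda_uS = eda),
    events = tibble(subject_id = sid, time_s = ev),
    truth = tibble(time_s = tt, tonic = tonic, phasic = phasic, noise = noise)
  )
}

.Random.seed_exists <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  list(had = had, seed = if (had) get(".Random.seed", envir = globalenv()))
}

#' Simulate a multi-subject synthetic EDA dataset
#'
#' Subjects are mutually independent; each subject's stream is seeded
#' deterministically from the master seed, so individual subjects can be
#' regenerated without the rest.
#'
#' @param config A [sim_config()].
#' @return A list of class `eda_dataset` with elements `records` (one tibble,
#'   all subjects), `events`, `truths` (named list per subject) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subs <- purrr::map(seq_len(config$n_subjects), ~generate_subject(config, .x))
  structure(
    list(
      records = purrr::map_dfr(subs, "record"),
      events = if (length(subs)) purrr::map_dfr(subs, "events")
               else tibble(subject_id = character(), time_s = numeric()),
      truths = setNames(purrr::map(subs, "truth"),
                        purrr::map_chr(subs, ~.x$record$subject_id[1])),
      config = config
    ),
    class = "eda_dataset"
  )
}

#' @export
print.eda_dataset <- function(x, ...) {
  cat("Synthetic EDA dataset:", x$config$n_subjects, "subjects,",
      x$config$n_stimuli_per_subject, "stimuli/subject,",
      "raw rate", x$config$raw_rate, "Hz\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory of CSV files
#'
#' One recording CSV per subject plus a single `events.csv`, in the package's
#' standard formats, with a JSON sidecar logging the configuration and seed.
#'
#' @param dataset An `eda_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "eda_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (sid in unique(dataset$records$subject_id)) {
    p <- file.path(dir, paste0(sid, ".csv"))
    write_eda_recording(dplyr::filter(dataset$records, .data$subject_id == sid), p)
    paths <- c(paths, p)
  }
  pev <- file.path(dir, "events.csv")
  write_stimulus_events(dataset$events, pev)
  cfg <- unclass(dataset$config)
  write_run_sidecar(pev, cfg, seed = cfg$seed)
  invisible(c(paths, pev))
}
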