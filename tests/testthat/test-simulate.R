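test_that("scr_kernel matches its closed form and boundary behaviour", {
  expect_equal(scr_kernel(0), 0)
  expect_equal(scr_kernel(-3), 0)
  expect_equal(scr_kernel(1, tau0 = 2, tau1 = 0.7),
               exp(-0.5) - exp(-1 / 0.7))
  expect_lt(scr_kernel(60), 1e-10)
  expect_error(scr_kernel(1, tau0 = 0.5, tau1 = 0.7), "tau0 > tau1")
  # peak-normalised kernel has maximum 1 at the analytic peak time
  tpk <- log(2 / 0.7) * 2 * 0.7 / (2 - 0.7)
  expect_equal(scr_kernel(tpk, normalize = TRUE), 1)
  expect_true(all(scr_kernel(seq(0, 30, 0.1), normalize = TRUE) <= 1 + 1e-12))
})

test_that("degenerate config yields a constant trace at tonic level", {
  cfg <- sim_config(n_subjects = 1, scr_amplitude_pain = 0, scr_amplitude_sd = 0,
                    spontaneous_scr_rate = 0, noise_sd = 0, tonic_drift_sd = 0,
                    raw_rate = 20, seed = 1)
  sub <- generate_subject(cfg, 1)
  expect_equal(unique(sub$record$eda_uS), cfg$tonic_level)
})

test_that("subject generation is seeded-deterministic and stimulus counts hold", {
  cfg <- sim_config(n_subjects = 2, raw_rate = 30, seed = 5)
  a <- generate_subject(cfg, 1)
  b <- generate_subject(cfg, 1)
  expect_identical(a, b)
  expect_equal(nrow(a$events), 10L)
  # different subjects differ
  c2 <- generate_subject(cfg, 2)
  expect_false(isTRUE(all.equal(a$record$eda_uS, c2$record$eda_uS)))
})

test_that("ground-truth decomposition identity holds exactly", {
  sub <- generate_subject(sim_config(n_subjects = 1, raw_rate = 30, seed = 9), 1)
  expect_equal(sub$truth$tonic + sub$truth$phasic + sub$truth$noise,
               sub$record$eda_uS, tolerance = 1e-12)
  expect_true(all(sub$record$eda_uS >= 0))
  expect_true(all(diff(sub$record$time_s) > 0))
})

test_that("dataset generation respects n_subjects including zero", {
  cfg <- sim_config(n_subjects = 3, n_stimuli_per_subject = 2, raw_rate = 20,
                    seed = 2)
  ds <- generate_dataset(cfg)
  expect_equal(length(unique(ds$records$subject_id)), 3L)
  expect_equal(nrow(ds$events), 6L)
  ds0 <- generate_dataset(sim_config(n_subjects = 0, seed = 1))
  expect_equal(nrow(ds0$records), 0L)
})

test_that("config validation rejects inverted time constants", {
  expect_error(sim_config(tau0 = 0.5, tau1 = 0.7), "tau0 > tau1")
  expect_error(sim_config(n_subjects = -1))
})

test_that("with zero effect and no spontaneous SCRs the features are
           indistinguishable between pain and painless segments", {
  cfg <- sim_config(n_subjects = 6, scr_amplitude_pain = 0, scr_amplitude_sd = 0,
                    spontaneous_scr_rate = 0, raw_rate = 60, seed = 41)
  seg <- dataset_segments(cfg)
  expect_gte(nrow(seg), 100)
  for (f in edapain:::feature_names()) {
    a <- auroc(seg[[f]], seg$label, ci = FALSE)$auroc
    expect_gte(a, 0.4)
    expect_lte(a, 0.6)
  }
})

test_that("a strong evoked effect drives streamed MTVSymp max above chance", {
  cfg <- sim_config(n_subjects = 2, seed = 21)   # amplitude 25x noise sd
  ds <- generate_dataset(cfg)
  scfg <- stream_config(hop_s = 1)
  seg <- purrr::map_dfr(unique(ds$records$subject_id), function(sid) {
    st <- run_stream_simulation(dplyr::filter(ds$records, subject_id == sid),
                                scfg)
    suppressWarnings(extract_segments(
      st, dplyr::filter(ds$events, subject_id == sid)))
  })
  expect_gte(auroc(seg$mtvsymp_max, seg$label, ci = FALSE)$auroc, 0.9)
})
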