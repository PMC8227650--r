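test_that("fixed demodulation recovers tone amplitude and rejects stopband", {
  ser <- series_2hz(function(t) cos(2 * pi * 0.12 * t))
  env <- fixed_demodulate(ser, f0 = 0.12)
  interior <- ser$time_s > 10 & ser$time_s < 290
  expect_lt(max(abs(env$amplitude[interior] - 1)), 0.02)

  far <- series_2hz(function(t) cos(2 * pi * (0.12 + 3 * 0.08) * t))
  envf <- fixed_demodulate(far, f0 = 0.12)
  expect_lt(max(envf$amplitude[interior]), 0.05)

  zero <- series_2hz(function(t) numeric(length(t)))
  expect_equal(fixed_demodulate(zero, 0.12)$amplitude,
               numeric(nrow(zero)))
  expect_error(fixed_demodulate(ser, f0 = 1.2), "rate/2")
})

test_that("instantaneous frequency tracks tones and detunings", {
  ser <- series_2hz(function(t) cos(2 * pi * 0.12 * t))
  f <- instantaneous_frequency(fixed_demodulate(ser, 0.12))
  interior <- ser$time_s > 10 & ser$time_s < 290
  expect_lt(max(abs(f[interior] - 0.12)), 1e-3)

  det <- series_2hz(function(t) cos(2 * pi * 0.15 * t))
  fd <- instantaneous_frequency(fixed_demodulate(det, 0.12))
  expect_lt(max(abs(fd[interior] - 0.15)), 2e-3)

  zero <- series_2hz(function(t) numeric(length(t)))
  fz <- instantaneous_frequency(fixed_demodulate(zero, 0.12))
  expect_equal(fz, rep(0.12, nrow(zero)))
})

test_that("variable demodulation at a constant track equals fixed demodulation", {
  # duration chosen so the demodulating carriers are periodic on the record
  ser <- series_2hz(function(t) cos(2 * pi * 0.12 * t), duration = 300 - 0.5)
  comp_var <- variable_demodulate(ser, rep(0.12, nrow(ser)))
  env <- fixed_demodulate(ser, 0.12)
  comp_fix <- 2 * Re(env$zlp * exp(2i * pi * 0.12 * (ser$time_s - ser$time_s[1])))
  expect_equal(comp_var, comp_fix, tolerance = 1e-9)

  zero <- series_2hz(function(t) numeric(length(t)))
  expect_equal(variable_demodulate(zero, rep(0.12, nrow(zero))),
               numeric(nrow(zero)))
  expect_error(variable_demodulate(ser, rep(0.12, 5)), "length")
})

test_that("a chirp inside one band is reconstructed by that band", {
  t <- seq(0, 300, by = 0.5)
  fi <- 0.10 + 0.04 * t / 300
  phase <- 2 * pi * cumsum(c(0, (fi[-1] + fi[-length(fi)]) / 2 * diff(t)))
  ser <- tibble::tibble(time_s = t, eda = sin(phase))
  d <- vfcdm_decompose(ser)
  interior <- t > 10 & t < 290
  expect_gt(cor(d$components[2, interior], ser$eda[interior]), 0.95)
})

test_that("band assignment: a 0.12 Hz tone lands in component 2", {
  ser <- series_2hz(function(t) sin(2 * pi * 0.12 * t))
  d <- vfcdm_decompose(ser)
  interior <- ser$time_s > 10 & ser$time_s < 290
  v <- apply(d$components[, interior], 1, var)
  expect_gte(v[2] / sum(v), 0.9)
  expect_equal(nrow(d$components), 12L)
  expect_equal(d$center_frequencies, seq(0.04, 0.92, by = 0.08))
})

test_that("sum of components reconstructs band-limited signals", {
  ser <- series_2hz(multitone)
  d <- vfcdm_decompose(ser)
  interior <- ser$time_s > 10 & ser$time_s < 290
  recon <- colSums(d$components)
  rel <- sqrt(mean((recon[interior] - ser$eda[interior])^2)) /
    sqrt(mean(ser$eda[interior]^2))
  expect_lt(rel, 0.05)

  zero <- series_2hz(function(t) numeric(length(t)))
  expect_equal(max(abs(vfcdm_decompose(zero)$components)), 0)
  expect_error(vfcdm_decompose(ser[1:40, ]), "50 samples")
})

test_that("decomposition is linear and bands are spectrally concentrated", {
  t <- seq(0, 300, by = 0.5)
  ser <- tibble::tibble(time_s = t, eda = scr_train(t))
  d1 <- vfcdm_decompose(ser)
  d2 <- vfcdm_decompose(dplyr::mutate(ser, eda = 2.5 * eda))
  expect_equal(d2$components, 2.5 * d1$components, tolerance = 1e-9)

  rate <- 2
  conc <- function(comp, fc) {
    n <- length(comp)
    sp <- Mod(fft(comp))^2
    fr <- (seq_len(n) - 1) / n * rate
    fr <- ifelse(fr > rate / 2, fr - rate, fr)
    sum(sp[abs(abs(fr) - fc) <= 0.06]) / sum(sp)
  }
  for (k in 1:6) {
    if (var(d1$components[k, ]) < 1e-12) next
    expect_gte(conc(d1$components[k, ], d1$center_frequencies[k]), 0.8)
  }
})

test_that("tidy() returns the long component table", {
  ser <- series_2hz(multitone, duration = 60)
  d <- vfcdm_decompose(ser)
  td <- tidy(d)
  expect_equal(nrow(td), 12 * nrow(ser))
  expect_named(td, c("time_s", "band", "center_hz", "value"))
})
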