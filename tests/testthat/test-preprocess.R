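test_that("spline resampling reproduces knots, constants and slow sinusoids", {
  # uniform 4 Hz input resampled at 4 Hz returns the original values
  t4 <- seq(0, 30, by = 0.25)
  rec <- tibble::tibble(time_s = t4, eda_uS = sin(t4))
  out <- resample_cubic_spline(rec, 4)
  expect_equal(out$eda, sin(t4), tolerance = 1e-9)

  const <- tibble::tibble(time_s = t4, eda_uS = rep(2, length(t4)))
  expect_equal(unique(resample_cubic_spline(const, 4)$eda), 2)

  # irregular ~120 Hz sampling of a slow sinusoid: analytic oracle
  set.seed(1)
  ti <- sort(runif(120 * 60, 0, 60))
  reci <- tibble::tibble(time_s = ti, eda_uS = sin(2 * pi * 0.05 * ti))
  o <- resample_cubic_spline(reci, 4)
  expect_lt(max(abs(o$eda - sin(2 * pi * 0.05 * o$time_s))), 1e-6)

  expect_error(resample_cubic_spline(rec[1:3, ], 4), "at least 4")
})

test_that("median filter removes spikes, keeps constants and interior ramps", {
  t4 <- seq(0, 10, by = 0.25)
  const <- tibble::tibble(time_s = t4, eda = rep(1.5, length(t4)))
  expect_equal(median_filter_1s(const)$eda, const$eda)

  spike <- const
  spike$eda[20] <- spike$eda[20] + 10
  expect_equal(median_filter_1s(spike)$eda, const$eda)

  ramp <- tibble::tibble(time_s = t4, eda = t4)
  mf <- median_filter_1s(ramp)$eda
  expect_equal(mf[3:(length(t4) - 2)], ramp$eda[3:(length(t4) - 2)])
})

test_that("decimation to 2 Hz keeps every other sample", {
  t4 <- seq(0, 1.75, by = 0.25)
  s <- tibble::tibble(time_s = t4, eda = seq_along(t4))
  d <- downsample_to_2hz(s)
  expect_equal(nrow(d), 4L)
  expect_equal(d$eda, c(1, 3, 5, 7))
  # slow sinusoid matches analytic values at kept times
  t4 <- seq(0, 100, by = 0.25)
  s2 <- tibble::tibble(time_s = t4, eda = sin(2 * pi * 0.1 * t4))
  d2 <- downsample_to_2hz(s2)
  expect_lt(max(abs(d2$eda - sin(2 * pi * 0.1 * d2$time_s))), 1e-6)
})

test_that("high-pass removes DC and preserves the passband", {
  t2 <- seq(0, 300, by = 0.5)
  const <- tibble::tibble(time_s = t2, eda = rep(2, length(t2)))
  expect_lt(max(abs(highpass_001(const)$eda)), 1e-3)

  tone <- tibble::tibble(time_s = t2, eda = sin(2 * pi * 0.2 * t2))
  hp <- highpass_001(tone)$eda
  interior <- t2 > 20 & t2 < 280
  expect_lt(max(abs(hp[interior] - tone$eda[interior])) /
              max(abs(tone$eda)), 0.02)

  zero <- tibble::tibble(time_s = t2, eda = numeric(length(t2)))
  expect_equal(highpass_001(zero)$eda, zero$eda)
})

test_that("full chain yields 2 Hz output with near-zero response to constants", {
  t <- seq(0, 300, by = 1 / 30)
  rec <- tibble::tibble(time_s = t, eda_uS = rep(2, length(t)))
  out <- preprocess_eda(rec)
  expect_equal(edapain:::series_rate(out$time_s), 2)
  expect_lt(max(abs(out$eda)), 1e-3)
  expect_lt(abs(nrow(out) - 300 * 2), 2)
  expect_error(preprocess_eda(rec[t <= 30, ]), "60 s")
})

test_that("stage order matters on spiky input (median before high-pass)", {
  set.seed(2)
  t <- seq(0, 120, by = 1 / 30)
  x <- 2 + 0.5 * sin(2 * pi * 0.1 * t)
  x[sample(length(t), 30)] <- x[sample(length(t), 30)] + 8  # spikes
  rec <- tibble::tibble(time_s = t, eda_uS = x)
  ref <- preprocess_eda(rec)
  permuted <- rec %>%
    resample_cubic_spline(4) %>%
    highpass_001() %>%            # high-pass before median: wrong order
    median_filter_1s() %>%
    downsample_to_2hz()
  expect_gt(sqrt(mean((permuted$eda - ref$eda)^2)), 0.01)
})

test_that("linear stages commute with scalar scaling; chain is deterministic", {
  sub <- generate_subject(sim_config(n_subjects = 1, raw_rate = 30, seed = 3), 1)
  a <- preprocess_eda(sub$record)
  b <- preprocess_eda(dplyr::mutate(sub$record, eda_uS = 3 * eda_uS))
  expect_equal(b$eda, 3 * a$eda, tolerance = 1e-9)
  expect_identical(a, preprocess_eda(sub$record))
})
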