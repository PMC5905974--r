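test_that("beat detection recovers every generated beat", {
  abp <- generate_abp(abp_spec(heart_rate = 60, systolic = 120, diastolic = 80,
                               duration = 60, fs = 1000), seed = 1)
  b <- detect_beats(abp)
  expect_equal(nrow(b), 60)
  expect_lt(max(abs(b$systolic - 120)), 0.1)
  expect_lt(max(abs(b$diastolic - 80)), 0.5)
})

test_that("beat detection is robust to 1 mmHg white noise", {
  clean <- generate_abp(abp_spec(heart_rate = 60, systolic = 120, diastolic = 80,
                                 duration = 60, fs = 1000), seed = 2)
  noisy <- generate_abp(abp_spec(heart_rate = 60, systolic = 120, diastolic = 80,
                                 duration = 60, fs = 1000, noise_sd = 1), seed = 2)
  expect_equal(nrow(detect_beats(noisy)), nrow(detect_beats(clean)))
})

test_that("flat or too-short signals raise signal-quality errors", {
  flat <- raw_signal(rep(90, 20000), fs = 1000, units = "mmHg")
  expect_error(detect_beats(flat), class = "cacoupling_signal_quality")
  short <- generate_abp(abp_spec(duration = 5, fs = 1000), seed = 1)
  expect_error(detect_beats(short), class = "cacoupling_invalid_parameter")
})

test_that("MAP formula is diastolic plus a third of pulse pressure", {
  b <- tibble::tibble(time = 1:3, systolic = c(120, 100, 150),
                      diastolic = c(80, 100, 90), map = NA_real_)
  out <- compute_map(b)
  expect_equal(out$map, c(80 + 40 / 3, 100, 110))
  b$systolic[2] <- 99
  expect_error(compute_map(b), class = "cacoupling_data_integrity")
})

test_that("spline resampling honours the grid contract and reproduces signals", {
  # constants pass through exactly
  b <- tibble::tibble(time = seq(0, 30, by = 0.8))
  b$systolic <- 120; b$diastolic <- 80
  b$map <- 93
  out <- resample_uniform(b, 10)
  expect_equal(unique(out$value), 93)
  expect_equal(signal_fs(out), 10)
  expect_equal(nrow(out), floor((max(b$time) - min(b$time)) * 10) + 1)
  # a slow sinusoid sampled at beat times is recovered to < 1% RMS
  bt <- seq(0, 120, by = 0.85)
  b2 <- tibble::tibble(time = bt, systolic = 120, diastolic = 80,
                       map = 93 + 3 * sin(2 * pi * 0.05 * bt))
  r <- resample_uniform(b2, 10)
  truth <- 93 + 3 * sin(2 * pi * 0.05 * r$time)
  expect_lt(sqrt(mean((r$value - truth)^2)) / 3, 0.01)
  expect_error(resample_uniform(b2[1:3, ]), class = "cacoupling_insufficient_data")
})

test_that("despiking leaves clean signals untouched and repairs spikes", {
  x <- tone_signal(0.1, duration = 60, fs = 10)
  expect_identical(despike(x)$value, x$value)
  # one 10-SD spike
  v <- x$value
  v[300] <- v[300] + 10 * stats::sd(x$value)
  d1 <- despike(raw_signal(v, 10))
  expect_lt(max(abs(d1$value - x$value)), 0.05)
  # two adjacent spikes removed in one interpolated span
  v2 <- x$value
  v2[300:301] <- v2[300:301] + 8 * stats::sd(x$value)
  d2 <- despike(raw_signal(v2, 10))
  expect_equal(attr(d2, "flagged"), c(300L, 301L))
  expect_lt(max(abs(d2$value - x$value)), 0.05)
  # idempotence
  expect_identical(despike(d2)$value, d2$value)
})

test_that("band-pass keeps the passband, kills DC, and guards Nyquist", {
  x <- tone_signal(0.1, duration = 60, fs = 10)
  f <- bandpass(x)
  core <- 150:451
  expect_lt(abs((max(f$value[core]) - min(f$value[core])) / 2 - 1), 0.02)
  dc <- bandpass(raw_signal(rep(5, 601), 10))
  expect_lt(max(abs(dc$value[core])), 0.05)
  expect_error(bandpass(x, f_hi = 5), class = "cacoupling_invalid_parameter")
})

test_that("filtering is zero-phase", {
  # a palindromic input is invariant under reversal, so filtering commutes
  t <- seq(0, 99.9, by = 0.1)
  pal <- cos(2 * pi * 0.08 * (t - max(t) / 2))
  f <- bandpass(raw_signal(pal, 10))
  frev <- bandpass(raw_signal(rev(pal), 10))
  # agreement up to the finite-record transient of the 0.005 Hz high-pass
  expect_lt(max(abs(rev(frev$value) - f$value)), 0.02)
  # and a passband tone suffers no phase shift
  x <- tone_signal(0.1, duration = 600, fs = 10)
  f2 <- bandpass(x)
  mid <- 600:5400
  s <- sin(2 * pi * 0.1 * x$time[mid])
  cc <- cos(2 * pi * 0.1 * x$time[mid])
  fit <- stats::lm(f2$value[mid] ~ s + cc - 1)
  shift <- atan2(stats::coef(fit)["cc"], stats::coef(fit)["s"])
  expect_lt(abs(shift), 0.01)
})

test_that("normalization is an exact z-score and affine invariant", {
  x <- tone_signal(0.07, duration = 60, fs = 10)
  z <- normalize_signal(x)
  expect_lt(abs(mean(z$value)), 1e-12)
  expect_lt(abs(stats::var(z$value) - 1), 1e-12)
  z2 <- normalize_signal(raw_signal(3.7 * x$value + 11, 10))
  expect_equal(z2$value, z$value, tolerance = 1e-9)
  expect_error(normalize_signal(raw_signal(rep(1, 100), 10)),
               class = "cacoupling_degenerate_signal")
})

test_that("the ABP-to-MAP chain preserves injected slow oscillations", {
  spec <- abp_spec(heart_rate = 70, systolic = 120, diastolic = 80,
                   slow_modulation = data.frame(frequency = 0.05, amplitude = 3),
                   duration = 180, fs = 500)
  abp <- generate_abp(spec, seed = 7)
  m10 <- resample_uniform(compute_map(detect_beats(abp)), 10)
  ref <- 3 * sin(2 * pi * 0.05 * m10$time)
  expect_gt(band_coherence(m10$value, ref, 10, 0.05), 0.95)
})
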