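test_that("noise-free uncoupled oscillators advance exactly linearly", {
  pp <- simulate_phase_pair(oscillator_spec(0.1), oscillator_spec(0.13),
    duration = 120, dt = 0.01, seed = 1
  )
  expect_lt(max(abs(pp$phase1 - 2 * pi * 0.1 * pp$time)), 1e-9)
  expect_lt(max(abs(pp$phase2 - 2 * pi * 0.13 * pp$time)), 1e-9)
})

test_that("simulation is a pure function of (spec, seed)", {
  s1 <- oscillator_spec(0.1, noise_intensity = 0.01)
  s2 <- oscillator_spec(0.1, coupling_term(0.2), noise_intensity = 0.01)
  a <- simulate_phase_pair(s1, s2, 60, seed = 11)
  b <- simulate_phase_pair(s1, s2, 60, seed = 11)
  expect_identical(a$phase1, b$phase1)
  expect_identical(a$phase2, b$phase2)
  d <- simulate_phase_pair(s1, s2, 60, seed = 12)
  expect_false(identical(a$phase2, d$phase2))
})

test_that("invalid step or duration is rejected", {
  s <- oscillator_spec(0.1)
  expect_error(simulate_phase_pair(s, s, duration = -1, dt = 0.01),
               class = "cacoupling_invalid_parameter")
  expect_error(simulate_phase_pair(s, s, duration = 60, dt = 0),
               class = "cacoupling_invalid_parameter")
})

test_that("sin-coupled identical oscillators phase-lock", {
  s1 <- oscillator_spec(0.1, coupling_term(0.5), noise_intensity = 1e-4)
  s2 <- oscillator_spec(0.1, noise_intensity = 1e-4)
  pp <- simulate_phase_pair(s1, s2, 600, dt = 0.01, seed = 3)
  last <- pp$time > 300
  expect_lt(circular_variance(pp$phase2[last] - pp$phase1[last]), 0.1)
})

test_that("Euler integration agrees with a 10x finer step when noise-free", {
  s1 <- oscillator_spec(0.1, coupling_term(0.5))
  s2 <- oscillator_spec(0.11)
  coarse <- simulate_phase_pair(s1, s2, 120, dt = 0.01, seed = 1, fs_out = 10)
  fine <- simulate_phase_pair(s1, s2, 120, dt = 0.001, seed = 1, fs_out = 10)
  expect_lt(max(abs(coarse$phase1 - fine$phase1)), 5e-3)
})

test_that("phase increments have mean h*omega and variance 2*D*h", {
  D <- 0.01
  h <- 0.01
  s <- oscillator_spec(0.1, noise_intensity = D)
  pp <- simulate_phase_pair(s, s, duration = 1e5 * h, dt = h, seed = 9)
  dp <- diff(pp$phase1)
  expect_lt(abs(mean(dp) - h * 2 * pi * 0.1) / (h * 2 * pi * 0.1), 0.05)
  expect_lt(abs(stats::var(dp) - 2 * D * h) / (2 * D * h), 0.05)
})

test_that("generated pressure waveform hits the specified beat extrema", {
  spec <- abp_spec(heart_rate = 60, systolic = 120, diastolic = 80,
                   duration = 60, fs = 1000)
  abp <- generate_abp(spec, seed = 1)
  gt <- attr(abp, "ground_truth")
  expect_equal(nrow(gt), 60)
  # per-beat max/min equal systolic/diastolic on the sampled grid
  beat_id <- findInterval(abp$time, gt$onset)
  mx <- tapply(abp$value, beat_id, max)
  mn <- tapply(abp$value, beat_id, min)
  expect_lt(max(abs(mx - 120)), 0.1)
  expect_lt(max(abs(mn - 80)), 0.1)
})

test_that("beat-wise MAP of an unmodulated waveform is constant at DBP + PP/3", {
  spec <- abp_spec(heart_rate = 70, systolic = 120, diastolic = 80,
                   duration = 60, fs = 500)
  abp <- generate_abp(spec, seed = 2)
  beats <- compute_map(detect_beats(abp))
  expect_lt(max(abs(beats$map - (80 + 40 / 3))), 0.2)
})

test_that("degenerate pressure specifications are rejected", {
  expect_error(abp_spec(duration = 0), class = "cacoupling_empty_signal")
  expect_error(abp_spec(systolic = 80, diastolic = 120),
               class = "cacoupling_invalid_parameter")
  expect_error(abp_spec(heart_rate = 20), class = "cacoupling_invalid_parameter")
})

test_that("slow modulation appears as a spectral peak of the beat MAP trend", {
  spec <- abp_spec(heart_rate = 70, systolic = 120, diastolic = 80,
                   slow_modulation = data.frame(frequency = 0.05, amplitude = 4),
                   duration = 300, fs = 500)
  abp <- generate_abp(spec, seed = 3)
  m10 <- resample_uniform(compute_map(detect_beats(abp)), 10)
  sp <- stats::spec.pgram(stats::ts(m10$value - mean(m10$value), frequency = 10),
                          spans = 3, plot = FALSE)
  slow <- sp$freq < 0.5
  expect_lt(abs(sp$freq[slow][which.max(sp$spec[slow])] - 0.05), 0.01)
})

test_that("HbO2 channel with no artifacts is exactly the oscillation sum", {
  n <- 600
  drv <- list(III = phase_series(2 * pi * 0.1 * (0:(n - 1)) / 10, fs = 10))
  specs <- list(III = oscillator_spec(0.08, coupling_term(0.3),
                                      noise_intensity = 0.005))
  ch <- generate_hbo2_channel(drv, specs, artifact = artifact_spec(spike_rate = 0),
                              fs = 10, noise_sd = 0, seed = 4)
  gt <- attr(ch, "ground_truth")
  expect_equal(ch$value, cos(gt$band_phase$III), tolerance = 1e-12)
  expect_length(attr(ch, "spike_times"), 0)
  expect_equal(gt$coupling$coefficient, 0.3)
})

test_that("spikes are injected at the configured rate and mismatched spans error", {
  n <- 6000
  drv <- list(III = phase_series(2 * pi * 0.1 * (0:(n - 1)) / 10, fs = 10))
  specs <- list(III = oscillator_spec(0.08, noise_intensity = 0.005))
  ch <- generate_hbo2_channel(drv, specs,
    artifact = artifact_spec(spike_rate = 2, spike_amplitude = 8),
    fs = 10, noise_sd = 0.1, seed = 5
  )
  expect_gt(length(attr(ch, "spike_times")), 0)
  bad <- list(III = drv$III, IV = phase_series(rep(0, n - 10), fs = 10))
  specs2 <- c(specs, list(IV = oscillator_spec(0.03)))
  expect_error(
    generate_hbo2_channel(bad, specs2, fs = 10, seed = 1),
    class = "cacoupling_alignment_error"
  )
})

test_that("signal CSV round-trips with ground-truth sidecar", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  x <- tone_signal(0.1, duration = 30, fs = 10)
  write_signal_csv(x, tmp, ground_truth = list(f = 0.1))
  y <- read_signal_csv(tmp)
  expect_equal(y$value, x$value, tolerance = 1e-9)
  expect_equal(signal_fs(y), 10, tolerance = 1e-9)
  expect_true(file.exists(paste0(tmp, ".json")))
  expect_equal(jsonlite::read_json(paste0(tmp, ".json"))$f, 0.1)
})
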