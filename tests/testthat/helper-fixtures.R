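# shared fixtures: the standard validation pair used across inference tests
# (source 0.25 Hz, target 0.1 Hz: detuned enough that a <= 0.5 rad/s coupling
# does not phase-lock the pair, keeping the Fourier basis well conditioned)

validation_pair <- function(a = 0.3, seed = 1L, duration = 600, D = 0.01,
                            f_source = 0.25, f_target = 0.1, dt = 0.02,
                            fs_out = 10) {
  src <- oscillator_spec(f_source, noise_intensity = D)
  tgt <- oscillator_spec(f_target,
    coupling = if (a > 0) coupling_term(a) else NULL,
    noise_intensity = D
  )
  simulate_phase_pair(src, tgt, duration,
    dt = dt, seed = seed, fs_out = fs_out, labels = c("map", "hbo2")
  )
}

quiet_infer <- function(...) {
  suppressMessages(suppressWarnings(infer_window(...)))
}

tone_signal <- function(f, duration = 600, fs = 10, amplitude = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  raw_signal(amplitude * sin(2 * pi * f * t + phase), fs, label = "tone")
}

# circular variance of an angle sample: 1 - |mean resultant|
circular_variance <- function(theta) {
  1 - Mod(mean(exp(1i * theta)))
}
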