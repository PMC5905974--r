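#' Specify a stochastic phase oscillator
#'
#' Describes one oscillator of a coupled phase-oscillator pair: its natural
#' frequency, the Fourier coupling terms through which the other oscillator's
#' phase enters its phase equation, and the intensity of its additive Gaussian
#' white phase noise. The phase equation is
#' \deqn{\dot\phi = 2\pi f_0 + \sum_j c_j \, g_j(k_{src,j}\phi_{src} +
#'   k_{self,j}\phi) + \xi(t),}
#' with \eqn{g_j \in \{\sin, \cos\}} and \eqn{\langle\xi(t)\xi(s)\rangle =
#' 2D\,\delta(t-s)}.
#'
#' @param natural_frequency Natural frequency in cycles/s (> 0).
#' @param coupling Tibble/data frame with columns `k_source`, `k_self`
#'   (integers), `coefficient` (rad/s) and `func` (`"sin"` or `"cos"`), or
#'   `NULL` for an uncoupled oscillator. [coupling_term()] builds one row.
#' @param noise_intensity Phase-noise intensity D in rad^2/s (>= 0).
#' @return An object of class `oscillator_spec`.
#' @export
#' @examples
#' # phase driven by 0.3 sin(phi_src - phi_self), weak noise
#' oscillator_spec(0.1, coupling_term(0.3), noise_intensity = 0.01)
oscillator_spec <- function(natural_frequency, coupling = NULL, noise_intensity = 0) {
  if (!is.numeric(natural_frequency) || natural_frequency <= 0) {
    rlang::abort("`natural_frequency` must be positive.",
      class = "cacoupling_invalid_parameter")
  }
  if (noise_intensity < 0) {
    rlang::abort("`noise_intensity` must be >= 0.", class = "cacoupling_invalid_parameter")
  }
  if (is.null(coupling)) {
    coupling <- tibble::tibble(
      k_source = integer(), k_self = integer(),
      coefficient = numeric(), func = character()
    )
  }
  coupling <- tibble::as_tibble(coupling)
  stopifnot(all(c("k_source", "k_self", "coefficient", "func") %in% names(coupling)))
  if (any(!is.finite(coupling$coefficient))) {
    rlang::abort("Coupling coefficients must be finite.",
      class = "cacoupling_invalid_parameter")
  }
  if (!all(coupling$func %in% c("sin", "cos"))) {
    rlang::abort("`func` must be 'sin' or 'cos'.", class = "cacoupling_invalid_parameter")
  }
  structure(
    list(
      natural_frequency = natural_frequency,
      coupling = coupling,
      noise_intensity = noise_intensity
    ),
    class = "oscillator_spec"
  )
}

#' One sinusoidal coupling term
#'
#' Convenience constructor for the most common coupling form
#' `coefficient * sin(phi_source - phi_self)` (defaults), returned as a one-row
#' tibble suitable for [oscillator_spec()].
#'
#' @param coefficient Coupling coefficient in rad/s.
#' @param k_source,k_self Integer Fourier orders of the source and self phase.
#' @param func `"sin"` or `"cos"`.
#' @export
coupling_term <- function(coefficient, k_source = 1L, k_self = -1L, func = "sin") {
  tibble::tibble(
    k_source = as.integer(k_source), k_self = as.integer(k_self),
    coefficient = coefficient, func = func
  )
}

# evaluate q(phi_self, phi_source) for an oscillator_spec (vectorised)
eval_coupling <- function(spec, phi_self, phi_source) {
  q <- 0
  cp <- spec$coupling
  if (nrow(cp)) {
    for (j in seq_len(nrow(cp))) {
      arg <- cp$k_source[j] * phi_source + cp$k_self[j] * phi_self
      q <- q + cp$coefficient[j] * if (cp$func[j] == "sin") sin(arg) else cos(arg)
    }
  }
  q
}

#' Simulate a pair of coupled stochastic phase oscillators
#'
#' Integrates the two coupled phase equations with the Euler--Maruyama scheme
#' and returns unwrapped phase trajectories. With identical `seed` the output
#' is bitwise identical.
#'
#' @param spec1,spec2 [oscillator_spec()] objects. `spec1`'s coupling terms
#'   take oscillator 2 as the source and vice versa.
#' @param duration Record length in seconds (>= dt).
#' @param dt Integration step in seconds; default 0.01 s.
#' @param seed Integer RNG seed.
#' @param fs_out Output sampling rate in Hz; the trajectory is decimated from
#'   the integration grid (`1/dt` must be a multiple of `fs_out`). Default
#'   `1/dt` (no decimation).
#' @param labels Oscillator labels for the returned [phase_pair()].
#' @return A [phase_pair()].
#' @export
simulate_phase_pair <- function(spec1, spec2, duration, dt = 0.01, seed = 1L,
                                fs_out = NULL, labels = c("osc1", "osc2")) {
  if (!is.numeric(dt) || dt <= 0 || !is.numeric(duration) || duration <= 0) {
    rlang::abort("`dt` and `duration` must be positive.",
      class = "cacoupling_invalid_parameter")
  }
  n <- floor(duration / dt)
  if (n < 2) {
    rlang::abort("Duration too short for the requested step.",
      class = "cacoupling_invalid_parameter")
  }
  sd1 <- sqrt(2 * spec1$noise_intensity * dt)
  sd2 <- sqrt(2 * spec2$noise_intensity * dt)
  w1 <- 2 * pi * spec1$natural_frequency
  w2 <- 2 * pi * spec2$natural_frequency
  withr::with_seed(seed, {
    e1 <- if (sd1 > 0) stats::rnorm(n - 1, 0, sd1) else numeric(n - 1)
    e2 <- if (sd2 > 0) stats::rnorm(n - 1, 0, sd2) else numeric(n - 1)
  })
  phi1 <- numeric(n)
  phi2 <- numeric(n)
  c1 <- spec1$coupling
  c2 <- spec2$coupling
  if (nrow(c1) == 0L && nrow(c2) == 0L) {
    # uncoupled: both are driftless random walks, integrate vectorised
    phi1 <- cumsum(c(0, w1 * dt + e1))
    phi2 <- cumsum(c(0, w2 * dt + e2))
  } else {
    k1s <- c1$k_source; k1i <- c1$k_self; a1 <- c1$coefficient; s1 <- c1$func == "sin"
    k2s <- c2$k_source; k2i <- c2$k_self; a2 <- c2$coefficient; s2 <- c2$func == "sin"
    for (l in seq_len(n - 1)) {
      p1 <- phi1[l]; p2 <- phi2[l]
      q1 <- 0
      if (length(a1)) {
        arg <- k1s * p2 + k1i * p1
        q1 <- sum(a1 * ifelse(s1, sin(arg), cos(arg)))
      }
      q2 <- 0
      if (length(a2)) {
        arg <- k2s * p1 + k2i * p2
        q2 <- sum(a2 * ifelse(s2, sin(arg), cos(arg)))
      }
      phi1[l + 1] <- p1 + (w1 + q1) * dt + e1[l]
      phi2[l + 1] <- p2 + (w2 + q2) * dt + e2[l]
    }
  }
  fs_int <- 1 / dt
  if (is.null(fs_out)) fs_out <- fs_int
  step <- fs_int / fs_out
  if (abs(step - round(step)) > 1e-8) {
    rlang::abort("`1/dt` must be an integer multiple of `fs_out`.",
      class = "cacoupling_invalid_parameter")
  }
  idx <- seq(1L, n, by = round(step))
  phase_pair(phi1[idx], phi2[idx], fs = fs_out, labels = labels)
}

#' Specify a pulsatile arterial-pressure waveform
#'
#' @param heart_rate Beats per minute, in \[30, 180\].
#' @param systolic,diastolic Per-beat extreme pressures in mmHg
#'   (`systolic > diastolic`).
#' @param slow_modulation Tibble/data frame with columns `frequency` (Hz) and
#'   `amplitude` (mmHg) describing additive slow sinusoidal MAP oscillations,
#'   or `NULL`.
#' @param duration Record length in seconds.
#' @param fs Sampling frequency in Hz (>= 100).
#' @param noise_sd SD of additive white measurement noise in mmHg.
#' @return An object of class `abp_spec`.
#' @export
abp_spec <- function(heart_rate = 70, systolic = 120, diastolic = 80,
                     slow_modulation = NULL, duration = 600, fs = 1000,
                     noise_sd = 0) {
  if (systolic <= diastolic) {
    rlang::abort("`systolic` must exceed `diastolic`.",
      class = "cacoupling_invalid_parameter")
  }
  if (heart_rate < 30 || heart_rate > 180) {
    rlang::abort("`heart_rate` must lie in [30, 180] bpm.",
      class = "cacoupling_invalid_parameter")
  }
  if (fs < 100) {
    rlang::abort("`fs` must be >= 100 Hz.", class = "cacoupling_invalid_parameter")
  }
  if (duration <= 0) {
    rlang::abort("`duration` must be positive.", class = "cacoupling_empty_signal")
  }
  if (is.null(slow_modulation)) {
    slow_modulation <- tibble::tibble(frequency = numeric(), amplitude = numeric())
  }
  structure(
    list(
      heart_rate = heart_rate, systolic = systolic, diastolic = diastolic,
      slow_modulation = tibble::as_tibble(slow_modulation),
      duration = duration, fs = fs, noise_sd = noise_sd
    ),
    class = "abp_spec"
  )
}

# beat template on tau in [0,1): fast half-Gaussian systolic upstroke,
# exponential decay with a dicrotic-notch bump; rescaled to exactly [0,1]
abp_beat_template <- function(tau) {
  y <- ifelse(
    tau <= 0.15,
    exp(-(tau - 0.15)^2 / (2 * 0.04^2)),
    exp(-(tau - 0.15) / 0.22) + 0.15 * exp(-(tau - 0.45)^2 / (2 * 0.03^2))
  )
  (y - min(y)) / (max(y) - min(y))
}

#' Generate a pulsatile arterial-pressure signal with known ground truth
#'
#' Before slow modulation and noise, every complete beat attains exactly the
#' specified systolic maximum and diastolic minimum. The per-beat ground truth
#' (onset, systolic, diastolic, beat MAP) is attached as attribute
#' `ground_truth`.
#'
#' @param spec An [abp_spec()].
#' @param seed Integer RNG seed (used only when `noise_sd > 0`).
#' @param modulation_signal Optional numeric vector of length
#'   `duration * fs` overriding the sinusoidal `slow_modulation` (mmHg).
#' @return A [raw_signal()] in mmHg with attribute `ground_truth` (tibble:
#'   `onset`, `peak_time`, `systolic`, `diastolic`, `map`).
#' @export
generate_abp <- function(spec, seed = 1L, modulation_signal = NULL) {
  stopifnot(inherits(spec, "abp_spec"))
  n <- floor(spec$duration * spec$fs)
  if (n < 1) {
    rlang::abort("Empty signal: duration too short.", class = "cacoupling_empty_signal")
  }
  t <- (seq_len(n) - 1) / spec$fs
  period <- 60 / spec$heart_rate
  onsets <- seq(0, spec$duration - 1e-9, by = period)
  beat_idx <- pmin(findInterval(t, onsets), length(onsets))
  tau <- (t - onsets[beat_idx]) / period
  x <- spec$diastolic + (spec$systolic - spec$diastolic) * abp_beat_template(tau)
  if (is.null(modulation_signal)) {
    m <- rep(0, n)
    if (nrow(spec$slow_modulation)) {
      for (j in seq_len(nrow(spec$slow_modulation))) {
        m <- m + spec$slow_modulation$amplitude[j] *
          sin(2 * pi * spec$slow_modulation$frequency[j] * t)
      }
    }
  } else {
    stopifnot(length(modulation_signal) == n)
    m <- as.numeric(modulation_signal)
  }
  x <- x + m
  if (spec$noise_sd > 0) {
    x <- x + withr::with_seed(seed, stats::rnorm(n, 0, spec$noise_sd))
  }
  onset_m <- m[pmin(round(onsets * spec$fs) + 1, n)]
  gt <- tibble::tibble(
    onset = onsets,
    peak_time = onsets + 0.15 * period,
    systolic = spec$systolic + onset_m,
    diastolic = spec$diastolic + onset_m,
    map = spec$diastolic + (spec$systolic - spec$diastolic) / 3 + onset_m
  )
  out <- raw_signal(x, fs = spec$fs, units = "mmHg", label = "abp")
  attr(out, "ground_truth") <- gt
  out
}

#' Specify movement-artifact spikes
#'
#' @param spike_rate Events per minute (>= 0).
#' @param spike_amplitude Spike height in multiples of the clean-signal SD.
#' @param spike_duration Spike length in seconds.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(spike_rate = 0, spike_amplitude = 8, spike_duration = 0.5) {
  if (spike_rate < 0 || spike_amplitude < 0 || spike_duration < 0) {
    rlang::abort("Artifact parameters must be >= 0.",
      class = "cacoupling_invalid_parameter")
  }
  structure(
    list(
      spike_rate = spike_rate, spike_amplitude = spike_amplitude,
      spike_duration = spike_duration
    ),
    class = "artifact_spec"
  )
}

# integrate one driven phase oscillator: dphi = (w + q(phi, phi_drv(t)))dt + noise
# drv is the unwrapped driver phase sampled at fs; integration at fs*substeps
integrate_driven_phase <- function(spec, drv, fs, substeps = 10L, noise = NULL) {
  n <- length(drv)
  dt <- 1 / (fs * substeps)
  nn <- (n - 1L) * substeps + 1L
  # linear interpolation of the unwrapped driver phase onto the fine grid
  drv_fine <- stats::approx(seq_len(n), drv, xout = seq(1, n, length.out = nn))$y
  w <- 2 * pi * spec$natural_frequency
  if (is.null(noise)) noise <- numeric(nn - 1L)
  cp <- spec$coupling
  phi <- numeric(nn)
  if (nrow(cp) == 0L) {
    phi <- cumsum(c(0, w * dt + noise))
  } else {
    ks <- cp$k_source; ki <- cp$k_self; a <- cp$coefficient; is_sin <- cp$func == "sin"
    for (l in seq_len(nn - 1L)) {
      arg <- ks * drv_fine[l] + ki * phi[l]
      q <- sum(a * ifelse(is_sin, sin(arg), cos(arg)))
      phi[l + 1L] <- phi[l] + (w + q) * dt + noise[l]
    }
  }
  phi[seq(1L, nn, by = substeps)]
}

#' Generate one artifact-contaminated HbO2-like channel
#'
#' Each frequency interval contributes `amplitude * cos(phi(t))` where the
#' band phase evolves as a stochastic phase oscillator driven by the supplied
#' MAP band phase. White measurement noise and sparse boxcar-plus-ramp spikes
#' are then added. The injected coupling coefficients are recorded in the
#' `ground_truth` attribute.
#'
#' @param map_phase Named list (interval name -> [phase_series()] or numeric
#'   unwrapped phase) of MAP driving phases, all sampled at `fs` over the same
#'   span.
#' @param coupling_specs Named list (interval name -> [oscillator_spec()]) of
#'   the HbO2 band oscillators; names must match `map_phase`.
#' @param artifact An [artifact_spec()].
#' @param fs Output sampling frequency in Hz (default 10).
#' @param amplitudes Named numeric, oscillation amplitude per interval
#'   (arbitrary concentration units); default 1 for every interval.
#' @param noise_sd SD of additive white measurement noise.
#' @param seed Integer RNG seed.
#' @return A [raw_signal()] with attributes `ground_truth` (list with the
#'   coupling tables and band phases) and `spike_times`.
#' @export
generate_hbo2_channel <- function(map_phase, coupling_specs,
                                  artifact = artifact_spec(), fs = 10,
                                  amplitudes = NULL, noise_sd = 0.1, seed = 1L) {
  ivs <- names(coupling_specs)
  stopifnot(length(ivs) > 0, all(ivs %in% names(map_phase)))
  drv <- purrr::map(map_phase[ivs], function(p) {
    if (inherits(p, "phase_series")) p$phase else as.numeric(p)
  })
  n <- unique(vapply(drv, length, integer(1)))
  if (length(n) != 1L) {
    rlang::abort("All MAP phase series must cover the same time span.",
      class = "cacoupling_alignment_error")
  }
  if (is.null(amplitudes)) amplitudes <- stats::setNames(rep(1, length(ivs)), ivs)
  # integration step <= 0.01 s
  substeps <- as.integer(max(1, ceiling((1 / fs) / 0.01)))
  nn <- (n - 1L) * substeps + 1L
  dt <- 1 / (fs * substeps)
  withr::with_seed(seed, {
    noises <- purrr::map(coupling_specs, function(sp) {
      if (sp$noise_intensity > 0) {
        stats::rnorm(nn - 1L, 0, sqrt(2 * sp$noise_intensity * dt))
      } else numeric(nn - 1L)
    })
    meas <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    n_spk <- stats::rpois(1, artifact$spike_rate * n / fs / 60)
    spk_start <- sort(stats::runif(n_spk, 0, (n - 1) / fs))
    spk_sign <- sample(c(-1, 1), n_spk, replace = TRUE)
  })
  band_phase <- purrr::imap(coupling_specs, function(sp, iv) {
    integrate_driven_phase(sp, drv[[iv]], fs, substeps, noises[[iv]])
  })
  x <- rep(0, n)
  for (iv in ivs) x <- x + amplitudes[[iv]] * cos(band_phase[[iv]])
  clean_sd <- stats::sd(x)
  x <- x + meas
  if (artifact$spike_rate > 0 && n_spk > 0 && artifact$spike_duration > 0) {
    w <- max(1L, round(artifact$spike_duration * fs))
    ramp <- max(1L, round(0.2 * w))
    shape <- c(seq(0, 1, length.out = ramp + 1)[-1], rep(1, max(0, w - 2 * ramp)),
               seq(1, 0, length.out = ramp + 1)[-(ramp + 1)])
    for (j in seq_len(n_spk)) {
      i0 <- round(spk_start[j] * fs) + 1L
      idx <- i0:min(n, i0 + length(shape) - 1L)
      x[idx] <- x[idx] + spk_sign[j] * artifact$spike_amplitude * clean_sd *
        shape[seq_along(idx)]
    }
  } else {
    spk_start <- numeric()
  }
  out <- raw_signal(x, fs = fs, units = "a.u.", label = "hbo2")
  attr(out, "ground_truth") <- list(
    coupling = purrr::imap_dfr(coupling_specs, function(sp, iv) {
      cp <- sp$coupling
      if (nrow(cp) == 0L) return(tibble::tibble())
      dplyr::mutate(cp, interval = iv, .before = 1)
    }),
    band_phase = band_phase,
    amplitudes = amplitudes
  )
  attr(out, "spike_times") <- spk_start
  out
}

#' Default per-interval MAP driver specification
#'
#' Centre frequencies and phase-noise intensities of the slow MAP oscillators
#' used by [simulate_subject()]: respiratory 0.25 Hz, myogenic 0.1 Hz,
#' neurogenic 0.033 Hz, all with D = 0.01 rad^2/s; the cardiac phase is the
#' deterministic beat phase. MAP modulation amplitudes are in mmHg.
#'
#' @return Tibble with columns `interval`, `frequency`, `noise_intensity`,
#'   `map_amplitude`.
#' @export
map_driver_defaults <- function() {
  tibble::tibble(
    interval = c("II", "III", "IV"),
    frequency = c(0.25, 0.1, 0.033),
    noise_intensity = 0.01,
    map_amplitude = c(1.5, 2, 2)
  )
}

#' Simulate a complete synthetic subject
#'
#' Produces the two inputs the analysis pipeline consumes -- a pulsatile
#' 1000 Hz arterial-pressure waveform whose slow MAP oscillations follow
#' stochastic band drivers, and a 24-channel 10 Hz HbO2-like recording whose
#' band phases are driven by those same MAP phases -- together with the full
#' ground truth.
#'
#' @param coupling Tibble with columns `channel`, `interval`, `coefficient`:
#'   channels/intervals receiving MAP -> HbO2 coupling
#'   `coefficient * sin(phi_MAP - phi_HbO2)`. All other cells are uncoupled.
#' @param n_channels Number of NIRS channels (default 24).
#' @param duration Record length in seconds (default 600).
#' @param abp An [abp_spec()]; its `duration` is overridden.
#' @param drivers Tibble as [map_driver_defaults()].
#' @param hbo2_frequencies Named numeric: natural frequency of the HbO2 band
#'   oscillator in each interval. Defaults sit inside each band but detuned
#'   from the MAP drivers (cardiac excepted), mimicking local oscillators
#'   entrained only through the coupling.
#' @param hbo2_noise_intensity Phase-noise D of the HbO2 band oscillators
#'   (rad^2/s).
#' @param noise_sd Measurement-noise SD per channel (signal units).
#' @param artifact An [artifact_spec()] applied to every channel.
#' @param nirs_fs NIRS sampling rate in Hz (default 10).
#' @param seed Integer RNG seed.
#' @return List with elements `abp` ([raw_signal()]), `hbo2` (wide tibble:
#'   `time`, `ch01`...), `map_phase` (named list of driver [phase_series()]),
#'   and `ground_truth` (list: coupling table, seed, specs).
#' @export
simulate_subject <- function(coupling = NULL, n_channels = 24, duration = 600,
                             abp = abp_spec(duration = duration),
                             drivers = map_driver_defaults(),
                             hbo2_frequencies = NULL,
                             hbo2_noise_intensity = 0.01, noise_sd = 0.1,
                             artifact = artifact_spec(spike_rate = 1),
                             nirs_fs = 10, seed = 1L) {
  if (is.null(coupling)) {
    coupling <- tibble::tibble(channel = integer(), interval = character(),
                               coefficient = numeric())
  }
  n10 <- floor(duration * nirs_fs)
  t10 <- (seq_len(n10) - 1) / nirs_fs
  # stochastic slow drivers (II-IV) at the NIRS rate; cardiac phase is exact
  drv_phase <- list(I = 2 * pi * (abp$heart_rate / 60) * t10)
  for (j in seq_len(nrow(drivers))) {
    iv <- drivers$interval[j]
    sp <- oscillator_spec(drivers$frequency[j],
                          noise_intensity = drivers$noise_intensity[j])
    pp <- simulate_phase_pair(sp, sp, duration,
      dt = 1 / nirs_fs, seed = seed * 13L + j, fs_out = nirs_fs
    )
    drv_phase[[iv]] <- pp$phase1[seq_len(n10)]
  }
  # slow MAP modulation built from the drivers, interpolated to the ABP rate
  m10 <- rep(0, n10)
  for (j in seq_len(nrow(drivers))) {
    m10 <- m10 + drivers$map_amplitude[j] * cos(drv_phase[[drivers$interval[j]]])
  }
  n_abp <- floor(duration * abp$fs)
  t_abp <- (seq_len(n_abp) - 1) / abp$fs
  m_abp <- stats::approx(t10, m10, xout = t_abp, rule = 2)$y
  abp_sig <- generate_abp(abp, seed = seed * 17L, modulation_signal = m_abp)

  if (is.null(hbo2_frequencies)) {
    # in-band natural frequencies, detuned from the MAP drivers so uncoupled
    # channels do not sit at exactly the driver frequency
    hbo2_frequencies <- c(I = 0.9 * abp$heart_rate / 60, II = 0.28, III = 0.065,
                          IV = 0.04)
  }
  freq_of <- hbo2_frequencies[c("I", drivers$interval)]
  channels <- purrr::map(seq_len(n_channels), function(ch) {
    specs <- purrr::imap(freq_of, function(f0, iv) {
      row <- coupling[coupling$channel == ch & coupling$interval == iv, ]
      cp <- if (nrow(row)) coupling_term(row$coefficient[1]) else NULL
      oscillator_spec(f0, cp, noise_intensity = hbo2_noise_intensity)
    })
    generate_hbo2_channel(drv_phase, specs,
      artifact = artifact, fs = nirs_fs,
      noise_sd = noise_sd, seed = seed * 1009L + ch
    )
  })
  hbo2 <- tibble::as_tibble(
    c(list(time = t10),
      stats::setNames(purrr::map(channels, "value"),
                      sprintf("ch%02d", seq_len(n_channels))))
  )
  list(
    abp = abp_sig,
    hbo2 = hbo2,
    map_phase = purrr::imap(drv_phase, function(p, iv) {
      phase_series(p, fs = nirs_fs, interval = iv, label = "map_driver")
    }),
    ground_truth = list(coupling = coupling, seed = seed,
                        drivers = drivers, abp = unclass(abp))
  )
}

#' Write / read the two-column signal CSV format
#'
#' Signals are exchanged as plain CSV with a one-line header: either
#' two columns (`time`, `value`) for a single signal or a wide multichannel
#' table (`time`, `ch01`, ...). Ground truth travels in a JSON sidecar
#' (`<path>.json`) when supplied.
#'
#' @param x A [raw_signal()] or a wide tibble whose first column is `time`.
#' @param path Output CSV path.
#' @param ground_truth Optional list serialized to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path, ground_truth = NULL) {
  df <- as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(ground_truth)) {
    jsonlite::write_json(ground_truth, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_signal_csv
#' @param fs Sampling rate override; inferred from the `time` column when `NULL`.
#' @param units,label Metadata for the returned [raw_signal()].
#' @export
read_signal_csv <- function(path, fs = NULL, units = "", label = "") {
  df <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time))
  if (ncol(df) == 2L) {
    raw_signal(df[[2]], fs = fs, start = df$time[1], units = units, label = label)
  } else {
    tibble::as_tibble(df)
  }
}

# fast Euler step for a target phase driven through a * sin(phi_drv - phi)
sim_driven_sine <- function(drv, w, a, dt, noise) {
  n <- length(drv)
  phi <- numeric(n)
  for (l in seq_len(n - 1L)) {
    phi[l + 1L] <- phi[l] + (w + a * sin(drv[l] - phi[l])) * dt + noise[l]
  }
  phi
}

#' Simulate a two-group cohort of channel-wise coupling strengths
#'
#' Phase-level cohort experiment for validating the group statistics: every
#' subject has one myogenic-band MAP driver phase shared by all channels and
#' one HbO2 band oscillator per channel coupled to it through
#' `a * sin(phi_MAP - phi_HbO2)`. All channels carry the baseline coupling;
#' in the patient group one manipulated channel is raised. Coupling strength
#' is inferred per channel by dynamical Bayesian inference on the full
#' record, giving a tidy CS table ready for [channelwise_anova()].
#'
#' @param n_ref,n_alt Subjects in the reference ("healthy") and altered
#'   group (default 17 and 9).
#' @param n_channels Channels per subject (default 24).
#' @param manipulated_channel Channel whose coupling is raised in the altered
#'   group (default 8).
#' @param a_base,a_raised Baseline and raised coupling coefficients in rad/s
#'   (defaults 0.1 and 0.25, inside the identifiable non-locked regime of
#'   the band-III frequencies used).
#' @param driver_frequency,target_frequency Natural frequencies in Hz
#'   (defaults 0.1 and 0.065, both in the myogenic interval III).
#' @param noise_intensity Phase-noise D for both oscillators (rad^2/s).
#' @param duration Record length in seconds (default 600).
#' @param fs Sampling/inference rate in Hz (default 10).
#' @param seed Integer RNG seed.
#' @param groups Length-2 group labels.
#' @return Tidy tibble: `subject`, `group`, `channel`, `interval`,
#'   `direction`, `sigma`, `a_true`.
#' @export
simulate_cs_cohort <- function(n_ref = 17, n_alt = 9, n_channels = 24,
                               manipulated_channel = 8, a_base = 0.1,
                               a_raised = 0.25, driver_frequency = 0.1,
                               target_frequency = 0.065,
                               noise_intensity = 0.01, duration = 600,
                               fs = 10, seed = 1L,
                               groups = c("healthy", "L-H")) {
  dt <- 1 / fs
  n <- floor(duration * fs)
  w_d <- 2 * pi * driver_frequency
  w_t <- 2 * pi * target_frequency
  sdn <- sqrt(2 * noise_intensity * dt)
  basis <- build_basis(2)
  subj <- tidyr::expand_grid(
    group = factor(groups, levels = groups), idx = seq_len(max(n_ref, n_alt))
  )
  subj <- subj[(subj$group == groups[1] & subj$idx <= n_ref) |
                 (subj$group == groups[2] & subj$idx <= n_alt), ]
  purrr::pmap_dfr(subj, function(group, idx) {
    sseed <- seed + 7919L * match(group, groups) + idx
    noise <- withr::with_seed(sseed, {
      matrix(stats::rnorm(n * (n_channels + 1L), 0, sdn), ncol = n_channels + 1L)
    })
    drv <- cumsum(c(0, w_d * dt + noise[seq_len(n - 1L), 1L]))
    purrr::map_dfr(seq_len(n_channels), function(ch) {
      a <- if (ch == manipulated_channel && group == groups[2]) a_raised else a_base
      tgt <- sim_driven_sine(drv, w_t, a, dt, noise[seq_len(n - 1L), ch + 1L])
      pp <- phase_pair(drv, tgt, fs = fs, labels = c("map", "hbo2"))
      m <- suppressMessages(suppressWarnings(infer_window(pp, basis)))
      tibble::tibble(
        subject = sprintf("%s_%02d", group, idx), group = as.character(group),
        channel = ch, interval = "III", direction = "map->hbo2",
        sigma = coupling_strength(m, "1->2")$sigma, a_true = a
      )
    })
  })
}
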