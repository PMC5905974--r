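#' Detect heart beats in an arterial-pressure waveform
#'
#' Gradient-based beat detection: the waveform is lightly low-pass filtered,
#' its derivative is compared against an adaptive threshold (a fraction of the
#' rolling maximum of dP/dt over `window` seconds) to find systolic upstrokes,
#' and each upstroke is refined to the systolic peak (local maximum within
#' 0.3 s after) and the diastolic trough (local minimum within 0.5 s before).
#' A refractory period suppresses double detections.
#'
#' @param abp A [raw_signal()] sampled at >= 100 Hz, >= 10 s long.
#' @param window Adaptive-threshold window in seconds (default 2).
#' @param threshold_frac Fraction of the rolling dP/dt maximum required for an
#'   upstroke (default 0.5).
#' @param refractory Minimum spacing between upstrokes in seconds (default 0.25).
#' @return A tibble of class `beat_series`: `time` (systolic peak time, s),
#'   `trough_time`, `systolic`, `diastolic` (mmHg), `map` (`NA` until
#'   [compute_map()]).
#' @export
detect_beats <- function(abp, window = 2, threshold_frac = 0.5, refractory = 0.25) {
  fs <- attr(abp, "fs")
  if (is.null(fs) || fs < 100) {
    rlang::abort("Beat detection requires fs >= 100 Hz.",
      class = "cacoupling_invalid_parameter")
  }
  x <- abp$value
  n <- length(x)
  if (n / fs < 10) {
    rlang::abort("Beat detection requires at least 10 s of signal.",
      class = "cacoupling_invalid_parameter")
  }
  # centred moving-average smoothing (~25 ms) so sample noise does not
  # dominate dP/dt; no edge transient, unlike recursive filters
  wsm <- max(3L, round(0.025 * fs))
  if (wsm %% 2L == 0L) wsm <- wsm + 1L
  xs <- as.numeric(stats::filter(x, rep(1 / wsm, wsm), sides = 2))
  xs <- zoo::na.fill(xs, "extend")
  d <- c(diff(xs), 0) * fs
  w <- max(3L, round(window * fs))
  # O(n) rolling maximum of dP/dt: chunk maxima, each sample sees its own and
  # the two neighbouring chunks (window ~ [w, 2w])
  chunk <- (seq_along(d) - 1L) %/% w + 1L
  cm <- tapply(d, chunk, max)
  nc <- length(cm)
  thr_chunk <- pmax(cm, c(cm[-1], cm[nc]), c(cm[1], cm[-nc]))
  roll_max <- as.numeric(thr_chunk[chunk])
  # gradient floor: a flat or noise-only record must yield no beats
  floor_grad <- max(1e-8, 2 * stats::sd(d) * 1e-2, 5 * stats::mad(d))
  cand <- which(d > pmax(threshold_frac * roll_max, floor_grad))
  if (length(cand) < 5) {
    rlang::abort("Signal quality too poor: fewer than 5 beats detected.",
      class = "cacoupling_signal_quality")
  }
  # group consecutive candidates, keep the max-gradient sample of each run
  grp <- cumsum(c(1L, diff(cand) > 1L))
  ups <- vapply(split(cand, grp), function(ix) ix[which.max(d[ix])], integer(1))
  ups <- sort(ups)
  # refractory
  keep <- rep(TRUE, length(ups))
  last <- -Inf
  ref_n <- refractory * fs
  for (i in seq_along(ups)) {
    if (ups[i] - last < ref_n) keep[i] <- FALSE else last <- ups[i]
  }
  ups <- ups[keep]
  peak_w <- round(0.3 * fs)
  trough_w <- round(0.5 * fs)
  beats <- purrr::map_dfr(ups, function(u) {
    pk_ix <- u:min(n, u + peak_w)
    tr_ix <- max(1, u - trough_w):u
    pk <- pk_ix[which.max(x[pk_ix])]
    tr <- tr_ix[which.min(x[tr_ix])]
    tibble::tibble(
      time = abp$time[pk], trough_time = abp$time[tr],
      systolic = x[pk], diastolic = x[tr]
    )
  })
  # drop incomplete beats at the edges (peak clipped to the border)
  beats <- beats[beats$systolic > beats$diastolic, ]
  if (nrow(beats) < 5) {
    rlang::abort("Signal quality too poor: fewer than 5 beats detected.",
      class = "cacoupling_signal_quality")
  }
  beats$map <- NA_real_
  structure(beats, class = c("beat_series", class(beats)))
}

#' Compute the per-beat mean arterial pressure
#'
#' MAP is the diastolic pressure plus one third of the pulse pressure.
#'
#' @param beats A `beat_series` from [detect_beats()] (or any tibble with
#'   `systolic` and `diastolic` columns).
#' @return The same tibble with `map` filled.
#' @export
compute_map <- function(beats) {
  if (any(beats$systolic < beats$diastolic)) {
    rlang::abort("Data integrity: systolic < diastolic on some beat.",
      class = "cacoupling_data_integrity")
  }
  dplyr::mutate(beats, map = .data$diastolic + (.data$systolic - .data$diastolic) / 3)
}

#' Resample a beat-wise MAP series to a uniform grid
#'
#' Cubic-spline interpolation of the (beat time, MAP) pairs onto a uniform
#' grid at `target_fs`; no extrapolation beyond the first/last beat.
#'
#' @param beats A `beat_series` with `map` filled (>= 4 beats).
#' @param target_fs Target sampling frequency in Hz (default 10).
#' @return A [raw_signal()] of MAP in mmHg at `target_fs`.
#' @export
resample_uniform <- function(beats, target_fs = 10) {
  if (nrow(beats) < 4) {
    rlang::abort("Cubic spline resampling needs at least 4 beats.",
      class = "cacoupling_insufficient_data")
  }
  if (any(is.na(beats$map))) {
    rlang::abort("Run compute_map() before resampling.",
      class = "cacoupling_data_integrity")
  }
  t0 <- beats$time[1]
  t1 <- beats$time[nrow(beats)]
  grid <- seq(t0, t1, by = 1 / target_fs)
  y <- stats::spline(beats$time, beats$map, xout = grid, method = "fmm")$y
  raw_signal(y, fs = target_fs, start = t0, units = "mmHg", label = "map")
}

#' Remove abrupt spikes with moving statistics and spline interpolation
#'
#' Samples deviating from a centred moving location estimate by more than
#' `threshold` times the moving spread are flagged and replaced by
#' cubic-spline interpolation through the unflagged samples; all other
#' samples are unchanged. The moving statistics are the robust pair
#' (median, 1.4826 x MAD), so the spike itself cannot inflate the spread it
#' is tested against and bursts of adjacent spikes are still caught.
#' Contiguous flagged runs are repaired in one interpolated span, making the
#' operation idempotent.
#'
#' @param x A [raw_signal()].
#' @param window Moving window in seconds (>= 3 samples; default 1).
#' @param threshold Flagging threshold in moving-spread multiples (default 5).
#' @return The despiked [raw_signal()]; the flagged indices are attached as
#'   attribute `flagged`.
#' @export
despike <- function(x, window = 1, threshold = 5) {
  fs <- attr(x, "fs")
  v <- x$value
  n <- length(v)
  w <- max(3L, round(window * fs))
  if (w %% 2L == 0L) w <- w + 1L
  zm <- zoo::zoo(v)
  mu <- as.numeric(zoo::rollapply(zm, w, stats::median, fill = NA, partial = TRUE))
  sdv <- as.numeric(zoo::rollapply(zm, w,
    function(z) stats::mad(z, constant = 1.4826), fill = NA, partial = TRUE))
  # floor the moving spread with (a) a numerical floor so flat stretches are
  # not flagged wholesale and (b) a global robust noise estimate from first
  # differences, so a locally quiet window cannot flag ordinary noise
  sd_floor <- 1e-12 + 1e-9 * max(abs(v))
  noise_floor <- stats::mad(diff(v), constant = 1.4826) / sqrt(2)
  bad <- abs(v - mu) > threshold * pmax(sdv, noise_floor, sd_floor)
  bad[is.na(bad)] <- FALSE
  if (mean(bad) > 0.2) {
    rlang::warn(sprintf("despike: %.1f%% of samples flagged; check signal quality.",
                        100 * mean(bad)))
  }
  if (any(bad)) {
    good <- which(!bad)
    v[bad] <- stats::spline(good, v[good], xout = which(bad), method = "natural")$y
  }
  out <- replace_values(x, v)
  attr(out, "flagged") <- which(bad)
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass between `f_lo` (default 0.005 Hz, removing very slow drifts) and
#' `f_hi` (default 2 Hz, removing uncorrelated fast noise), realised as a
#' cascade of second-order high-pass and low-pass Butterworth sections applied
#' forward--backward (`filtfilt`), i.e. zero phase distortion.
#'
#' @param x A [raw_signal()].
#' @param f_lo,f_hi Corner frequencies in Hz; `f_lo < f_hi < fs/2`.
#' @param order Butterworth order of each section (default 2; effective
#'   magnitude order doubles under filtfilt).
#' @return The filtered [raw_signal()] (mean approximately 0).
#' @export
bandpass <- function(x, f_lo = 0.005, f_hi = 2, order = 2) {
  fs <- attr(x, "fs")
  if (f_hi >= fs / 2 || f_lo >= f_hi || f_lo <= 0) {
    rlang::abort("Require 0 < f_lo < f_hi < fs/2.",
      class = "cacoupling_invalid_parameter")
  }
  v <- x$value - mean(x$value)
  hp <- signal::butter(order, f_lo / (fs / 2), type = "high")
  lp <- signal::butter(order, f_hi / (fs / 2), type = "low")
  v <- as.numeric(signal::filtfilt(hp, v))
  v <- as.numeric(signal::filtfilt(lp, v))
  replace_values(x, v)
}

#' Normalize a signal to zero mean and unit variance
#'
#' @param x A [raw_signal()] with positive SD.
#' @return The z-scored [raw_signal()].
#' @export
normalize_signal <- function(x) {
  s <- stats::sd(x$value)
  if (!is.finite(s) || s == 0) {
    rlang::abort("Cannot normalize a constant signal.",
      class = "cacoupling_degenerate_signal")
  }
  replace_values(x, (x$value - mean(x$value)) / s)
}

#' Full ABP-to-MAP preprocessing chain
#'
#' Beat detection, per-beat MAP, cubic-spline resampling to 10 Hz, despiking,
#' zero-phase Butterworth band-pass (0.005--2 Hz) and z-score normalization.
#'
#' @param abp A [raw_signal()] arterial-pressure waveform (>= 100 Hz).
#' @param target_fs Output rate in Hz (default 10).
#' @param config Optional list overriding `despike_window`,
#'   `despike_threshold`, `f_lo`, `f_hi`, `filter_order`.
#' @return The cleaned, normalized 10 Hz MAP [raw_signal()].
#' @export
preprocess_abp <- function(abp, target_fs = 10, config = list()) {
  cfg <- utils::modifyList(list(
    despike_window = 1, despike_threshold = 5,
    f_lo = 0.005, f_hi = 2, filter_order = 2
  ), config)
  detect_beats(abp) |>
    compute_map() |>
    resample_uniform(target_fs = target_fs) |>
    despike(window = cfg$despike_window, threshold = cfg$despike_threshold) |>
    bandpass(f_lo = cfg$f_lo, f_hi = cfg$f_hi, order = cfg$filter_order) |>
    normalize_signal()
}

#' Preprocess one HbO2 channel
#'
#' Despiking, zero-phase band-pass and normalization (the channel is already
#' uniformly sampled).
#'
#' @inheritParams preprocess_abp
#' @param x A [raw_signal()] HbO2 channel.
#' @return The cleaned, normalized [raw_signal()].
#' @export
preprocess_hbo2 <- function(x, config = list()) {
  cfg <- utils::modifyList(list(
    despike_window = 1, despike_threshold = 5,
    f_lo = 0.005, f_hi = 2, filter_order = 2
  ), config)
  despike(x, window = cfg$despike_window, threshold = cfg$despike_threshold) |>
    bandpass(f_lo = cfg$f_lo, f_hi = cfg$f_hi, order = cfg$filter_order) |>
    normalize_signal()
}

#' Magnitude-squared spectral coherence at one frequency
#'
#' Smoothed-periodogram coherence between two equally sampled series,
#' evaluated at the Fourier bin nearest `f`. Used to verify that the
#' preprocessing chain preserves injected slow MAP oscillations.
#'
#' @param x,y Numeric vectors of equal length.
#' @param fs Sampling frequency in Hz.
#' @param f Frequency of interest in Hz.
#' @param spans Daniell smoother spans passed to [stats::spec.pgram()].
#' @return Coherence in \[0, 1\].
#' @export
band_coherence <- function(x, y, fs, f, spans = 11) {
  sp <- stats::spec.pgram(stats::ts(cbind(x, y), frequency = fs),
    spans = spans, taper = 0.1, plot = FALSE, detrend = TRUE
  )
  sp$coh[which.min(abs(sp$freq - f))]
}
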