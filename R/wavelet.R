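#' Continuous Morlet wavelet transform
#'
#' Complex continuous wavelet transform on a logarithmically spaced frequency
#' grid, computed per scale in the Fourier domain. The mother wavelet is the
#' analytic Morlet \eqn{\psi(u) = e^{2\pi i f_0 u} e^{-u^2/2}} with central
#' frequency `f0 = 1` (cycle convention), so scale `s` maps to frequency
#' `f = f0/s`. Coefficients are normalized so that equal-amplitude sinusoids
#' produce equal-magnitude ridges (a unit-amplitude tone gives ridge modulus
#' ~ 1 at its frequency).
#'
#' @param x A [raw_signal()].
#' @param f_min,f_max Frequency range in Hz; `f_max < fs/2` and the record
#'   must contain at least 3 periods of `f_min`.
#' @param voices_per_octave Frequencies per octave (default 16, i.e. ~4.4%
#'   spacing).
#' @param f0 Morlet central frequency in the cycle convention (default 1).
#' @return An object of class `wavelet_transform`: list with `coef` (complex
#'   matrix, frequencies x times), `freq` (Hz, ascending), `time` (s), `fs`,
#'   `f0`.
#' @export
cwt_morlet <- function(x, f_min, f_max, voices_per_octave = 16, f0 = 1) {
  fs <- attr(x, "fs")
  if (f_max >= fs / 2) {
    rlang::abort("`f_max` must be below the Nyquist frequency.",
      class = "cacoupling_invalid_parameter")
  }
  if (f_min <= 0 || f_min >= f_max) {
    rlang::abort("Require 0 < f_min < f_max.", class = "cacoupling_invalid_parameter")
  }
  v <- x$value
  n <- length(v)
  if (n / fs < 3 / f_min) {
    rlang::abort("Record shorter than 3 periods of `f_min`.",
      class = "cacoupling_insufficient_duration")
  }
  n_oct <- log2(f_max / f_min)
  nf <- ceiling(n_oct * voices_per_octave)
  freq <- f_max * 2^(-seq(0, n_oct, length.out = nf + 1))
  freq <- sort(freq) # ascending, includes both endpoints
  # zero-pad to reduce circular wrap; edge effects handled via cone of influence
  npad <- stats::nextn(2 * n, 2)
  vf <- stats::fft(c(v - mean(v), rep(0, npad - n)))
  fgrid <- (seq_len(npad) - 1) / npad * fs
  coef <- matrix(0i, nrow = length(freq), ncol = n)
  for (j in seq_along(freq)) {
    s <- f0 / freq[j]
    # analytic Morlet frequency response, peak value 1 at f = f0/s;
    # factor 2 restores full amplitude for real-valued input
    kern <- numeric(npad)
    pos <- fgrid > 0 & fgrid <= fs / 2
    kern[pos] <- 2 * exp(-2 * pi^2 * (s * fgrid[pos] - f0)^2)
    w <- stats::fft(vf * kern, inverse = TRUE) / npad
    coef[j, ] <- w[seq_len(n)]
  }
  structure(
    list(coef = coef, freq = freq, time = x$time, fs = fs, f0 = f0),
    class = "wavelet_transform"
  )
}

#' @export
print.wavelet_transform <- function(x, ...) {
  cat(sprintf(
    "<wavelet_transform> %d frequencies (%.3g-%.3g Hz) x %d times @ %g Hz\n",
    length(x$freq), min(x$freq), max(x$freq), length(x$time), x$fs
  ))
  invisible(x)
}

#' Extract one band-limited instantaneous phase from a wavelet transform
#'
#' At each time the complex wavelet coefficients across the interval's
#' frequencies (lower edge inclusive, upper exclusive) are summed; the
#' instantaneous phase is the quadrant-aware arctangent of that sum,
#' unwrapped over time. Summation weights frequencies by their amplitude, so
#' the dominant oscillation in the band defines the phase.
#'
#' @param wt A `wavelet_transform` from [cwt_morlet()].
#' @param interval Interval name (`"I"`..`"IV"`) or a one-row tibble with
#'   `f_min`, `f_max` columns.
#' @param power_floor Relative amplitude floor: if the band amplitude is below
#'   `power_floor` times the RMS of the analysed record for more than half the
#'   samples, a low-amplitude warning is raised and recorded in the output's
#'   `low_amplitude` attribute.
#' @return A [phase_series()] (unwrapped phase, radians).
#' @export
extract_band_phase <- function(wt, interval, power_floor = 0.01) {
  if (is.character(interval)) interval <- get_interval(interval)
  sel <- wt$freq >= interval$f_min & wt$freq < interval$f_max
  if (!any(sel)) {
    rlang::abort("Interval lies outside the transform's frequency range.",
      class = "cacoupling_invalid_parameter")
  }
  z <- colSums(wt$coef[sel, , drop = FALSE])
  amp <- Mod(z)
  # reference amplitude: strongest ridge anywhere in the transform
  ref <- max(Mod(wt$coef))
  low <- mean(amp < power_floor * ref) > 0.5
  if (low) {
    rlang::warn(sprintf(
      "Band %s: amplitude below the floor for >50%% of samples; phase unreliable.",
      interval$interval %||% ""
    ))
  }
  ph <- unwrap_phase(atan2(Im(z), Re(z)))
  out <- phase_series(ph,
    fs = wt$fs, start = wt$time[1],
    interval = interval$interval %||% NULL, label = "band_phase"
  )
  attr(out, "low_amplitude") <- low
  out
}

#' Extract all four band phases of a signal
#'
#' Convenience wrapper: one Morlet transform over 0.021--2 Hz and one
#' [extract_band_phase()] per canonical interval.
#'
#' @param x A [raw_signal()] (10 Hz typical).
#' @param voices_per_octave Frequency resolution of the transform.
#' @return Named list of [phase_series()] (`I`, `II`, `III`, `IV`).
#' @export
band_phases <- function(x, voices_per_octave = 16) {
  iv <- frequency_intervals()
  wt <- cwt_morlet(x,
    f_min = min(iv$f_min), f_max = min(max(iv$f_max), attr(x, "fs") / 2 * 0.98),
    voices_per_octave = voices_per_octave
  )
  out <- purrr::map(iv$interval, function(nm) {
    suppressWarnings(extract_band_phase(wt, nm))
  })
  stats::setNames(out, iv$interval)
}

#' Cone-of-influence trim length
#'
#' Number of seconds at each record edge that downstream inference should
#' discard: one period of the lowest analysed frequency.
#'
#' @param f_min Lowest analysed frequency in Hz.
#' @return Trim length in seconds.
#' @export
coi_trim <- function(f_min = 0.021) 1 / f_min
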