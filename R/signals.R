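#' Construct a uniformly sampled physiological signal
#'
#' A `raw_signal` is a tibble with columns `time` (seconds) and `value`,
#' carrying the sampling rate, units and a label as attributes. All
#' preprocessing and wavelet functions consume and return this class, so
#' calls chain with the pipe.
#'
#' @param value Numeric vector of samples.
#' @param fs Sampling frequency in Hz (> 0).
#' @param start Time of the first sample in seconds.
#' @param units Unit string (e.g. `"mmHg"`, `"a.u."`).
#' @param label Short label identifying the signal.
#' @return A tibble of class `raw_signal` with columns `time`, `value`.
#' @export
raw_signal <- function(value, fs, start = 0, units = "", label = "") {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    rlang::abort("`fs` must be a single positive number.", class = "cacoupling_invalid_parameter")
  }
  value <- as.numeric(value)
  out <- tibble::tibble(
    time = start + seq_along(value) / fs - 1 / fs,
    value = value
  )
  structure(out,
    class = c("raw_signal", class(out)),
    fs = fs, units = units, label = label
  )
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf(
    "<raw_signal> %s: %d samples @ %g Hz (%.1f s)%s\n",
    attr(x, "label"), nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs"),
    if (nzchar(attr(x, "units"))) paste0(" [", attr(x, "units"), "]") else ""
  ))
  NextMethod()
}

#' Sampling frequency of a signal or phase object
#' @param x A `raw_signal`, `phase_series` or `phase_pair`.
#' @return Sampling frequency in Hz.
#' @export
signal_fs <- function(x) attr(x, "fs")

# rebuild a raw_signal from an existing one with new samples
replace_values <- function(x, value) {
  raw_signal(value,
    fs = attr(x, "fs"), start = x$time[1],
    units = attr(x, "units"), label = attr(x, "label")
  )
}

#' Construct an instantaneous-phase series
#'
#' Holds one unwrapped phase trajectory for an oscillator confined to a
#' frequency interval. The wrapped phase is available through [wrap_phase()].
#'
#' @param phase Unwrapped phase in radians.
#' @param fs Sampling frequency in Hz.
#' @param start Time of the first sample in seconds.
#' @param interval Optional interval name (`"I"`, `"II"`, `"III"`, `"IV"`).
#' @param label Source-signal label.
#' @return A tibble of class `phase_series` with columns `time`, `phase`.
#' @export
phase_series <- function(phase, fs, start = 0, interval = NULL, label = "") {
  if (!is.numeric(fs) || fs <= 0) {
    rlang::abort("`fs` must be positive.", class = "cacoupling_invalid_parameter")
  }
  out <- tibble::tibble(
    time = start + seq_along(phase) / fs - 1 / fs,
    phase = as.numeric(phase)
  )
  structure(out,
    class = c("phase_series", class(out)),
    fs = fs, interval = interval, label = label
  )
}

#' @export
print.phase_series <- function(x, ...) {
  iv <- attr(x, "interval")
  cat(sprintf(
    "<phase_series> %s%s: %d samples @ %g Hz\n",
    attr(x, "label"), if (!is.null(iv)) paste0(" [interval ", iv, "]") else "",
    nrow(x), attr(x, "fs")
  ))
  NextMethod()
}

#' Wrap a phase to (-pi, pi]
#' @param phi Phase in radians (vector).
#' @return Wrapped phase in `(-pi, pi]`.
#' @export
wrap_phase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  # map -pi to +pi so the range is (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Unwrap a wrapped phase sequence
#'
#' Removes 2*pi jumps so successive differences are bounded by pi in
#' magnitude, recovering a continuous phase trajectory.
#'
#' @param phi Wrapped phase in radians.
#' @return Unwrapped phase.
#' @export
unwrap_phase <- function(phi) {
  dp <- diff(phi)
  dps <- (dp + pi) %% (2 * pi) - pi
  dps[dps == -pi & dp > 0] <- pi
  phi[1] + c(0, cumsum(dps))
}

#' Pair two phase series for coupling inference
#'
#' @param ph1,ph2 `phase_series` objects sampled at the same rate, or plain
#'   numeric unwrapped-phase vectors (then `fs` is required).
#' @param fs Sampling frequency, required when plain vectors are given.
#' @param labels Length-2 character: names of the two oscillators
#'   (conventionally `c("map", "hbo2")`).
#' @return A tibble of class `phase_pair` with columns `time`, `phase1`,
#'   `phase2` and attributes `fs`, `labels`.
#' @export
phase_pair <- function(ph1, ph2, fs = NULL, labels = c("map", "hbo2")) {
  get_phase <- function(p) if (inherits(p, "phase_series")) p$phase else as.numeric(p)
  if (inherits(ph1, "phase_series")) fs <- attr(ph1, "fs")
  if (is.null(fs)) {
    rlang::abort("`fs` is required when phases are plain vectors.",
      class = "cacoupling_invalid_parameter")
  }
  p1 <- get_phase(ph1)
  p2 <- get_phase(ph2)
  if (length(p1) != length(p2)) {
    rlang::abort("Phase series must cover the same time span.",
      class = "cacoupling_alignment_error")
  }
  out <- tibble::tibble(
    time = seq_along(p1) / fs - 1 / fs,
    phase1 = p1, phase2 = p2
  )
  structure(out,
    class = c("phase_pair", class(out)),
    fs = fs, labels = labels
  )
}

#' @export
print.phase_pair <- function(x, ...) {
  cat(sprintf(
    "<phase_pair> %s / %s: %d samples @ %g Hz\n",
    attr(x, "labels")[1], attr(x, "labels")[2], nrow(x), attr(x, "fs")
  ))
  NextMethod()
}

#' The four canonical frequency intervals
#'
#' Cardiac (I), respiratory (II), myogenic (III) and neurogenic (IV)
#' oscillation bands. Lower edges are inclusive, upper edges exclusive, so
#' the four intervals partition 0.021--2 Hz without gaps or overlaps.
#'
#' @return A tibble with columns `interval`, `f_min`, `f_max` (Hz).
#' @export
frequency_intervals <- function() {
  tibble::tibble(
    interval = c("I", "II", "III", "IV"),
    f_min = c(0.6, 0.145, 0.052, 0.021),
    f_max = c(2, 0.6, 0.145, 0.052)
  )
}

#' Look up one frequency interval by name
#' @param name One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return One-row tibble with `interval`, `f_min`, `f_max`.
#' @export
get_interval <- function(name) {
  iv <- frequency_intervals()
  row <- iv[iv$interval == name, ]
  if (nrow(row) != 1L) {
    rlang::abort(sprintf("Unknown frequency interval '%s'.", name),
      class = "cacoupling_invalid_parameter")
  }
  row
}
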