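#' Phase-randomized surrogate of a phase series
#'
#' Cyclic rotation surrogate: the wrapped increments of the unwrapped phase
#' are rotated cyclically by a uniformly random offset of at least
#' `min_offset` seconds and re-integrated from the original initial value.
#' The increment distribution, mean frequency and increment autocorrelation
#' are preserved exactly, while the temporal alignment with any other signal
#' is destroyed.
#'
#' @param phase A [phase_series()] or numeric unwrapped phase vector.
#' @param seed Integer RNG seed.
#' @param min_offset Minimum rotation in seconds (default 10).
#' @param fs Sampling rate, required when `phase` is a plain vector.
#' @param offset Force a specific offset in samples (testing hook); `NULL`
#'   draws it from the seed.
#' @return An object of the same type as `phase` with surrogate phases.
#' @export
make_surrogate_phase <- function(phase, seed = 1L, min_offset = 10, fs = NULL,
                                 offset = NULL) {
  is_ps <- inherits(phase, "phase_series")
  p <- if (is_ps) phase$phase else as.numeric(phase)
  if (is_ps) fs <- attr(phase, "fs")
  if (is.null(fs)) {
    rlang::abort("`fs` required for plain vectors.",
      class = "cacoupling_invalid_parameter")
  }
  n <- length(p)
  k_min <- round(min_offset * fs)
  if (is.null(offset)) {
    if (n - 1L <= 2L * k_min) {
      rlang::abort("Record too short for the minimum surrogate offset.",
        class = "cacoupling_invalid_parameter")
    }
    offset <- withr::with_seed(seed, sample(k_min:(n - 1L - k_min), 1L))
  }
  dp <- diff(p)
  if (offset %% (n - 1L) != 0L) {
    k <- offset %% (n - 1L)
    dp <- c(dp[(k + 1L):(n - 1L)], dp[1:k])
  }
  out_p <- p[1] + c(0, cumsum(dp))
  if (is_ps) {
    phase_series(out_p,
      fs = fs, start = phase$time[1],
      interval = attr(phase, "interval"), label = paste0(attr(phase, "label"), "_surr")
    )
  } else {
    out_p
  }
}

#' Surrogate ensemble of coupling strengths
#'
#' Re-runs the coupling-strength estimate against `n_surrogates` surrogate
#' versions of the source phase (the target phase is left untouched) and
#' stores the empirical null distribution together with the mean + 2 SD
#' significance threshold.
#'
#' @param pair A [phase_pair()] (oscillator 1 = source of `direction`).
#' @param direction `"1->2"` or `"2->1"`: which coupling the null is built for.
#' @param basis A [build_basis()] result.
#' @param n_surrogates Ensemble size (default 100).
#' @param seed Integer seed; surrogate `i` uses `seed + i`.
#' @param window Window length in seconds for the estimator; `NULL` (default)
#'   uses one batch window over the whole record.
#' @param propagation Propagation factor when `window` is given.
#' @param burn_in Leading windows excluded from the CS average (see
#'   [coupling_strength()]).
#' @param min_offset Minimum rotation offset in seconds.
#' @return An object of class `surrogate_ensemble`: list with `sigma`
#'   (numeric vector), `threshold`, `method`, `n_surrogates`, `seed`,
#'   `direction`.
#' @export
surrogate_ensemble <- function(pair, direction = "1->2", basis = build_basis(2),
                               n_surrogates = 100, seed = 1L, window = NULL,
                               propagation = 0.2, burn_in = 0, min_offset = 10) {
  fs <- attr(pair, "fs")
  src <- if (direction == "1->2") "phase1" else "phase2"
  cs_of <- function(pp) {
    if (is.null(window)) {
      coupling_strength(infer_window(pp, basis), direction)$sigma
    } else {
      coupling_strength(
        infer_time_evolving(pp, basis, window = window, propagation = propagation),
        direction, burn_in = burn_in
      )$sigma
    }
  }
  sig <- vapply(seq_len(n_surrogates), function(i) {
    ps <- make_surrogate_phase(pair[[src]], seed = seed + i, min_offset = min_offset,
                               fs = fs)
    pp <- if (direction == "1->2") {
      phase_pair(ps, pair$phase2, fs = fs, labels = attr(pair, "labels"))
    } else {
      phase_pair(pair$phase1, ps, fs = fs, labels = attr(pair, "labels"))
    }
    suppressMessages(suppressWarnings(cs_of(pp)))
  }, numeric(1))
  structure(
    list(
      sigma = sig,
      threshold = mean(sig) + 2 * stats::sd(sig),
      method = "cyclic-increment-rotation",
      n_surrogates = n_surrogates, seed = seed, direction = direction
    ),
    class = "surrogate_ensemble"
  )
}

#' Significance of a coupling strength against its surrogate null
#'
#' A CS is significant when it exceeds the surrogate mean plus twice the
#' surrogate SD.
#'
#' @param sigma Observed coupling strength (scalar) or a one-row tibble from
#'   [coupling_strength()].
#' @param ensemble A [surrogate_ensemble()].
#' @return A one-row tibble: `sigma`, `significant`, `surrogate_mean`,
#'   `surrogate_sd`, `threshold`.
#' @export
significance <- function(sigma, ensemble) {
  if (is.data.frame(sigma)) sigma <- sigma$sigma
  tibble::tibble(
    sigma = sigma,
    significant = sigma > ensemble$threshold,
    surrogate_mean = mean(ensemble$sigma),
    surrogate_sd = stats::sd(ensemble$sigma),
    threshold = ensemble$threshold
  )
}

#' Dominant coupling direction of a channel/interval cell
#'
#' @param records Tibble with columns `direction` and `significant` (both
#'   directions of one cell).
#' @return Character: the significant direction(s) collapsed with `"+"`, or
#'   `"none"`.
#' @export
dominant_direction <- function(records) {
  sig <- records$direction[records$significant]
  if (length(sig) == 0L) "none" else paste(sig, collapse = "+")
}
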