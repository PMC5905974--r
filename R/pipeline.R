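#' Pipeline configuration
#'
#' Builds the nested configuration list controlling every stage, validated
#' against the known schema: unknown keys are rejected. Any subset of keys
#' may be overridden; [read_pipeline_config()] loads overrides from a YAML
#' file.
#'
#' @param ... Named overrides, e.g. `dbi = list(window = 40)`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    preprocess = list(
      target_fs = 10, despike_window = 1, despike_threshold = 5,
      f_lo = 0.005, f_hi = 2, filter_order = 2, edge_trim = 10
    ),
    wavelet = list(voices_per_octave = 16, f0 = 1, power_floor = 0.01),
    dbi = list(K = 2, window = 50, propagation = 0.2, include_self = FALSE),
    surrogate = list(n = 100, seed = 42, min_offset = 10),
    stats = list(alpha = 0.05, m = 8, reference = "healthy"),
    channels = list(n = 24, strict = TRUE),
    min_duration = 300
  )
  over <- list(...)
  cfg <- defaults
  for (nm in names(over)) {
    if (!nm %in% names(defaults)) {
      rlang::abort(sprintf("Unknown config key '%s'.", nm),
        class = "cacoupling_invalid_parameter")
    }
    if (is.list(defaults[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(defaults[[nm]]))
      if (length(bad)) {
        rlang::abort(sprintf("Unknown config key '%s.%s'.", nm, bad[1]),
          class = "cacoupling_invalid_parameter")
      }
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param path Path to a YAML file of overrides.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# per-interval edge trim in samples: filter transient + cone of influence
interval_trim <- function(interval, edge_trim, fs) {
  iv <- get_interval(interval)
  round(max(edge_trim, coi_trim(iv$f_min)) * fs)
}

#' Analyse one subject end-to-end
#'
#' Runs the full single-subject pipeline: ABP -> beat-wise MAP -> 10 Hz
#' cleaned/normalized MAP; despiked, filtered, normalized HbO2 channels;
#' Morlet band phases in the four frequency intervals; time-evolving
#' dynamical Bayesian inference per channel/interval in both directions;
#' coupling strength with surrogate significance; and the reconstructed
#' MAP -> HbO2 coupling surface per cell.
#'
#' @param abp A [raw_signal()] ABP waveform (or path to its CSV).
#' @param hbo2 Wide tibble (`time`, `ch01`, ...) of HbO2 channels at 10 Hz
#'   (or path to its CSV).
#' @param config A [pipeline_config()].
#' @param subject Subject identifier stored in the output tables.
#' @return List of class `subject_result`: `cs` (tidy tibble: `subject`,
#'   `channel`, `interval`, `direction`, `sigma`, `significant`,
#'   `surrogate_mean`, `surrogate_sd`, `threshold`, `dominant`), `surfaces`
#'   (list `[[channel]][[interval]]` of MAP -> HbO2 `coupling_surface`),
#'   `map_signal`, `provenance`.
#' @export
run_subject <- function(abp, hbo2, config = pipeline_config(), subject = "S1") {
  if (is.character(abp)) abp <- read_signal_csv(abp, units = "mmHg", label = "abp")
  if (is.character(hbo2)) hbo2 <- read_signal_csv(hbo2)
  pc <- config$preprocess
  fs <- pc$target_fs
  ch_names <- setdiff(names(hbo2), "time")
  n_ch <- length(ch_names)
  if (n_ch != config$channels$n) {
    msg <- sprintf("Expected %d channels, found %d.", config$channels$n, n_ch)
    if (isTRUE(config$channels$strict)) {
      rlang::abort(msg, class = "cacoupling_invalid_parameter")
    }
    rlang::warn(paste(msg, "Proceeding (lenient mode)."))
  }
  map10 <- preprocess_abp(abp, target_fs = fs, config = pc)
  # overlap of the MAP grid (starts at the first beat) and the NIRS grid
  t0 <- max(map10$time[1], hbo2$time[1])
  t1 <- min(map10$time[nrow(map10)], hbo2$time[nrow(hbo2)])
  if (t1 - t0 < config$min_duration) {
    rlang::abort(sprintf("Only %.0f usable seconds (< %d).", t1 - t0,
                         config$min_duration),
      class = "cacoupling_insufficient_data")
  }
  crop <- function(tt) which(tt >= t0 - 1e-9 & tt <= t1 + 1e-9)
  im <- crop(map10$time)
  ih <- crop(hbo2$time)
  n <- min(length(im), length(ih))
  im <- im[seq_len(n)]
  ih <- ih[seq_len(n)]
  map_sig <- raw_signal(map10$value[im], fs = fs, start = map10$time[im[1]],
                        units = "", label = "map")
  map_ph <- band_phases(map_sig, config$wavelet$voices_per_octave)
  ivs <- frequency_intervals()$interval
  dir_labels <- c("1->2" = "map->hbo2", "2->1" = "hbo2->map")
  basis <- build_basis(config$dbi$K)
  results <- purrr::map(seq_along(ch_names), function(ci) {
    sig <- raw_signal(hbo2[[ch_names[ci]]][ih], fs = fs,
                      start = hbo2$time[ih[1]], units = "", label = ch_names[ci])
    sig <- preprocess_hbo2(sig, config = pc)
    ph <- band_phases(sig, config$wavelet$voices_per_octave)
    per_iv <- purrr::map(ivs, function(iv) {
      trim <- interval_trim(iv, pc$edge_trim, fs)
      idx <- (trim + 1):(n - trim)
      pair <- phase_pair(map_ph[[iv]]$phase[idx], ph[[iv]]$phase[idx],
                         fs = fs, labels = c("map", "hbo2"))
      # CS estimation uses half-record windows: within-band pairs are
      # typically phase-locked, and only long windows accumulate enough
      # phase-difference exploration for the K=2 basis to be identifiable;
      # short windows both starve the coupled-cell estimate and inflate the
      # null-cell estimator variance, making CS magnitudes incomparable
      # across cells
      win_iv <- max(config$dbi$window, floor(length(idx) / fs / 2))
      models <- suppressMessages(suppressWarnings(
        infer_time_evolving(pair, basis,
          window = win_iv, propagation = config$dbi$propagation)
      ))
      cells <- purrr::map_dfr(c("1->2", "2->1"), function(dr) {
        cs <- coupling_strength(models, dr,
                                include_self = config$dbi$include_self,
                                burn_in = 1)
        ens <- surrogate_ensemble(pair, dr, basis,
          n_surrogates = config$surrogate$n,
          seed = config$surrogate$seed + 131 * ci + match(iv, ivs),
          window = win_iv, propagation = config$dbi$propagation,
          burn_in = 1, min_offset = config$surrogate$min_offset
        )
        dplyr::mutate(
          significance(cs$sigma, ens),
          direction = dir_labels[[dr]], .before = 1
        )
      })
      cells <- dplyr::mutate(cells,
        channel = ci, interval = iv, .before = 1,
        dominant = dominant_direction(
          tibble::tibble(direction = cells$direction,
                         significant = cells$significant))
      )
      list(cs = cells, surface = evaluate_surface(models, "1->2"))
    })
    list(
      cs = purrr::map_dfr(per_iv, "cs"),
      surfaces = stats::setNames(purrr::map(per_iv, "surface"), ivs)
    )
  })
  cs <- dplyr::mutate(purrr::map_dfr(results, "cs"), subject = subject, .before = 1)
  structure(
    list(
      cs = cs,
      surfaces = purrr::map(results, "surfaces"),
      map_signal = map_sig,
      provenance = list(
        subject = subject, config_hash = rlang::hash(unclass(config)),
        surrogate_seed = config$surrogate$seed, n_channels = n_ch,
        usable_seconds = t1 - t0
      )
    ),
    class = "subject_result"
  )
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf(
    "<subject_result> %s: %d channels, %d CS records (%d significant)\n",
    x$provenance$subject, length(x$surfaces), nrow(x$cs), sum(x$cs$significant)
  ))
  invisible(x)
}

#' Cohort-level statistics
#'
#' Combines per-subject CS tables, runs the channel-wise ANOVA of the
#' MAP -> HbO2 coupling strength against the reference group, the paired
#' affected-vs-unaffected hemispheric tests, and (when surfaces are given)
#' group-averaged region surfaces.
#'
#' @param cs_table Combined tidy CS table (rows from `subject_result$cs`, or
#'   any tibble with `subject`, `channel`, `interval`, `direction`, `sigma`).
#' @param manifest Tibble with columns `subject`, `group` and optionally
#'   `affected_side` (`"L"`/`"R"` hemiparetic side; the affected hemisphere
#'   is contralateral). Every analysed subject must carry a group label.
#' @param surfaces Optional named list (by subject) of per-channel surface
#'   lists, as in `subject_result$surfaces`.
#' @param map A [channel_region_map()].
#' @param config A [pipeline_config()] (significance level and family size).
#' @return List of class `cohort_result`: `anova` (channel-wise tibble),
#'   `hemispheric` (paired-test tibble or `NULL`), `region_surfaces`
#'   (per group, or `NULL`), `threshold`.
#' @export
run_cohort <- function(cs_table, manifest, surfaces = NULL,
                       map = channel_region_map(), config = pipeline_config()) {
  if (!all(c("subject", "group") %in% names(manifest)) ||
      any(is.na(manifest$group))) {
    bad <- manifest$subject[is.na(manifest$group)]
    rlang::abort(sprintf("Manifest missing group label for subject(s): %s",
                         paste(bad, collapse = ", ")),
      class = "cacoupling_invalid_parameter")
  }
  missing_sub <- setdiff(unique(cs_table$subject), manifest$subject)
  if (length(missing_sub)) {
    rlang::abort(sprintf("Subject(s) not in manifest: %s",
                         paste(missing_sub, collapse = ", ")),
      class = "cacoupling_invalid_parameter")
  }
  if ("direction" %in% names(cs_table)) {
    cs_table <- cs_table[cs_table$direction == "map->hbo2", ]
  }
  cs <- dplyr::left_join(cs_table, manifest[, c("subject", "group")],
                         by = "subject")
  n_sub <- tapply(cs$subject, cs$group, function(s) length(unique(s)))
  small <- names(n_sub)[n_sub < 3]
  anova_tab <- NULL
  if (length(small)) {
    rlang::warn(sprintf("Group(s) with < 3 subjects, statistics skipped: %s",
                        paste(small, collapse = ", ")))
  } else {
    anova_tab <- channelwise_anova(cs,
      reference = config$stats$reference,
      alpha = config$stats$alpha, m = config$stats$m
    )
  }
  # region-wise CS per subject for the hemispheric tests
  hemi <- NULL
  if ("affected_side" %in% names(manifest) &&
      any(!is.na(manifest$affected_side))) {
    region_cs <- cs |>
      dplyr::left_join(tibble::as_tibble(map)[, c("channel", "region")],
                       by = "channel") |>
      dplyr::group_by(.data$subject, .data$region, .data$interval) |>
      dplyr::summarise(sigma = mean(.data$sigma), .groups = "drop")
    pat <- manifest[!is.na(manifest$affected_side), ]
    affected <- stats::setNames(
      ifelse(pat$affected_side == "L", "R", "L"), pat$subject
    )
    region_cs <- region_cs[region_cs$subject %in% names(affected), ]
    if (length(unique(region_cs$subject)) >= 2) {
      hemi <- hemispheric_paired_test(region_cs, affected)
    }
  }
  region_surf <- NULL
  if (!is.null(surfaces)) {
    groups <- stats::setNames(manifest$group, manifest$subject)
    region_surf <- purrr::map(split(names(surfaces), groups[names(surfaces)]),
      function(subs) {
        # per subject: 6 region surfaces per interval; then mean over subjects
        ivs <- names(surfaces[[subs[1]]][[1]])
        stats::setNames(purrr::map(ivs, function(iv) {
          per_sub <- purrr::map(subs, function(s) {
            region_average_surfaces(purrr::map(surfaces[[s]], iv), map)
          })
          regions <- names(per_sub[[1]])
          stats::setNames(purrr::map(regions, function(rg) {
            average_surfaces(purrr::map(per_sub, rg))
          }), regions)
        }), ivs)
      })
  }
  structure(
    list(
      anova = anova_tab, hemispheric = hemi, region_surfaces = region_surf,
      threshold = bonferroni_threshold(config$stats$alpha, config$stats$m)
    ),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n")
  if (!is.null(x$anova)) {
    cat(sprintf("  channel-wise ANOVA: %d cells, %d below threshold %.5g\n",
                nrow(x$anova), sum(x$anova$significant), x$threshold$threshold))
  }
  if (!is.null(x$hemispheric)) {
    cat(sprintf("  hemispheric paired tests: %d cells\n", nrow(x$hemispheric)))
  }
  invisible(x)
}
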