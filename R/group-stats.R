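#' Default channel-to-region map
#'
#' Maps the 24 NIRS channels to the six cortical regions -- left/right
#' prefrontal (LPFC, RPFC), parietal (LPL, RPL) and occipital (LOL, ROL) --
#' four consecutive channels per region, with the hemisphere taken from the
#' leading L/R. The true montage is study-specific, so analyses accept any
#' map of this shape; this symmetric default is validated strictly.
#'
#' @param mapping Optional tibble with columns `channel`, `region` overriding
#'   the default assignment.
#' @return Tibble of class `channel_region_map`: `channel` (1..24), `region`,
#'   `hemisphere` (`"L"`/`"R"`).
#' @export
channel_region_map <- function(mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- tibble::tibble(
      channel = 1:24,
      region = rep(c("LPFC", "RPFC", "LPL", "RPL", "LOL", "ROL"), each = 4)
    )
  }
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("channel", "region") %in% names(mapping)))
  if (anyDuplicated(mapping$channel)) {
    rlang::abort("Every channel must be mapped exactly once.",
      class = "cacoupling_invalid_parameter")
  }
  regions <- unique(mapping$region)
  if (!all(regions %in% c("LPFC", "RPFC", "LPL", "RPL", "LOL", "ROL")) ||
      length(regions) != 6L) {
    rlang::abort("Map must use exactly the 6 regions LPFC/RPFC/LPL/RPL/LOL/ROL.",
      class = "cacoupling_invalid_parameter")
  }
  mapping$hemisphere <- substr(mapping$region, 1, 1)
  structure(mapping, class = c("channel_region_map", class(mapping)))
}

#' Bonferroni-corrected significance threshold
#'
#' For the study family of 4 frequency intervals x 2 patient-vs-healthy
#' contrasts = 8 comparisons at alpha = 0.05 the corrected threshold is
#' 0.00625, conventionally reported as 0.006 at three decimals.
#'
#' @param alpha Family-wise error level (default 0.05).
#' @param m Number of comparisons (>= 1; default 8).
#' @return One-row tibble: `alpha`, `m`, `threshold`, `threshold_reported`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 8) {
  if (!is.numeric(m) || m < 1) {
    rlang::abort("`m` must be >= 1.", class = "cacoupling_invalid_parameter")
  }
  thr <- alpha / m
  tibble::tibble(
    alpha = alpha, m = as.integer(m),
    threshold = thr, threshold_reported = round(thr, 3)
  )
}

# two-group one-way ANOVA p-value with degenerate-variance handling
anova_p <- function(value, group) {
  if (stats::var(value) < 1e-300) return(1) # identical values in both groups
  gm <- tapply(value, group, mean)
  if (any(tapply(value, group, stats::var) < 1e-300) &&
      length(unique(signif(gm, 12))) == 1L) {
    return(1)
  }
  fit <- stats::oneway.test(value ~ group, var.equal = TRUE)
  p <- fit$p.value
  if (!is.finite(p)) p <- 1
  p
}

#' Channel-wise one-way ANOVA of coupling strength between groups
#'
#' For every (contrast, channel, interval) cell, a classical equal-variance
#' one-way ANOVA compares the per-subject CS of the reference (healthy)
#' group against one patient group, with group means and SDs reported
#' alongside. The Bonferroni family is 4 intervals x the number of contrasts.
#'
#' @param cs_table Tidy tibble with columns `subject`, `group`, `channel`,
#'   `interval`, `sigma` (one CS per subject/channel/interval, typically the
#'   significant MAP -> HbO2 direction).
#' @param reference Name of the control group (default `"healthy"`).
#' @param alpha Family-wise error level (default 0.05).
#' @param m Bonferroni family size; default 4 intervals x number of
#'   contrasts.
#' @return Tibble: `contrast`, `channel`, `interval`, `p_value`,
#'   `mean_<reference>`, `sd_..`, `n_..` per group, `threshold`,
#'   `significant`.
#' @export
channelwise_anova <- function(cs_table, reference = "healthy", alpha = 0.05,
                              m = NULL) {
  groups <- unique(cs_table$group)
  if (!reference %in% groups || length(groups) < 2) {
    rlang::abort("Need the reference group plus at least one other group.",
      class = "cacoupling_invalid_parameter")
  }
  others <- setdiff(groups, reference)
  n_sub <- tapply(cs_table$subject, cs_table$group,
                  function(s) length(unique(s)))
  if (any(n_sub < 3)) {
    rlang::abort("Every group needs at least 3 subjects.",
      class = "cacoupling_insufficient_data")
  }
  if (is.null(m)) m <- length(unique(cs_table$interval)) * length(others)
  thr <- bonferroni_threshold(alpha, m)$threshold
  cells <- tidyr::expand_grid(
    contrast = others,
    channel = sort(unique(cs_table$channel)),
    interval = unique(cs_table$interval)
  )
  purrr::pmap_dfr(cells, function(contrast, channel, interval) {
    sub <- cs_table[cs_table$channel == channel &
                      cs_table$interval == interval &
                      cs_table$group %in% c(reference, contrast), ]
    if (nrow(sub) == 0L || length(unique(sub$group)) < 2L) {
      rlang::abort(sprintf(
        "Missing data in cell (%s, channel %s, interval %s).",
        contrast, channel, interval
      ), class = "cacoupling_missing_data")
    }
    p <- anova_p(sub$sigma, factor(sub$group))
    ref <- sub$sigma[sub$group == reference]
    grp <- sub$sigma[sub$group == contrast]
    tibble::tibble(
      contrast = paste(reference, "vs", contrast),
      channel = channel, interval = interval, p_value = p,
      mean_ref = mean(ref), sd_ref = stats::sd(ref), n_ref = length(ref),
      mean_grp = mean(grp), sd_grp = stats::sd(grp), n_grp = length(grp),
      threshold = thr, significant = p < thr
    )
  })
}

#' Paired hemispheric comparison of region-wise coupling strength
#'
#' For each homologous region pair (PFC, PL, OL) and interval, a paired
#' Student t-test compares each subject's affected-hemisphere CS against the
#' unaffected hemisphere. The affected hemisphere is contralateral to the
#' hemiparetic side.
#'
#' @param region_cs Tibble with columns `subject`, `region`, `interval`,
#'   `sigma` (region-averaged CS per subject).
#' @param affected Named character vector or tibble (`subject`,
#'   `affected_hemisphere` `"L"`/`"R"`) giving each subject's affected
#'   hemisphere. Subjects without a label are excluded with a message.
#' @return Tibble: `region_pair`, `interval`, `n_pairs`, `mean_affected`,
#'   `mean_unaffected`, `p_value`.
#' @export
hemispheric_paired_test <- function(region_cs, affected) {
  if (is.data.frame(affected)) {
    affected <- stats::setNames(affected$affected_hemisphere, affected$subject)
  }
  known <- region_cs$subject %in% names(affected)
  if (any(!known)) {
    rlang::inform(sprintf(
      "Excluding %d unpaired subject(s): %s",
      length(unique(region_cs$subject[!known])),
      paste(unique(region_cs$subject[!known]), collapse = ", ")
    ))
    region_cs <- region_cs[known, ]
  }
  region_cs$side <- substr(region_cs$region, 1, 1)
  region_cs$base <- sub("^[LR]", "", region_cs$region)
  region_cs$status <- ifelse(
    region_cs$side == affected[region_cs$subject], "affected", "unaffected"
  )
  cells <- tidyr::expand_grid(
    base = unique(region_cs$base), interval = unique(region_cs$interval)
  )
  purrr::pmap_dfr(cells, function(base, interval) {
    sub <- region_cs[region_cs$base == base & region_cs$interval == interval, ]
    wide <- tidyr::pivot_wider(
      sub[, c("subject", "status", "sigma")],
      names_from = "status", values_from = "sigma"
    )
    wide <- wide[stats::complete.cases(wide), ]
    if (nrow(wide) < 2) {
      rlang::abort("Paired t-test needs at least 2 complete pairs.",
        class = "cacoupling_insufficient_data")
    }
    d <- wide$affected - wide$unaffected
    p <- if (stats::sd(d) < 1e-300) {
      1 # identical affected/unaffected values
    } else {
      stats::t.test(wide$affected, wide$unaffected, paired = TRUE)$p.value
    }
    tibble::tibble(
      region_pair = base, interval = interval, n_pairs = nrow(wide),
      mean_affected = mean(wide$affected),
      mean_unaffected = mean(wide$unaffected), p_value = p
    )
  })
}

#' Region-averaged coupling surfaces
#'
#' Element-wise mean of the 24 channel coupling surfaces within each of the
#' six cortical regions; group averages are element-wise means over subjects
#' of these region surfaces.
#'
#' @param surfaces Named or ordered list of 24 `coupling_surface` objects
#'   (channel 1..24), all on one grid.
#' @param map A [channel_region_map()].
#' @return Named list of 6 `coupling_surface` objects (one per region).
#' @export
region_average_surfaces <- function(surfaces, map = channel_region_map()) {
  missing_ch <- setdiff(map$channel, seq_along(surfaces))
  if (length(missing_ch) || length(surfaces) < max(map$channel)) {
    rlang::abort(sprintf(
      "Missing surface for channel(s): %s",
      paste(setdiff(map$channel, seq_along(surfaces)), collapse = ", ")
    ), class = "cacoupling_missing_data")
  }
  regions <- unique(map$region)
  out <- purrr::map(regions, function(rg) {
    ch <- map$channel[map$region == rg]
    average_surfaces(surfaces[ch])
  })
  stats::setNames(out, regions)
}
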