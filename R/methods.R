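#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an inferred coupling model
#'
#' One row per basis term and phase equation, with a readable term label.
#'
#' @param x A `coupling_model`.
#' @param ... Unused.
#' @return Tibble: `equation` (1 or 2, target oscillator), `term`, `k1`,
#'   `k2`, `func`, `estimate`.
#' @method tidy coupling_model
#' @export
tidy.coupling_model <- function(x, ...) {
  b <- x$basis
  lab <- ifelse(
    b$func == "const", "const",
    sprintf("%s(%+d phi1 %+d phi2)", b$func, b$k1, b$k2)
  )
  tidyr::expand_grid(equation = 1:2, idx = seq_len(nrow(b))) |>
    dplyr::mutate(
      term = lab[.data$idx], k1 = b$k1[.data$idx], k2 = b$k2[.data$idx],
      func = b$func[.data$idx],
      estimate = x$c[cbind(.data$idx, .data$equation)]
    ) |>
    dplyr::select(-"idx")
}

#' @rdname tidy.coupling_model
#' @method glance coupling_model
#' @export
glance.coupling_model <- function(x, ...) {
  tibble::tibble(
    K = attr(x$basis, "K"), n_params = nrow(x$basis), n_samples = x$n_samples,
    h = x$h, iterations = x$iterations, converged = x$converged,
    D11 = x$D[1, 1], D22 = x$D[2, 2], D12 = x$D[1, 2]
  )
}

#' Tidy a coupling surface
#'
#' @param x A `coupling_surface`.
#' @param ... Unused.
#' @return Long tibble: `phi_target`, `phi_source`, `q`.
#' @method tidy coupling_surface
#' @export
tidy.coupling_surface <- function(x, ...) {
  tidyr::expand_grid(
    phi_target = x$phi_target, phi_source = x$phi_source
  ) |>
    dplyr::mutate(q = as.vector(t(x$q)))
}

#' Plot a coupling surface
#'
#' Filled raster of the reconstructed coupling function
#' `q(phi_target, phi_source)` over one period in each phase.
#'
#' @param object A `coupling_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coupling_surface
#' @export
autoplot.coupling_surface <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$phi_source, .data$phi_target,
                                   fill = .data$q)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "q (rad/s)") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(
      x = expression(phi[source]), y = expression(phi[target]),
      title = sprintf("Coupling function (%s)", object$direction)
    )
}

#' Plot a raw signal
#'
#' @param object A `raw_signal`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot raw_signal
#' @export
autoplot.raw_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)",
      y = paste0(attr(object, "label"),
                 if (nzchar(attr(object, "units"))) {
                   paste0(" (", attr(object, "units"), ")")
                 } else ""),
      title = NULL
    )
}

#' Channel-wise coupling-strength profile plot
#'
#' Column plot of group mean +/- SD coupling strength per channel, faceted by
#' frequency interval: the cohort-level summary figure of the analysis.
#'
#' @param cs_table Tidy CS tibble with columns `channel`, `interval`, `sigma`
#'   and optionally `group`.
#' @param direction Direction to display (default `"map->hbo2"`).
#' @return A ggplot.
#' @export
plot_cs_profile <- function(cs_table, direction = "map->hbo2") {
  if ("direction" %in% names(cs_table)) {
    cs_table <- cs_table[cs_table$direction == direction, ]
  }
  if (!"group" %in% names(cs_table)) cs_table$group <- "all"
  df <- cs_table |>
    dplyr::group_by(.data$group, .data$channel, .data$interval) |>
    dplyr::summarise(
      mean = mean(.data$sigma), sd = stats::sd(.data$sigma), .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$channel), .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25,
      linewidth = 0.3
    ) +
    ggplot2::facet_wrap(~interval, scales = "free_y") +
    ggplot2::labs(x = "channel", y = expression(sigma ~ "(coupling strength)"))
}

#' Write a tidy CS table as TSV
#'
#' @param cs_table Tidy CS tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cs_tsv <- function(cs_table, path) {
  utils::write.table(cs_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
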