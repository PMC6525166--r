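#' Plot a spectral library
#'
#' One panel per component, intensity vs wavenumber.
#'
#' @param object A `spectral_library`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_library <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot concentration-time profiles of a concentration field
#'
#' Per-time line mean of each component's fraction — the concentration
#' profile view of a dehydration run.
#'
#' @param object A `conc_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conc_field <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::summarise(fraction = mean(.data$fraction),
                     .by = c("time", "component"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$fraction,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an MCR fit
#'
#' @param object An `mcr_fit`.
#' @param what `"concentrations"` (profiles vs observation), `"spectra"`
#'   (resolved spectra) or `"lof"` (convergence trace).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcr_fit <- function(object, what = c("concentrations", "spectra", "lof"),
                             ...) {
  what <- match.arg(what)
  df <- tidy(object, what = what)
  if (what == "concentrations") {
    ggplot2::ggplot(df, ggplot2::aes(.data$observation, .data$fraction,
                                     colour = .data$component)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Observation (time order)", y = "Fraction",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else if (what == "spectra") {
    ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~component, ncol = 1) +
      ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                    y = "Intensity (a.u.)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$lof)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Iteration", y = "Lack of fit (%)") +
      ggplot2::theme_minimal()
  }
}

#' Plot a chemical map
#'
#' Position-time heat map per component.
#'
#' @param object A `chemical_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chemical_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$time,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "Position (mm)", y = "Time (min)",
                  fill = if (object$closure) "Fraction" else "Coefficient") +
    ggplot2::theme_minimal()
}

#' Plot an area map
#'
#' @param object An `area_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.area_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m)),
                  fill = "Value") +
    ggplot2::theme_minimal()
}

#' Stacked area plot of metastable series
#'
#' @param series Tibble from [metastable_area_plot()].
#' @return A ggplot.
#' @export
plot_area_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(.data$time, .data$fraction,
                                       fill = .data$component)) +
    ggplot2::geom_area(position = "stack", alpha = 0.8) +
    ggplot2::labs(x = "Time (min)", y = "Fraction", fill = NULL) +
    ggplot2::theme_minimal()
}
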