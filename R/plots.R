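#' @export
autoplot.saxs_curve <- function(object, ..., log_y = TRUE) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q,
                                            y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(q ~ (ring(A)^{-1})),
                  y = "intensity (a.u.)")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.raman_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavenumber,
                                       y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("wavenumber" ~ (cm^{-1})),
                  y = "intensity (a.u.)")
}

#' Plot helpers for depot maps, profiles and trajectories
#'
#' `autoplot()` methods render the package's result objects with
#' ggplot2: phase maps as rasters of the cubic-phase fraction (or
#' lattice parameter with `fill = "lattice_a"`), radial profiles as
#' fraction/lattice versus radius, and transport trajectories as
#' composition fields over radius faceted by time.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @param fill For `phase_map`: `"fraction"` or `"lattice_a"`.
#' @param log_y For `saxs_curve`: logarithmic intensity axis.
#' @return A ggplot object.
#' @name depotmap-autoplot
NULL

#' @rdname depotmap-autoplot
#' @export
autoplot.phase_map <- function(object, ..., fill = "fraction") {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     value = ifelse(.data$mask, .data[[fill]], NA_real_))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pixel_x_mm,
                                  y = .data$pixel_y_mm,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(option = "cividis", na.value = "grey15") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = fill)
}

#' @rdname depotmap-autoplot
#' @export
autoplot.radial_profile <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("mean_fraction", "mean_lattice_a"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_mid_mm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "radius (mm)", y = NULL)
}

#' @rdname depotmap-autoplot
#' @export
autoplot.depot_trajectory <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("c_water", "c_spc", "c_gdo"),
    names_to = "species", values_to = "fraction")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_mm, y = .data$fraction,
                                  colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~round(.data$time_days, 2)) +
    ggplot2::labs(x = "radius (mm)", y = "mass fraction",
                  colour = NULL)
}
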