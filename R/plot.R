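#' Plot a composition field
#'
#' Heatmap of a field (e.g. \eqn{\phi_h}) inside the nucleus mask.
#'
#' @param field Matrix on the geometry grid.
#' @param geom A [nucleus_geometry()].
#' @param name Fill legend title.
#' @return A ggplot object.
#' @export
plot_field <- function(field, geom, name = "phi_h") {
  df <- field_to_df(field, geom)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = name) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

field_to_df <- function(field, geom) {
  idx <- which(geom$mask, arr.ind = TRUE)
  tibble::tibble(x = idx[, 1] * geom$spacing, y = idx[, 2] * geom$spacing,
                 value = field[idx])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of the heterochromatin fraction of a state
#'
#' @param object A [field_state()].
#' @param geom A [nucleus_geometry()] (required).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.field_state <- function(object, geom, ...) {
  plot_field(derived_fractions(object)$phi_h, geom) +
    ggplot2::ggtitle(sprintf("t = %.1f", object$time))
}

#' Energy and mass series of a trajectory
#'
#' @param object A `chrom_trajectory`.
#' @param ... Unused.
#' @return A ggplot object (free energy and mean heterochromatin mass over
#'   time, free y scales).
#' @export
autoplot.chrom_trajectory <- function(object, ...) {
  s <- object$series
  df <- dplyr::bind_rows(
    tibble::tibble(time = s$time, value = s$energy, what = "free energy"),
    tibble::tibble(time = s$time, value = s$mass_phi_h,
                   what = "heterochromatin mass"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "rescaled time", y = NULL) +
    ggplot2::theme_minimal()
}

#' Domain-size distributions of scenario results
#'
#' Box plots of interior domain radii (and LAD thickness samples when
#' present) across conditions, the standard summary of a scenario battery.
#'
#' @param object A named list of `scenario_result`s.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_scenario_sizes <- function(object, ...) {
  rows <- dplyr::bind_rows(lapply(object, function(r) dplyr::bind_rows(
    tibble::tibble(condition = r$name, measure = "interior radius",
                   value = r$interior_radii),
    tibble::tibble(condition = r$name, measure = "LAD thickness",
                   value = r$lad_thickness))))
  rows$condition <- factor(rows$condition, levels = names(object))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "rescaled length") +
    ggplot2::theme_minimal()
}

#' Theory curves: growth rate and relative sizes
#'
#' @param p A [chrom_params()].
#' @param R_max Upper radius for the growth-rate curve.
#' @return A ggplot object of \eqn{dR/dt} versus \eqn{R} with the stable
#'   radius marked.
#' @export
plot_growth_rate <- function(p, R_max = NULL) {
  Rss <- steady_radius(p)
  if (is.null(R_max)) R_max <- 2 * Rss + 0.5
  R <- seq(R_max / 400, R_max, length.out = 400)
  df <- tibble::tibble(R = R, rate = droplet_growth_rate(R, p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$rate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tibble::tibble(R = Rss, rate = 0),
                        colour = "red", size = 2) +
    ggplot2::coord_cartesian(ylim = c(-1, 2) * min(2, max(abs(df$rate)))) +
    ggplot2::labs(x = "droplet radius (rescaled)", y = "dR/dt") +
    ggplot2::theme_minimal()
}

#' @rdname plot_growth_rate
#' @param gamma_a_grid Extrusion-rate grid for [relative_size_curves()].
#' @export
plot_relative_sizes <- function(p, gamma_a_grid = seq(0, 4, by = 0.1)) {
  cur <- relative_size_curves(p, gamma_a_grid)
  df <- dplyr::bind_rows(
    tibble::tibble(Gamma_a = cur$Gamma_a, value = cur$relative_radius,
                   what = "relative radius"),
    tibble::tibble(Gamma_a = cur$Gamma_a, value = cur$relative_lad_thickness,
                   what = "relative LAD thickness"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Gamma_a, y = .data$value,
                                   colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "extrusion rate", y = "size relative to no extrusion",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
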