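#' Composition state of the nucleus
#'
#' A state holds the nucleoplasm volume fraction \eqn{\phi_n} and the
#' chromatin order parameter \eqn{\phi_d = \phi_h - \phi_e} as full-grid
#' matrices (NA outside the mask). The three constituents are space filling,
#' so \eqn{\phi_h = (1 - \phi_n + \phi_d)/2} and
#' \eqn{\phi_e = (1 - \phi_n - \phi_d)/2} close to unity pointwise by
#' construction.
#'
#' @param phi_n,phi_d Matrices on the geometry grid.
#' @param geom A [nucleus_geometry()].
#' @param time Rescaled time, >= 0.
#' @return A `field_state`.
#' @export
field_state <- function(phi_n, phi_d, geom, time = 0) {
  stopifnot(inherits(geom, "nucleus_geometry"),
            identical(dim(phi_n), dim(phi_d)),
            identical(dim(phi_n), as.integer(geom$grid_shape)) ||
              identical(dim(phi_n), geom$grid_shape),
            time >= 0)
  structure(list(phi_n = phi_n, phi_d = phi_d, time = time),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> t = %g, grid %d x %d\n",
              x$time, nrow(x$phi_n), ncol(x$phi_n)))
  invisible(x)
}

#' Heterochromatin and euchromatin fractions of a state
#'
#' Inverts the order-parameter definition: \eqn{\phi_h = (1-\phi_n+\phi_d)/2},
#' \eqn{\phi_e = (1-\phi_n-\phi_d)/2}. The sum with \eqn{\phi_n} is exactly 1
#' at every point.
#'
#' @param state A [field_state()].
#' @return List with matrices `phi_h` and `phi_e`.
#' @examples
#' g <- nucleus_geometry(radius = 1, spacing = 0.1)
#' s <- initialize_state(g, phi_n_bar = 0.5, phi_d_bar = 0, noise_amplitude = 0, seed = 1)
#' f <- derived_fractions(s)
#' stopifnot(all(abs(f$phi_h + f$phi_e + s$phi_n - 1) < 1e-15, na.rm = TRUE))
#' @export
derived_fractions <- function(state) {
  stopifnot(inherits(state, "field_state"),
            identical(dim(state$phi_n), dim(state$phi_d)))
  list(phi_h = (1 - state$phi_n + state$phi_d) / 2,
       phi_e = (1 - state$phi_n - state$phi_d) / 2)
}

#' Initial state: uniform composition plus smoothed heterogeneity
#'
#' \eqn{\phi_n} is uniform at `phi_n_bar`. \eqn{\phi_d} is `phi_d_bar` plus a
#' zero-mean random perturbation representing intrinsic intranuclear
#' heterogeneity. The perturbation is white noise smoothed with a Gaussian
#' kernel of physical width `noise_sigma`, rescaled to standard deviation
#' `noise_amplitude`; smoothing concentrates the perturbation at nucleation-
#' relevant wavelengths so compaction seeds are present at finite amplitude.
#' Identical seeds give bit-identical states.
#'
#' @param geom A [nucleus_geometry()].
#' @param phi_n_bar Mean nucleoplasm fraction.
#' @param phi_d_bar Mean order parameter; must satisfy
#'   `abs(phi_d_bar) <= 1 - phi_n_bar`.
#' @param noise_amplitude Standard deviation of the perturbation (0 gives an
#'   exactly uniform state).
#' @param seed Integer RNG seed.
#' @param noise_sigma Gaussian smoothing length of the perturbation, in
#'   rescaled length units.
#' @return A [field_state()] at time 0.
#' @export
initialize_state <- function(geom, phi_n_bar, phi_d_bar,
                             noise_amplitude = 0.45, seed = 1L,
                             noise_sigma = 0.4) {
  stopifnot(inherits(geom, "nucleus_geometry"),
            phi_n_bar > 0, phi_n_bar < 1,
            abs(phi_d_bar) <= 1 - phi_n_bar + 1e-12,
            noise_amplitude >= 0)
  n <- geom$grid_shape[1]
  pd_int <- rep(phi_d_bar, sum(geom$mask))
  if (noise_amplitude > 0) {
    set.seed(seed)
    z <- matrix(stats::rnorm(n * n), n, n)
    sigma_cells <- max(noise_sigma / geom$spacing, 0.5)
    zs <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(z), sigma = sigma_cells)))
    v <- zs[geom$mask]
    v <- v - mean(v)
    v <- v * (noise_amplitude / stats::sd(v))
    pd_int <- phi_d_bar + v
    lim <- 0.98 * (1 - phi_n_bar)
    n_clamped <- sum(pd_int > lim | pd_int < -lim)
    if (n_clamped > 0) {
      warning(sprintf("clamped %d cells where noise exceeded |phi_d| <= %.3f",
                      n_clamped, lim))
      pd_int <- pmax(pmin(pd_int, lim), -lim)
    }
  }
  field_state(field_from_interior(rep(phi_n_bar, sum(geom$mask)), geom),
              field_from_interior(pd_int, geom), geom, time = 0)
}
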