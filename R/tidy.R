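#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into its time series
#'
#' @param x A `chrom_trajectory`.
#' @param ... Unused.
#' @return The series tibble (time, energy, masses, steady indicator).
#' @export
tidy.chrom_trajectory <- function(x, ...) x$series

#' One-row trajectory summary
#'
#' @param x A `chrom_trajectory`.
#' @param ... Unused.
#' @return Tibble: final time, termination reason, final energy, relative
#'   nucleoplasm-mass drift, maximum fraction overshoot.
#' @export
glance.chrom_trajectory <- function(x, ...) {
  s <- x$series
  tibble::tibble(
    t_final = x$final$time,
    terminated_by = x$terminated_by,
    energy_final = s$energy[nrow(s)],
    mass_drift = abs(s$mass_phi_n[nrow(s)] - s$mass_phi_n[1]) /
      abs(s$mass_phi_n[1]),
    max_overshoot = max(s$overshoot, na.rm = TRUE))
}

#' @export
tidy.scenario_result <- function(x, ...) {
  tibble::as_tibble(x$domains)
}

#' @export
glance.scenario_result <- function(x, ...) {
  tibble::tibble(
    name = x$name, gamma_a = x$gamma_a, n_seeds = length(x$seeds),
    n_interior = length(x$interior_radii),
    mean_interior_radius = mean(x$interior_radii),
    n_lad_samples = length(x$lad_thickness),
    mean_lad_thickness = mean(x$lad_thickness))
}

#' @export
tidy.condition_comparison <- function(x, ...) tibble::as_tibble(x)
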