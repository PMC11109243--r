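#' Bulk free-energy density
#'
#' The local (gradient-free) part of the free energy at every interior point:
#' \deqn{W = \phi_e^2 + \phi_h^2(\phi_h^{max}-\phi_h)^2
#'       - V_L \phi_h e^{-d/d_0}.}
#' The first two terms are the Flory-Huggins-like double well with minima at
#' the euchromatin (\eqn{\phi_e = 0, \phi_h = 0}) and heterochromatin
#' (\eqn{\phi_e = 0, \phi_h = \phi_h^{max}}) compositions; the last is the
#' attractive chromatin-lamina interaction, active within \eqn{d_0} of the
#' nuclear boundary.
#'
#' @param state A [field_state()].
#' @param geom A [nucleus_geometry()].
#' @param p A [chrom_params()].
#' @return Matrix of energy densities (NA outside the mask).
#' @export
bulk_energy_density <- function(state, geom, p) {
  stopifnot(inherits(state, "field_state"), inherits(geom, "nucleus_geometry"),
            inherits(p, "chrom_params"),
            identical(dim(state$phi_n), dim(geom$mask)))
  f <- derived_fractions(state)
  f$phi_e^2 + f$phi_h^2 * (p$phi_h_max - f$phi_h)^2 -
    p$V_L * f$phi_h * exp(-geom$lamina_distance / p$d0)
}

## partial derivatives of the bulk density w.r.t. (phi_n, phi_d) via the
## chain rule through phi_h, phi_e:
## d(phi_h)/d(phi_n) = -1/2, d(phi_h)/d(phi_d) = +1/2,
## d(phi_e)/d(phi_n) = -1/2, d(phi_e)/d(phi_d) = -1/2.
bulk_energy_grad <- function(state, geom, p) {
  f <- derived_fractions(state)
  ## d/d(phi_h) of the double well
  gh <- 2 * f$phi_h * (p$phi_h_max - f$phi_h)^2 -
    2 * f$phi_h^2 * (p$phi_h_max - f$phi_h)
  lam <- p$V_L * exp(-geom$lamina_distance / p$d0)
  list(dn = -f$phi_e - gh / 2 + lam / 2,
       dd = -f$phi_e + gh / 2 - lam / 2)
}

#' Total discrete free energy
#'
#' Integral over the nucleus of the bulk density plus the interfacial energy
#' \eqn{(\delta^2/2)(|\nabla\phi_n|^2 + |\nabla\phi_d|^2)}, with the gradient
#' energy evaluated through the same masked no-flux Laplacian the solver
#' uses, so [chemical_potentials()] is its exact discrete functional
#' derivative.
#'
#' @inheritParams bulk_energy_density
#' @return A scalar (energy in rescaled units).
#' @export
total_free_energy <- function(state, geom, p) {
  w <- sum(bulk_energy_density(state, geom, p)[geom$mask])
  L <- geom$laplacian
  pn <- interior_values(state$phi_n, geom)
  pd <- interior_values(state$phi_d, geom)
  ## phi' (-L) phi is the discrete Dirichlet form sum over edges of
  ## (phi_i - phi_j)^2 / h^2
  grad <- -(sum(pn * as.vector(L %*% pn)) + sum(pd * as.vector(L %*% pd)))
  (w + (p$delta^2 / 2) * grad) * geom$spacing^2
}

#' Chemical potentials driving the diffusive fluxes
#'
#' Functional derivatives of the free energy with respect to the two
#' composition variables:
#' \eqn{\mu_{n,d} = \partial W/\partial\phi_{n,d} - \delta^2\nabla^2\phi_{n,d}},
#' with the Laplacian under no-flux conditions on the mask.
#'
#' @inheritParams bulk_energy_density
#' @return List of matrices `mu_n`, `mu_d` (NA outside the mask).
#' @export
chemical_potentials <- function(state, geom, p) {
  g <- bulk_energy_grad(state, geom, p)
  L <- geom$laplacian
  pn <- interior_values(state$phi_n, geom)
  pd <- interior_values(state$phi_d, geom)
  mu_n <- interior_values(g$dn, geom) - p$delta^2 * as.vector(L %*% pn)
  mu_d <- interior_values(g$dd, geom) - p$delta^2 * as.vector(L %*% pd)
  list(mu_n = field_from_interior(mu_n, geom),
       mu_d = field_from_interior(mu_d, geom))
}
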