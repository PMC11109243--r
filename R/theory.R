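#' Mean phase fractions set by the reaction kinetics
#'
#' Averaging the order-parameter kinetics at steady state gives the mean
#' heterochromatin and euchromatin content of the nucleus:
#' \deqn{\bar\phi_h = \frac{\Gamma_{me}(1-\bar\phi_n)}
#'        {\Gamma_{me} + 1 + \kappa\Gamma_a}, \qquad
#'       \bar\phi_e = \frac{(1+\kappa\Gamma_a)(1-\bar\phi_n)}
#'        {\Gamma_{me} + 1 + \kappa\Gamma_a},}
#' where \eqn{\kappa} folds the interface localization of the extrusion sink
#' into an effective bulk rate. The reactions, not the energetics, fix these
#' averages — the model's breaking of detailed balance.
#'
#' @param p A [chrom_params()].
#' @return Named list `phi_h_bar`, `phi_e_bar`.
#' @examples
#' mean_fractions(chrom_params(Gamma_me = 1, phi_n_bar = 0.5, Gamma_a = 0))
#' @export
mean_fractions <- function(p) {
  stopifnot(inherits(p, "chrom_params"))
  den <- p$Gamma_me + 1 + p$kappa * p$Gamma_a
  list(phi_h_bar = p$Gamma_me * (1 - p$phi_n_bar) / den,
       phi_e_bar = (1 + p$kappa * p$Gamma_a) * (1 - p$phi_n_bar) / den)
}

#' Sharp-interface growth rate of a heterochromatin droplet
#'
#' Balance of the reaction-diffusion influx of methylated material against
#' acetylation inside the droplet and extrusion at its surface:
#' \deqn{4\pi\tilde R^2 \frac{d\tilde R}{d\tilde t} =
#'   4\pi\tilde R\,\bar\phi_h - \tfrac{4}{3}\pi\tilde R^3\phi_h^{max}
#'   - 4\pi\tilde R^2\tfrac{\delta}{2}\Gamma_a\phi_h^{max},}
#' returned here as \eqn{d\tilde R/d\tilde t} (the printed balance divided
#' by \eqn{4\pi\tilde R^2}). As printed the rate diverges to \eqn{+\infty}
#' as \eqn{R \to 0^+} (influx dominates), so the smaller fixed point of the
#' printed form sits at 0; see [fixed_points()].
#'
#' @param R Droplet radius (rescaled length), > 0. Vectorized.
#' @param p A [chrom_params()].
#' @return Growth rate(s) \eqn{dR/dt}.
#' @export
droplet_growth_rate <- function(R, p) {
  stopifnot(all(R > 0))
  phb <- mean_fractions(p)$phi_h_bar
  (4 * pi * R * phb - (4 / 3) * pi * R^3 * p$phi_h_max -
     4 * pi * R^2 * (p$delta / 2) * p$Gamma_a * p$phi_h_max) / (4 * pi * R^2)
}

#' Fixed points of the droplet growth law
#'
#' All non-negative roots of [droplet_growth_rate()], found by bracketed
#' root-finding and classified by the sign structure of the growth rate:
#' the smaller root is critical (growth negative below it), the larger is
#' the stable steady radius. For the growth law as printed, growth is
#' positive as \eqn{R \to 0^+}, so the critical radius is 0 and the single
#' positive root equals [steady_radius()].
#'
#' @param p A [chrom_params()].
#' @return Named list `R_crit`, `R_ss` (numeric(0) if no positive root).
#' @export
fixed_points <- function(p) {
  f <- function(R) droplet_growth_rate(R, p)
  upper <- 2 * sqrt(3 * max(mean_fractions(p)$phi_h_bar, 1e-12) / p$phi_h_max) + 1
  if (mean_fractions(p)$phi_h_bar <= 0)
    return(list(R_crit = 0, R_ss = numeric(0)))
  ## growth is positive near 0+ and negative at large R: one sign change
  lo <- 1e-8
  if (f(lo) <= 0) return(list(R_crit = 0, R_ss = numeric(0)))
  root <- stats::uniroot(f, c(lo, upper), tol = 1e-14)$root
  list(R_crit = 0, R_ss = root)
}

#' Closed-form steady-state droplet radius
#'
#' \deqn{\tilde R_d^{ss} = -\frac{3\Gamma_a\delta}{4} +
#'   \sqrt{\Big(\frac{3\Gamma_a\delta}{4}\Big)^2 +
#'   \frac{3}{\phi_h^{max}}\,
#'   \frac{\Gamma_{me}(1-\bar\phi_n)}{1+\Gamma_{me}+\kappa\Gamma_a}}.}
#' Increasing methylation grows domains; increasing extrusion (or
#' acetylation) shrinks them.
#'
#' @param p A [chrom_params()].
#' @return Steady radius in rescaled length units.
#' @export
steady_radius <- function(p) {
  b <- 3 * p$Gamma_a * p$delta / 4
  c0 <- (3 / p$phi_h_max) * p$Gamma_me * (1 - p$phi_n_bar) /
    (1 + p$Gamma_me + p$kappa * p$Gamma_a)
  -b + sqrt(b^2 + c0)
}

#' Steady-state thickness of lamina-associated domains
#'
#' \deqn{\tilde x_t^{ss} =
#'   \frac{\Gamma_{me}(1-\bar\phi_n)}
#'        {\phi_h^{max}(1+\Gamma_{me}+\kappa\Gamma_a)} -
#'   \frac{\delta\,\Gamma_a}{2}.}
#' The raw value is returned; a negative value means no stable LAD layer.
#' Use `clip = TRUE` for the plotting accessor clipped at zero.
#'
#' @param p A [chrom_params()].
#' @param clip If `TRUE`, negative values are reported as 0.
#' @return Steady LAD thickness in rescaled length units.
#' @export
lad_thickness <- function(p, clip = FALSE) {
  x <- p$Gamma_me * (1 - p$phi_n_bar) /
    (p$phi_h_max * (1 + p$Gamma_me + p$kappa * p$Gamma_a)) -
    p$delta * p$Gamma_a / 2
  if (clip) pmax(x, 0) else x
}

#' Relative domain size and LAD thickness versus extrusion rate
#'
#' Evaluates [steady_radius()] and [lad_thickness()] on a grid of extrusion
#' rates and normalizes both by their value at \eqn{\Gamma_a = 0}.
#'
#' @param p_base A [chrom_params()]; its `Gamma_a` is replaced by each grid
#'   value.
#' @param gamma_a_grid Numeric vector of extrusion rates, >= 0.
#' @return A tibble with columns `Gamma_a`, `R_ss`, `lad_thickness`,
#'   `relative_radius`, `relative_lad_thickness`.
#' @export
relative_size_curves <- function(p_base, gamma_a_grid) {
  stopifnot(all(gamma_a_grid >= 0))
  p0 <- update_params(p_base, Gamma_a = 0)
  R0 <- steady_radius(p0)
  x0 <- lad_thickness(p0)
  rows <- lapply(gamma_a_grid, function(ga) {
    pg <- update_params(p_base, Gamma_a = ga)
    tibble::tibble(Gamma_a = ga,
                   R_ss = steady_radius(pg),
                   lad_thickness = lad_thickness(pg))
  })
  out <- dplyr::bind_rows(rows)
  out$relative_radius <- out$R_ss / R0
  out$relative_lad_thickness <- out$lad_thickness / x0
  out
}

#' Full set of sharp-interface predictions for a parameter set
#'
#' @param p A [chrom_params()].
#' @return A one-row tibble: mean fractions, critical and stable radius,
#'   steady LAD thickness.
#' @export
theory_prediction <- function(p) {
  mf <- mean_fractions(p)
  fp <- fixed_points(p)
  tibble::tibble(phi_h_bar = mf$phi_h_bar, phi_e_bar = mf$phi_e_bar,
                 R_crit = fp$R_crit,
                 R_ss = if (length(fp$R_ss)) fp$R_ss else NA_real_,
                 x_t_ss = lad_thickness(p))
}
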