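#' Model parameters for the chromatin phase-field model
#'
#' Bundles the dimensionless constants of the free-energy functional and the
#' reaction kinetics. Time is measured in units of the inverse histone-tail
#' acetylation rate; length in units of the reaction-diffusion length, so the
#' acetylation rate itself never appears as a number.
#'
#' @param phi_h_max Maximum heterochromatin volume fraction, in (0, 1].
#'   Location of the heterochromatin energy well.
#' @param V_L Rescaled chromatin-lamina affinity, >= 0. Strength of the
#'   attractive lamina term \eqn{-V_L \phi_h e^{-d/d_0}}.
#' @param d0 Decay length of the lamina interaction, rescaled length, > 0.
#' @param delta Interface-width parameter \eqn{\delta}, rescaled length, > 0.
#'   Controls the gradient-energy penalty \eqn{(\delta^2/2)|\nabla\phi|^2}.
#' @param Gamma_me Rescaled methylation rate, >= 0 (acetylation rate is 1 by
#'   the choice of time unit).
#' @param Gamma_a Rescaled supercoiling-driven loop-extrusion rate, >= 0.
#' @param delta_phi Width \eqn{\Delta\phi} (in volume-fraction units) of the
#'   Gaussian that localizes extrusion to the interface composition
#'   \eqn{\phi_h^{max}/2}, > 0.
#' @param kappa Surface-reaction geometry factor entering the mean-fraction
#'   and steady-size theory only, >= 0. Fitted from the interface average
#'   \eqn{\langle G\phi_h\rangle/\bar\phi_h} of a calibrated control run.
#' @param phi_n_bar Mean nucleoplasm volume fraction, in (0, 1). Conserved by
#'   the dynamics.
#'
#' @return An object of class `chrom_params` (a validated named list).
#' @examples
#' p <- chrom_params()
#' p$Gamma_a
#' @export
chrom_params <- function(phi_h_max = 0.8,
                         V_L = 0.08,
                         d0 = 0.4,
                         delta = 0.07,
                         Gamma_me = 1.0,
                         Gamma_a = 2.35,
                         delta_phi = 0.03,
                         kappa = 0.071,
                         phi_n_bar = 0.4) {
  p <- list(phi_h_max = phi_h_max, V_L = V_L, d0 = d0, delta = delta,
            Gamma_me = Gamma_me, Gamma_a = Gamma_a, delta_phi = delta_phi,
            kappa = kappa, phi_n_bar = phi_n_bar)
  validate_chrom_params(p)
  structure(p, class = "chrom_params")
}

validate_chrom_params <- function(p) {
  stopifnot(
    "phi_h_max must be in (0, 1]" = is.numeric(p$phi_h_max) &&
      p$phi_h_max > 0 && p$phi_h_max <= 1,
    "V_L must be >= 0"       = is.numeric(p$V_L) && p$V_L >= 0,
    "d0 must be > 0"         = is.numeric(p$d0) && p$d0 > 0,
    "delta must be > 0"      = is.numeric(p$delta) && p$delta > 0,
    "Gamma_me must be >= 0"  = is.numeric(p$Gamma_me) && p$Gamma_me >= 0,
    "Gamma_a must be >= 0"   = is.numeric(p$Gamma_a) && p$Gamma_a >= 0,
    "delta_phi must be > 0"  = is.numeric(p$delta_phi) && p$delta_phi > 0,
    "kappa must be >= 0"     = is.numeric(p$kappa) && p$kappa >= 0,
    "phi_n_bar must be in (0, 1)" = is.numeric(p$phi_n_bar) &&
      p$phi_n_bar > 0 && p$phi_n_bar < 1
  )
  invisible(p)
}

#' @export
print.chrom_params <- function(x, ...) {
  cat("<chrom_params>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Update a parameter set
#'
#' @param .data A `chrom_params` object.
#' @param ... Named fields to replace (e.g. `Gamma_a = 0`).
#' @return A new validated `chrom_params`.
#' @export
update_params <- function(.data, ...) {
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(.data)))
  .data[names(dots)] <- dots
  validate_chrom_params(.data)
  structure(.data, class = "chrom_params")
}

#' Cohesin/transcription decomposition of the extrusion rate
#'
#' The effective loop-extrusion rate factorizes into transcription-driven
#' supercoiling and net cohesin loading:
#' \eqn{\Gamma_a = \Gamma_{tr}(\Gamma_l - \Gamma_{ul})}.
#'
#' @param Gamma_tr Transcription/supercoiling rate, >= 0.
#' @param Gamma_l Cohesin loading rate, >= 0.
#' @param Gamma_ul Cohesin unloading rate, >= 0, at most `Gamma_l`.
#' @return An `extrusion_kinetics` object with derived field `Gamma_coh`.
#' @examples
#' effective_extrusion_rate(extrusion_kinetics(2, 3, 1)) # 4
#' @export
extrusion_kinetics <- function(Gamma_tr, Gamma_l, Gamma_ul) {
  stopifnot(Gamma_tr >= 0, Gamma_l >= 0, Gamma_ul >= 0,
            "Gamma_ul must not exceed Gamma_l" = Gamma_ul <= Gamma_l)
  structure(list(Gamma_tr = Gamma_tr, Gamma_l = Gamma_l, Gamma_ul = Gamma_ul,
                 Gamma_coh = Gamma_l - Gamma_ul),
            class = "extrusion_kinetics")
}

#' @rdname extrusion_kinetics
#' @param k An `extrusion_kinetics` object.
#' @export
effective_extrusion_rate <- function(k) {
  stopifnot(inherits(k, "extrusion_kinetics"))
  k$Gamma_tr * (k$Gamma_l - k$Gamma_ul)
}

#' Read or write model parameters as YAML
#'
#' Every field of [chrom_params()] is a top-level key. Unknown keys error.
#'
#' @param path File path of a YAML parameter file.
#' @return For `read_params`, a `chrom_params`.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(chrom_params))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown parameter keys: ", paste(bad, collapse = ", "))
  do.call(chrom_params, raw)
}

#' @rdname read_params
#' @param p A `chrom_params` object to write.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "chrom_params"))
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}
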