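#' Simulation configuration
#'
#' Controls the time integration. The integrator is a semi-implicit
#' (Eyre-stabilized) scheme: the stiff linear gradient-energy term is treated
#' implicitly through a cached sparse Cholesky factorization, the nonlinear
#' bulk derivative and the epigenetic reactions explicitly, and the
#' interface-localized extrusion sink by a pointwise exponential update.
#' A finer step `dt` is used up to `t_fine` (early reorganization), then
#' `dt_coarse`.
#'
#' @param dt Fine time step (rescaled units), > 0.
#' @param t_end Maximum integration time.
#' @param steady_tol Steady-state criterion: max pointwise
#'   `|d phi_d| / dt` below this stops the run.
#' @param noise_amplitude Initial perturbation amplitude (see
#'   [initialize_state()]).
#' @param seed Integer RNG seed for the initial state.
#' @param snapshot_every Interval between stored snapshots (`Inf` keeps only
#'   the final state).
#' @param dt_coarse Coarse step used after `t_fine`.
#' @param t_fine Time up to which the fine step is used.
#' @param gamma_a_on Time at which the extrusion sink is switched on. The
#'   scenario protocol lets the nucleus organize without extrusion first,
#'   mimicking a treatment applied to an already-organized nucleus; 0 applies
#'   extrusion from the start.
#' @param dt_active Optional step used once the extrusion sink is active
#'   (from `gamma_a_on` on); defaults to `dt_coarse`. The sink is the
#'   stiffest process, so treatment phases use a finer step.
#' @param s_stab Eyre stabilization constant (>= max curvature of the bulk
#'   energy along the fields; 2 is conservative).
#' @param reactions Logical; `FALSE` turns off all reaction terms (pure
#'   conserved gradient flow, used for coarsening controls).
#' @param steady_settle Minimum time after `gamma_a_on` before the steady
#'   criterion may fire.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(dt = 0.05, t_end = 130, steady_tol = 1e-5,
                              noise_amplitude = 0.45, seed = 1L,
                              snapshot_every = Inf, dt_coarse = 0.1,
                              t_fine = 10, gamma_a_on = 0, dt_active = NULL,
                              s_stab = 2, reactions = TRUE,
                              steady_settle = 20) {
  stopifnot(dt > 0, t_end > 0, steady_tol >= 0, snapshot_every > 0,
            dt_coarse >= dt, t_fine >= 0, gamma_a_on >= 0, s_stab >= 0,
            is.null(dt_active) || dt_active > 0)
  structure(list(dt = dt, t_end = t_end, steady_tol = steady_tol,
                 noise_amplitude = noise_amplitude, seed = seed,
                 snapshot_every = snapshot_every, dt_coarse = dt_coarse,
                 t_fine = t_fine, gamma_a_on = gamma_a_on,
                 dt_active = dt_active, s_stab = s_stab,
                 reactions = reactions, steady_settle = steady_settle),
            class = "simulation_config")
}

#' Reaction rate field of the order-parameter equation
#'
#' The non-conservative part of the \eqn{\phi_d} kinetics:
#' \deqn{2(\Gamma_{me}\phi_e - \phi_h)
#'   - 2\Gamma_a e^{-((\phi_h - \phi_h^{max}/2)/(2\Delta\phi))^2}\phi_h,}
#' i.e. methylation/acetylation interconversion plus the supercoiling-driven
#' extrusion sink, which the Gaussian factor restricts to a narrow
#' composition band around the domain-boundary value \eqn{\phi_h^{max}/2}.
#'
#' @param state A [field_state()].
#' @param p A [chrom_params()].
#' @return Matrix of rates (NA outside the mask).
#' @export
reaction_rate <- function(state, p) {
  stopifnot(inherits(state, "field_state"), inherits(p, "chrom_params"))
  f <- derived_fractions(state)
  G <- exp(-((f$phi_h - p$phi_h_max / 2) / (2 * p$delta_phi))^2)
  2 * (p$Gamma_me * f$phi_e - f$phi_h) - 2 * p$Gamma_a * G * f$phi_h
}

## ---- solver internals -----------------------------------------------------

.stepper_cache <- new.env(parent = emptyenv())

geom_uid <- function(geom) {
  uid <- attr(geom, "uid")
  if (is.null(uid)) {
    uid <- sprintf("g%dx%d_h%g_N%d", geom$grid_shape[1], geom$grid_shape[2],
                   geom$spacing, sum(geom$mask))
  }
  uid
}

## Cholesky factor of M = I - dt*s*L + dt*delta^2*L^2 (symmetric positive
## definite; M 1 = 1, so solves preserve the interior sum exactly)
get_stepper <- function(geom, p, dt, s_stab) {
  key <- sprintf("%s_dt%.6g_s%g_d%g", geom_uid(geom), dt, s_stab, p$delta)
  st <- .stepper_cache[[key]]
  if (is.null(st)) {
    L <- geom$laplacian
    M <- Matrix::Diagonal(nrow(L)) - (dt * s_stab) * L +
      (dt * p$delta^2) * (L %*% L)
    st <- list(chol = Matrix::Cholesky(Matrix::forceSymmetric(M)), dt = dt)
    if (length(ls(.stepper_cache)) > 16) # bound memory
      rm(list = ls(.stepper_cache)[1], envir = .stepper_cache)
    .stepper_cache[[key]] <- st
  }
  st
}

## one step on interior vectors; returns updated (pn, pd)
step_interior <- function(pn, pd, lam_half, geom, p, cfg, dt, gamma_a) {
  L <- geom$laplacian
  s <- cfg$s_stab
  ## (1) interface-localized extrusion sink, pointwise exponential update
  if (cfg$reactions && gamma_a > 0) {
    ph <- (1 - pn + pd) / 2
    G <- exp(-((ph - p$phi_h_max / 2) / (2 * p$delta_phi))^2)
    pd <- pd + 2 * (ph * exp(-gamma_a * G * dt) - ph)
  }
  ## (2) conserved diffusion of both fields + explicit epigenetic reactions
  ph <- (1 - pn + pd) / 2; pe <- (1 - pn - pd) / 2
  gh <- ph * (p$phi_h_max - ph)^2 - ph^2 * (p$phi_h_max - ph)
  dWn <- -pe - gh + lam_half
  dWd <- -pe + gh - lam_half
  R <- if (cfg$reactions) 2 * (p$Gamma_me * pe - ph) else 0
  st <- get_stepper(geom, p, dt, s)
  B <- cbind(pn + dt * as.vector(L %*% (dWn - s * pn)),
             pd + dt * (as.vector(L %*% (dWd - s * pd)) + R))
  X <- as.matrix(Matrix::solve(st$chol, B, system = "A"))
  list(pn = X[, 1], pd = X[, 2])
}

#' Advance the state by one time step
#'
#' One step of the coupled kinetics
#' \eqn{\partial\phi_n/\partial t = \nabla^2\mu_n} and
#' \eqn{\partial\phi_d/\partial t = \nabla^2\mu_d + R(\phi)} under no-flux
#' boundary conditions. The interior integral of \eqn{\phi_n} is conserved to
#' round-off; \eqn{\phi_d} changes only through the reaction terms.
#'
#' @param state A [field_state()].
#' @param geom A [nucleus_geometry()].
#' @param p A [chrom_params()].
#' @param cfg A [simulation_config()]; the step uses `cfg$dt`.
#' @return The advanced [field_state()].
#' @export
step_state <- function(state, geom, p, cfg = simulation_config()) {
  stopifnot(inherits(state, "field_state"))
  pn <- interior_values(state$phi_n, geom)
  pd <- interior_values(state$phi_d, geom)
  lam_half <- (p$V_L / 2) * exp(-interior_values(geom$lamina_distance, geom) / p$d0)
  ga <- if (state$time >= cfg$gamma_a_on) p$Gamma_a else 0
  out <- step_interior(pn, pd, lam_half, geom, p, cfg, cfg$dt, ga)
  if (anyNA(out$pd) || any(!is.finite(out$pd)) || any(!is.finite(out$pn)))
    stop("non-finite field values after step at t = ", state$time,
         "; diagnostic state returned in condition", call. = FALSE)
  field_state(field_from_interior(out$pn, geom),
              field_from_interior(out$pd, geom), geom,
              time = state$time + cfg$dt)
}

#' Integrate the kinetics to steady state
#'
#' Repeatedly advances the state, recording a time series of total free
#' energy, constituent masses and the steady-state indicator, plus optional
#' snapshots. Terminates when the pointwise change rate of \eqn{\phi_d} falls
#' below `cfg$steady_tol` (after a settling period) or at `cfg$t_end`,
#' whichever comes first.
#'
#' @param state Initial [field_state()] (see [initialize_state()]).
#' @param geom A [nucleus_geometry()].
#' @param p A [chrom_params()].
#' @param cfg A [simulation_config()].
#' @param checkpoint_at Optional time at which a copy of the state is stored
#'   (used by the scenario machinery to branch treatments from a shared
#'   organization phase).
#' @return A `chrom_trajectory`: list with `final` (state), `series`
#'   (tibble: time, energy, mass_phi_n, mass_phi_h, mass_phi_e, max_rate,
#'   overshoot), `snapshots`, `terminated_by` ("steady" or "t_end"), and
#'   `checkpoint` (state or NULL).
#' @export
evolve <- function(state, geom, p, cfg = simulation_config(),
                   checkpoint_at = NULL) {
  pn <- interior_values(state$phi_n, geom)
  pd <- interior_values(state$phi_d, geom)
  lam_half <- (p$V_L / 2) *
    exp(-interior_values(geom$lamina_distance, geom) / p$d0)
  h2 <- geom$spacing^2
  t <- state$time
  rows <- list(); snaps <- list(); checkpoint <- NULL
  next_snap <- if (is.finite(cfg$snapshot_every)) t else Inf
  terminated <- "t_end"
  record <- function(t, chg, pn, pd) {
    ph <- (1 - pn + pd) / 2; pe <- (1 - pn - pd) / 2
    st <- field_state(field_from_interior(pn, geom),
                      field_from_interior(pd, geom), geom, time = t)
    tibble::tibble(time = t,
                   energy = total_free_energy(st, geom, p),
                   mass_phi_n = sum(pn) * h2,
                   mass_phi_h = sum(ph) * h2,
                   mass_phi_e = sum(pe) * h2,
                   max_rate = chg,
                   overshoot = max(0, max(ph) - 1, max(pe) - 1, -min(ph), -min(pe)))
  }
  rows[[length(rows) + 1L]] <- record(t, NA_real_, pn, pd)
  repeat {
    if (t >= cfg$t_end - 1e-9) break
    dt <- if (t < cfg$t_fine) cfg$dt
          else if (!is.null(cfg$dt_active) && t >= cfg$gamma_a_on - 1e-9)
            cfg$dt_active
          else cfg$dt_coarse
    ga <- if (cfg$reactions && t >= cfg$gamma_a_on - 1e-9) p$Gamma_a else 0
    out <- step_interior(pn, pd, lam_half, geom, p, cfg, dt, ga)
    if (any(!is.finite(out$pd)) || any(!is.finite(out$pn))) {
      warning("non-finite values at t = ", t, "; stopping early")
      terminated <- "nonfinite"
      break
    }
    chg <- max(abs(out$pd - pd)) / dt
    pn <- out$pn; pd <- out$pd; t <- t + dt
    if (!is.null(checkpoint_at) && is.null(checkpoint) &&
        t >= checkpoint_at - 1e-9) {
      checkpoint <- field_state(field_from_interior(pn, geom),
                                field_from_interior(pd, geom), geom, time = t)
    }
    if (t >= next_snap - 1e-9) {
      rows[[length(rows) + 1L]] <- record(t, chg, pn, pd)
      snaps[[length(snaps) + 1L]] <-
        field_state(field_from_interior(pn, geom),
                    field_from_interior(pd, geom), geom, time = t)
      next_snap <- next_snap + cfg$snapshot_every
    }
    if (t > cfg$gamma_a_on + cfg$steady_settle && chg < cfg$steady_tol) {
      terminated <- "steady"
      break
    }
  }
  final <- field_state(field_from_interior(pn, geom),
                       field_from_interior(pd, geom), geom, time = t)
  rows[[length(rows) + 1L]] <- record(t, NA_real_, pn, pd)
  if (terminated == "t_end")
    message("evolve: reached t_end = ", cfg$t_end,
            " without meeting the steady criterion")
  structure(list(final = final, series = dplyr::bind_rows(rows),
                 snapshots = snaps, terminated_by = terminated,
                 checkpoint = checkpoint),
            class = "chrom_trajectory")
}

#' @export
print.chrom_trajectory <- function(x, ...) {
  cat(sprintf("<chrom_trajectory> %d series rows, %d snapshots, ended at t = %g (%s)\n",
              nrow(x$series), length(x$snapshots), x$final$time,
              x$terminated_by))
  invisible(x)
}
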