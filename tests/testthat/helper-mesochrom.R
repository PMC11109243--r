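## Shared small geometries, built once per test run
tiny_geom <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- nucleus_geometry(radius = 0.33, spacing = 0.05, pad = 2L)
    g
  }
})

small_geom <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- nucleus_geometry(radius = 1.5, spacing = 0.05)
    g
  }
})

quant_geom <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- nucleus_geometry(radius = 3, spacing = 0.05)
    g
  }
})

## random valid state on a geometry: fractions bounded away from limits
random_state <- function(geom, seed = 1, spread = 0.15) {
  set.seed(seed)
  n_int <- sum(geom$mask)
  pn <- 0.45 + stats::runif(n_int, -spread, spread)
  pd <- stats::runif(n_int, -spread, spread)
  field_state(mesochrom:::field_from_interior(pn, geom),
              mesochrom:::field_from_interior(pd, geom), geom)
}

## uniform state at a prescribed (phi_n, phi_h) composition
uniform_state <- function(geom, phi_n, phi_h) {
  phi_d <- 2 * phi_h - (1 - phi_n)
  initialize_state(geom, phi_n_bar = phi_n, phi_d_bar = phi_d,
                   noise_amplitude = 0, seed = 1)
}

## two unequal heterochromatin droplets in a nucleoplasm-rich background:
## the planted initial condition for coarsening (Ostwald) controls
two_droplet_state <- function(gg) {
  n <- gg$grid_shape[1]
  ii <- matrix(seq_len(n), n, n); jj <- t(ii); h <- gg$spacing
  d1 <- sqrt((ii - gg$center[1] - 0.45 / h)^2 + (jj - gg$center[2])^2) * h
  d2 <- sqrt((ii - gg$center[1] + 0.38 / h)^2 + (jj - gg$center[2])^2) * h
  inside <- d1 <= 0.3 | d2 <= 0.18
  phi_n0 <- matrix(0.7, n, n); phi_n0[inside] <- 0.2
  phi_h0 <- matrix(0.1, n, n); phi_h0[inside] <- 0.75
  phi_d0 <- 2 * phi_h0 - (1 - phi_n0)
  field_state(mesochrom:::field_from_interior(phi_n0[gg$mask], gg),
              mesochrom:::field_from_interior(phi_d0[gg$mask], gg), gg)
}

## independent total-energy oracle: explicit loops over cells and neighbour
## pairs (a second discretization of the same functional)
energy_oracle <- function(state, geom, p) {
  h <- geom$spacing
  mask <- geom$mask
  f <- derived_fractions(state)
  w <- 0
  n <- nrow(mask)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!mask[i, j]) next
    w <- w + f$phi_e[i, j]^2 +
      f$phi_h[i, j]^2 * (p$phi_h_max - f$phi_h[i, j])^2 -
      p$V_L * f$phi_h[i, j] * exp(-geom$lamina_distance[i, j] / p$d0)
  }
  grad <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!mask[i, j]) next
    if (i < n && mask[i + 1, j]) {
      grad <- grad + (state$phi_n[i + 1, j] - state$phi_n[i, j])^2 / h^2
      grad <- grad + (state$phi_d[i + 1, j] - state$phi_d[i, j])^2 / h^2
    }
    if (j < n && mask[i, j + 1]) {
      grad <- grad + (state$phi_n[i, j + 1] - state$phi_n[i, j])^2 / h^2
      grad <- grad + (state$phi_d[i, j + 1] - state$phi_d[i, j])^2 / h^2
    }
  }
  (w + (p$delta^2 / 2) * grad) * h^2
}
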