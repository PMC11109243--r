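test_that("composition algebra closes to unity and inverts the order parameter", {
  g <- tiny_geom()
  ## pure nucleoplasm
  s <- uniform_state(g, 1 - 1e-9, 0)
  f <- derived_fractions(s)
  expect_equal(max(abs(f$phi_h[g$mask])), 0, tolerance = 1e-8)
  ## symmetric split
  s <- uniform_state(g, 0.5, 0.25)
  f <- derived_fractions(s)
  expect_equal(f$phi_h[g$mask][1], 0.25)
  expect_equal(f$phi_e[g$mask][1], 0.25)
  ## direct inversion of phi_d = phi_h - phi_e with phi_h + phi_e = 1 - phi_n
  s <- uniform_state(g, 0.2, 0.6)
  f <- derived_fractions(s)
  expect_equal(f$phi_h[g$mask][1], 0.6)
  expect_equal(f$phi_e[g$mask][1], 0.2)
  ## closure is exact for arbitrary states
  for (seed in 1:5) {
    s <- random_state(g, seed)
    f <- derived_fractions(s)
    expect_equal(max(abs((f$phi_h + f$phi_e + s$phi_n - 1)[g$mask])), 0)
  }
})

test_that("bulk energy density matches hand evaluation and well structure", {
  g <- tiny_geom()
  p <- chrom_params(phi_h_max = 0.8, V_L = 0)
  ## euchromatin well: phi_e = 0, phi_h = 0
  w <- bulk_energy_density(uniform_state(g, 1 - 1e-12, 0), g, p)
  expect_equal(max(abs(w[g$mask])), 0, tolerance = 1e-10)
  ## heterochromatin well: phi_e = 0, phi_h = phi_h_max
  w <- bulk_energy_density(uniform_state(g, 1 - 0.8, 0.8), g, p)
  expect_equal(max(abs(w[g$mask])), 0, tolerance = 1e-12)
  ## hand evaluation of the printed polynomial:
  ## phi_e = 0.1, phi_h = 0.3 -> 0.01 + 0.09 * 0.25 = 0.0325
  s <- uniform_state(g, 0.6, 0.3)
  w <- bulk_energy_density(s, g, p)
  expect_equal(w[g$mask][1], 0.0325, tolerance = 1e-12)
  ## the lamina term is the only negative contribution
  pL <- chrom_params(V_L = 0.3)
  for (seed in 1:5) {
    w <- bulk_energy_density(random_state(g, seed), g, pL)
    expect_gte(min(w[g$mask]), -pL$V_L * pL$phi_h_max - 1e-12)
  }
})

test_that("both wells are stationary points of the bulk energy without lamina", {
  g <- tiny_geom()
  p <- chrom_params(V_L = 0)
  for (phi_h_well in c(0, p$phi_h_max)) {
    s <- uniform_state(g, 1 - phi_h_well - 1e-13, phi_h_well)
    gr <- mesochrom:::bulk_energy_grad(s, g, p)
    expect_equal(max(abs(gr$dn[g$mask])), 0, tolerance = 1e-10)
    expect_equal(max(abs(gr$dd[g$mask])), 0, tolerance = 1e-10)
  }
})

test_that("total free energy agrees with an independent quadrature oracle", {
  g <- tiny_geom()
  p <- chrom_params(V_L = 0.1)
  for (seed in 1:3) {
    s <- random_state(g, seed)
    expect_equal(total_free_energy(s, g, p), energy_oracle(s, g, p),
                 tolerance = 1e-10)
  }
  ## uniform state: energy = area x bulk density (gradients vanish)
  p0 <- chrom_params(V_L = 0)
  s <- uniform_state(g, 0.5, 0.2)
  area <- sum(g$mask) * g$spacing^2
  expect_equal(total_free_energy(s, g, p0),
               area * bulk_energy_density(s, g, p0)[g$mask][1],
               tolerance = 1e-12)
  ## gradient energy is quadratic in delta: doubling delta quadruples it
  s2 <- random_state(g, 9)
  e_bulk <- sum(bulk_energy_density(s2, g, p0)[g$mask]) * g$spacing^2
  e1 <- total_free_energy(s2, g, p0) - e_bulk
  p2 <- update_params(p0, delta = 2 * p0$delta)
  e2 <- total_free_energy(s2, g, p2) - e_bulk
  expect_equal(e2 / e1, 4, tolerance = 1e-10)
})

test_that("chemical potentials equal the numerical functional derivative", {
  g <- tiny_geom()   # 16x16-scale masked grid
  p <- chrom_params(V_L = 0.1)
  h2 <- g$spacing^2
  eps <- 1e-6
  for (seed in 1:2) {
    s <- random_state(g, seed)
    mu <- chemical_potentials(s, g, p)
    cells <- which(g$mask)
    ## probe a deterministic subset of cells (incl. boundary-adjacent ones)
    probe <- cells[seq(1, length(cells), by = 3)]
    for (ix in probe) {
      sp <- s; sp$phi_n[ix] <- sp$phi_n[ix] + eps
      sm <- s; sm$phi_n[ix] <- sm$phi_n[ix] - eps
      num <- (total_free_energy(sp, g, p) - total_free_energy(sm, g, p)) /
        (2 * eps * h2)
      expect_equal(mu$mu_n[ix], num, tolerance = 1e-5)
      sp <- s; sp$phi_d[ix] <- sp$phi_d[ix] + eps
      sm <- s; sm$phi_d[ix] <- sm$phi_d[ix] - eps
      num <- (total_free_energy(sp, g, p) - total_free_energy(sm, g, p)) /
        (2 * eps * h2)
      expect_equal(mu$mu_d[ix], num, tolerance = 1e-5)
    }
  }
})

test_that("the lamina term shifts mu_d by -V_L/2 exp(-d/d0) exactly", {
  g <- tiny_geom()
  s <- random_state(g, 4)
  p0 <- chrom_params(V_L = 0)
  pL <- chrom_params(V_L = 0.25)
  mu0 <- chemical_potentials(s, g, p0)
  muL <- chemical_potentials(s, g, pL)
  shift <- (muL$mu_d - mu0$mu_d)[g$mask]
  expected <- -(pL$V_L / 2) * exp(-g$lamina_distance[g$mask] / pL$d0)
  expect_equal(shift, expected, tolerance = 1e-12)
  ## uniform state at a well has spatially uniform potentials (V_L = 0)
  sw <- uniform_state(g, 1 - 0.8, 0.8)
  muw <- chemical_potentials(sw, g, p0)
  expect_lt(diff(range(muw$mu_d[g$mask])), 1e-10)
  expect_lt(diff(range(muw$mu_n[g$mask])), 1e-10)
})
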