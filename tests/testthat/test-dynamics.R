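test_that("initialization is deterministic with exact mean and optional silence", {
  g <- small_geom()
  s0 <- initialize_state(g, 0.4, -0.3, noise_amplitude = 0, seed = 1)
  expect_equal(stats::sd(s0$phi_d[g$mask]), 0)
  expect_equal(mean(s0$phi_d[g$mask]), -0.3)
  s1 <- initialize_state(g, 0.4, -0.3, noise_amplitude = 0.06, seed = 7)
  s2 <- initialize_state(g, 0.4, -0.3, noise_amplitude = 0.06, seed = 7)
  expect_identical(s1$phi_d, s2$phi_d)
  s3 <- initialize_state(g, 0.4, -0.3, noise_amplitude = 0.06, seed = 8)
  expect_false(identical(s1$phi_d, s3$phi_d))
  ## centred noise (below the clamp): the mask mean equals phi_d_bar exactly
  expect_equal(mean(s1$phi_d[g$mask]), -0.3, tolerance = 1e-12)
  ## excessive noise is clamped with a warning
  expect_warning(initialize_state(g, 0.4, 0, noise_amplitude = 0.8, seed = 1),
                 "clamped")
})

test_that("the reaction rate matches hand evaluation at key compositions", {
  g <- tiny_geom()
  p <- chrom_params(Gamma_me = 1.2, Gamma_a = 0.9, phi_h_max = 0.8,
                    delta_phi = 0.03)
  ## no substrate: phi_h = phi_e = 0
  s <- uniform_state(g, 1 - 1e-13, 0)
  expect_equal(max(abs(reaction_rate(s, p)[g$mask])), 0, tolerance = 1e-10)
  ## epigenetic balance point phi_e = phi_h / Gamma_me, extrusion off
  p0 <- update_params(p, Gamma_a = 0)
  phi_h <- 0.3; phi_e <- phi_h / p0$Gamma_me
  s <- uniform_state(g, 1 - phi_h - phi_e, phi_h)
  expect_equal(max(abs(reaction_rate(s, p0)[g$mask])), 0, tolerance = 1e-12)
  ## at the interface midpoint the Gaussian factor is exactly 1
  phi_h <- p$phi_h_max / 2
  s <- uniform_state(g, 0.35, phi_h)
  phi_e <- (1 - 0.35) - phi_h
  expected <- 2 * (p$Gamma_me * phi_e - phi_h) - 2 * p$Gamma_a * phi_h
  expect_equal(reaction_rate(s, p)[g$mask][1], expected, tolerance = 1e-12)
})

test_that("each step conserves nucleoplasm and budgets phi_d by the reactions", {
  g <- small_geom()
  p <- chrom_params(Gamma_a = 0)
  cfg <- simulation_config(dt = 0.05)
  s <- suppressWarnings(
    initialize_state(g, 0.4, -0.3, noise_amplitude = 0.3, seed = 2))
  mass_n <- sum(s$phi_n[g$mask])
  for (k in 1:20) {
    R_int <- sum(reaction_rate(s, p)[g$mask])
    sum_d <- sum(s$phi_d[g$mask])
    s2 <- step_state(s, g, p, cfg)
    expect_equal(sum(s2$phi_n[g$mask]), mass_n, tolerance = 1e-12)
    ## with the sink off, the phi_d budget is exactly dt * integral of R
    expect_equal(sum(s2$phi_d[g$mask]) - sum_d, cfg$dt * R_int,
                 tolerance = 1e-9)
    s <- s2
  }
})

test_that("a balanced uniform composition is a fixed point of the dynamics", {
  g <- small_geom()
  p <- chrom_params(Gamma_a = 0, V_L = 0, Gamma_me = 1)
  ## phi_e = phi_h: reaction zero; uniform: all gradients zero
  s <- uniform_state(g, 0.5, 0.25)
  s2 <- step_state(s, g, p, simulation_config(dt = 0.1))
  expect_equal(max(abs((s2$phi_d - s$phi_d)[g$mask])), 0, tolerance = 1e-12)
  expect_equal(max(abs((s2$phi_n - s$phi_n)[g$mask])), 0, tolerance = 1e-12)
})

test_that("mass conservation holds to 1e-8 over a full noisy run", {
  g <- small_geom()
  p <- chrom_params()
  cfg <- simulation_config(dt = 0.05, t_end = 20, gamma_a_on = 5,
                           dt_active = 0.05)
  s <- suppressWarnings(
    initialize_state(g, p$phi_n_bar, -0.3, noise_amplitude = 0.45, seed = 3))
  tr <- suppressMessages(evolve(s, g, p, cfg))
  drift <- abs(tr$series$mass_phi_n - tr$series$mass_phi_n[1]) /
    tr$series$mass_phi_n[1]
  expect_lt(max(drift), 1e-8)
  ## overshoot beyond physical fractions stays small
  expect_lt(max(tr$series$overshoot, na.rm = TRUE), 0.05)
})

test_that("with reactions off the dynamics is a gradient flow that ripens to one droplet", {
  ## two planted unequal droplets, conserved Cahn-Hilliard only
  g <- nucleus_geometry(radius = 1.1, spacing = 0.05)
  p <- chrom_params(V_L = 0, Gamma_a = 0, Gamma_me = 0)
  h <- g$spacing
  s <- two_droplet_state(g)
  cfg <- simulation_config(dt = 0.05, dt_coarse = 0.25, t_fine = 5,
                           t_end = 260, reactions = FALSE,
                           snapshot_every = 10, steady_tol = 1e-7)
  tr <- suppressMessages(evolve(s, g, p, cfg))
  ## free energy is non-increasing along the recorded series
  e <- tr$series$energy
  expect_true(all(diff(e) <= 1e-8 * abs(e[1])))
  ## Ostwald ripening: a single cluster remains
  phi_h <- derived_fractions(tr$final)$phi_h
  ds <- segment_domains(phi_h, g, threshold = 0.4, min_area = 4 * h^2)
  expect_identical(nrow(ds), 1L)
})

test_that("evolution is deterministic and stops on the steady criterion", {
  g <- small_geom()
  p <- chrom_params(Gamma_a = 0)
  cfg <- simulation_config(dt = 0.05, t_end = 15, steady_tol = 1e-4,
                           steady_settle = 1)
  s1 <- suppressWarnings(
    initialize_state(g, 0.5, -0.1, noise_amplitude = 0.3, seed = 11))
  tr1 <- suppressMessages(evolve(s1, g, p, cfg))
  tr2 <- suppressMessages(evolve(s1, g, p, cfg))
  expect_identical(tr1$final$phi_d, tr2$final$phi_d)
  ## a balanced uniform start terminates on the steady criterion at once
  p_bal <- chrom_params(Gamma_a = 0, V_L = 0, Gamma_me = 1)
  s0 <- uniform_state(g, 0.5, 0.25)
  tr0 <- evolve(s0, g, p_bal, simulation_config(dt = 0.05, t_end = 50,
                                                steady_settle = 1))
  expect_identical(tr0$terminated_by, "steady")
  expect_lt(tr0$final$time, 10)
})
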