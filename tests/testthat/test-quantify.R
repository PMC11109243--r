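test_that("segmentation recovers planted disks across the radius range", {
  g <- quant_geom()
  h <- g$spacing
  ## radii from a few cells up to tens of cells
  for (r_true in c(0.15, 0.3, 0.6, 1.0)) {
    n_disks <- if (r_true > 0.5) 2 else 5
    fx <- generate_fixture("disks", g, n = n_disks, radius = r_true,
                           seed = 10 + round(100 * r_true))
    ds <- segment_domains(fx$field, g, threshold = 0.4, min_area = 4 * h^2)
    expect_identical(nrow(ds), as.integer(n_disks))
    expect_true(all(abs(ds$eq_radius - r_true) <= 0.5 * h))
  }
  ## uniform field below the threshold: empty set, not an error
  empty <- segment_domains(matrix(0.1, g$grid_shape[1], g$grid_shape[2]),
                           g, threshold = 0.4)
  expect_identical(nrow(empty), 0L)
  ## segmentation is deterministic
  fx <- generate_fixture("disks", g, n = 5, radius = 0.3, noise = 0.05,
                         seed = 3)
  d1 <- segment_domains(fx$field, g, threshold = 0.4)
  d2 <- segment_domains(fx$field, g, threshold = 0.4)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  ## label image and table agree on total area
  lab <- attr(d1, "label_image")
  expect_equal(sum(d1$area), sum(lab > 0) * h^2)
  expect_lte(sum(d1$area), sum(g$mask) * h^2)
})

test_that("touching disks merge into one connected domain", {
  g <- quant_geom()
  fld <- matrix(0, g$grid_shape[1], g$grid_shape[2])
  ii <- matrix(seq_len(nrow(fld)), nrow(fld), ncol(fld)); jj <- t(ii)
  h <- g$spacing
  r_cells <- 0.3 / h
  d1 <- sqrt((ii - g$center[1] + r_cells)^2 + (jj - g$center[2])^2)
  d2 <- sqrt((ii - g$center[1] - r_cells + 1)^2 + (jj - g$center[2])^2)
  fld[d1 <= r_cells | d2 <= r_cells] <- 0.8
  fld[!g$mask] <- NA
  ds <- segment_domains(fld, g, threshold = 0.4)
  expect_identical(nrow(ds), 1L)
})

test_that("classification separates interior domains from LADs by distance", {
  g <- quant_geom()
  fx_disks <- generate_fixture("disks", g, n = 4, radius = 0.25, seed = 5,
                               margin = 0.5)
  fx_ring <- generate_fixture("annulus", g, width = 0.3)
  fld <- pmax(fx_disks$field, fx_ring$field, na.rm = TRUE)
  fld[!g$mask] <- NA
  ds <- segment_domains(fld, g, threshold = 0.4)
  expect_message(ds <- classify_domains(ds, g, lad_cutoff = 0.14),
                 "interior")
  expect_identical(sum(ds$klass == "interior"), 4L)
  expect_identical(sum(ds$klass == "LAD"), 1L)
  ## a disk at the center is interior; the ring touches the boundary
  center_disk <- generate_fixture("tanh_disk", g, radius = 0.4, width = 0.05)
  dsc <- suppressMessages(classify_domains(
    segment_domains(center_disk$field, g, threshold = 0.4), g))
  expect_identical(dsc$klass, "interior")
})

test_that("LAD thickness profile recovers a planted band width", {
  g <- quant_geom()
  for (w in c(0.2, 0.4)) {
    fx <- generate_fixture("annulus", g, width = w)
    ds <- suppressMessages(classify_domains(
      segment_domains(fx$field, g, threshold = 0.4), g))
    prof <- lad_thickness_profile(ds, fx$field, g)
    expect_gt(nrow(prof), 100)
    expect_lt(abs(attr(prof, "mean") - w), g$spacing)
  }
  ## no boundary-contiguous material: empty profile
  fx2 <- generate_fixture("disks", g, n = 3, radius = 0.25, seed = 2,
                          margin = 0.5)
  ds2 <- suppressMessages(classify_domains(
    segment_domains(fx2$field, g, threshold = 0.4), g))
  prof2 <- lad_thickness_profile(ds2, fx2$field, g)
  expect_identical(nrow(prof2), 0L)
})

test_that("radial profiles are flat for uniform fields and step at disk edges", {
  g <- quant_geom()
  uni <- matrix(0.3, g$grid_shape[1], g$grid_shape[2])
  prof <- radial_density_profile(uni, g, g$center, r_max = 2, n_annuli = 15)
  expect_lt(diff(range(prof$density)), 1e-12)
  ## sharp disk: profile falls from the plateau to 0 within one annulus of
  ## the planted radius
  fx <- generate_fixture("disks", g, n = 1, radius = 0.5, seed = 1)
  ds <- segment_domains(fx$field, g, threshold = 0.4)
  prof <- radial_density_profile(fx$field, g, c(ds$x[1], ds$y[1]),
                                 r_max = 1.2, n_annuli = 24)
  dr <- prof$r[2] - prof$r[1]
  inside <- prof$density[prof$r < 0.5 - dr]
  outside <- prof$density[prof$r > 0.5 + dr]
  expect_true(all(inside > 0.7))
  expect_true(all(outside < 0.1))
})

test_that("interface width recovers a programmed tanh profile", {
  g <- quant_geom()
  for (w in c(0.15, 0.3)) {
    fx <- generate_fixture("tanh_disk", g, radius = 0.8, width = w)
    ds <- suppressMessages(classify_domains(
      segment_domains(fx$field, g, threshold = 0.4), g))
    meas <- interface_width(fx$field, ds, g)
    ## the 80-20 descent of level/2*(1-tanh((r-R)/(w/2))) spans
    ## (w/2)*2*atanh(0.6) in radius
    expected <- w * atanh(0.6)
    expect_lt(abs(meas - expected) / expected, 0.15)
  }
  ## a sharp disk cannot measure wider than the resolution floor
  fx <- generate_fixture("disks", g, n = 1, radius = 0.8, seed = 1)
  ds <- suppressMessages(classify_domains(
    segment_domains(fx$field, g, threshold = 0.4), g))
  expect_lte(interface_width(fx$field, ds, g), 2 * g$spacing)
})

test_that("condition comparison reports calibrated ratios and Welch tests", {
  ## identical sets: unit ratio, p ~ 1
  x <- c(9.5, 10.2, 10.1, 9.9, 10.3)
  cmp <- compare_conditions(x, x)
  expect_equal(cmp$ratio, 1)
  expect_gt(cmp$p_value, 0.99)
  ## sampling oracle: Normal(10,1) vs Normal(12,1)
  set.seed(99)
  a <- stats::rnorm(100, 10, 1); b <- stats::rnorm(100, 12, 1)
  cmp2 <- compare_conditions(a, b)
  expect_equal(cmp2$ratio, 1.2, tolerance = 0.05)
  expect_lt(cmp2$p_value, 1e-6)
  ## ratio is invariant under a common rescaling
  cmp3 <- compare_conditions(3.7 * a, 3.7 * b)
  expect_equal(cmp3$ratio, cmp2$ratio, tolerance = 1e-12)
  expect_error(compare_conditions(numeric(0), b), "non-empty")
})

test_that("imported grayscale maps normalize to the unit interval", {
  m <- matrix(stats::runif(100, 40, 900), 10, 10)
  nm <- normalize_density_map(m)
  expect_equal(range(nm), c(0, 1))
  expect_equal(normalize_density_map(matrix(5, 3, 3)),
               matrix(0, 3, 3))
})
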