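test_that("local-deposition S-value is the energy/mass quotient", {
  # tumor sphere: 133.3 keV in 0.016 g
  s <- local_deposition_s(133.3, 0.016, "Tumors")
  expect_equal(s$s_gy_per_bq_s, 133.3 * 1.602176634e-16 / 1.6e-5)
  expect_equal(s$s_gy_per_bq_s, 1.3348e-9, tolerance = 1e-4)
  # liver-mass hand conversion
  s_liver <- local_deposition_s(133.3, 1.333)
  expect_equal(s_liver$s_gy_per_bq_s, 1.602e-11, tolerance = 1e-3)
  expect_error(local_deposition_s(0, 1), "positive")
  expect_error(local_deposition_s(100, -1), "positive")
})

test_that("local deposition bounds every tabulated organ S-value from above", {
  tab <- s_value_table()
  expect_equal(nrow(tab), 7)
  for (i in seq_len(nrow(tab))) {
    bound <- local_deposition_s(133.3, tab$ref_mass_g[i])$s_gy_per_bq_s
    expect_gte(bound, tab$s_gy_per_bq_s[i])
  }
})

test_that("sphere geometry keeps radius, mass and density consistent", {
  g <- sphere_geometry(mass_g = 0.016)
  expect_equal(g$radius_mm, 10 * (3 * 0.016 / (4 * pi))^(1 / 3))
  g2 <- sphere_geometry(radius_mm = 1.5)
  expect_equal(g2$mass_g, 4 / 3 * pi * 0.15^3, tolerance = 1e-12)
  # nominal 3 mm diameter with a measured 0.015 g: density is derived
  g3 <- sphere_geometry(radius_mm = 1.5, mass_g = 0.015)
  expect_equal(g3$density_g_per_cm3, 0.015 / (4 / 3 * pi * 0.15^3))
  # an explicitly inconsistent triple is rejected
  expect_error(sphere_geometry(radius_mm = 1.5, mass_g = 0.025,
                               density_g_per_cm3 = 1), "inconsistent")
})

test_that("absorbed fraction obeys its geometric limits", {
  g <- sphere_geometry(mass_g = 0.016)
  # zero track length: all energy deposited at the source point
  expect_equal(sphere_absorbed_fraction_mc(g, 0, 100, seed = 1)$phi, 1)
  expect_equal(sphere_absorbed_fraction_quad(g, 0), 1)
  # bounds and monotonicity in track length (quadrature route)
  lens <- c(0.05, 0.2, 1, 5, 50)
  phis <- vapply(lens, function(L) sphere_absorbed_fraction_quad(g, L), 0)
  expect_true(all(phis > 0 & phis <= 1))
  expect_true(all(diff(phis) < 0))
  # monotonically non-decreasing in radius at fixed track length
  radii <- c(1, 1.5, 3, 10)
  phir <- vapply(radii, function(r)
    sphere_absorbed_fraction_quad(sphere_geometry(radius_mm = r), 0.2), 0)
  expect_true(all(diff(phir) > 0))
})

test_that("Monte Carlo estimator agrees with the quadrature within 3 SE", {
  g <- sphere_geometry(mass_g = 0.016)
  for (L in c(0.2, 100 * g$radius_mm)) {
    mc <- sphere_absorbed_fraction_mc(g, L, n_histories = 2e5, seed = 9)
    phi_ref <- sphere_absorbed_fraction_quad(g, L)
    expect_lt(abs(mc$phi - phi_ref), 3 * mc$se)
  }
})

test_that("Monte Carlo estimator is seeded and converges as 1/sqrt(n)", {
  g <- sphere_geometry(mass_g = 0.016)
  a <- sphere_absorbed_fraction_mc(g, 0.2, 1e4, seed = 21)
  b <- sphere_absorbed_fraction_mc(g, 0.2, 1e4, seed = 21)
  expect_identical(a, b)
  c4 <- sphere_absorbed_fraction_mc(g, 0.2, 4e4, seed = 21)
  expect_equal(c4$se / a$se, 0.5, tolerance = 0.1)
})

test_that("Monte Carlo S-value reduces to the analytic limit and stays below it", {
  lu <- lu177()
  g <- sphere_geometry(mass_g = 0.016)
  local <- local_deposition_s(lu$mean_beta_energy_keV, g$mass_g)$s_gy_per_bq_s
  # zero range forces phi = 1, recovering the local-deposition limit
  pointlike <- nuclide_properties("Lu-177-pt", 6.65, 133.3, 498.3, 0)
  s_pt <- mc_s_value(g, pointlike, n_histories = 100, seed = 1)
  expect_equal(s_pt$s_gy_per_bq_s, local)
  # tumor sphere with the 0.2 mm mean range: a few percent of escape
  s_mc <- mc_s_value(g, lu, n_histories = 2e5, seed = 4)
  expect_gt(s_mc$s_gy_per_bq_s, 0.95 * local)
  expect_lt(s_mc$s_gy_per_bq_s, local)
  expect_equal(s_mc$provenance, "monte_carlo")
  # halving the mass at fixed absorbed fraction doubles S
  s_half <- local_deposition_s(133.3, 0.008)$s_gy_per_bq_s
  expect_equal(s_half, 2 * local)
})

test_that("spectrum-sampling mode gives a physical, seeded estimate", {
  lu <- lu177()
  g <- sphere_geometry(mass_g = 0.016)
  s1 <- mc_s_value(g, lu, n_histories = 5e4, seed = 6,
                   mode = "sampled_spectrum")
  s2 <- mc_s_value(g, lu, n_histories = 5e4, seed = 6,
                   mode = "sampled_spectrum")
  expect_identical(s1, s2)
  phi <- attr(s1, "phi")
  expect_true(phi > 0 && phi <= 1)
  # energy-weighted absorbed fraction cannot exceed the endpoint bound
  expect_lt(s1$s_gy_per_bq_s,
            local_deposition_s(lu$max_beta_energy_keV, g$mass_g)$s_gy_per_bq_s)
})

test_that("S-value CSV writer round-trips with provenance", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- s_value_table()
  write_s_values(tab, path, header_comment = "packaged table")
  back <- read_s_values(path)
  expect_equal(back$s_gy_per_bq_s, tab$s_gy_per_bq_s)
  expect_equal(back$provenance, rep("tabulated", 7))
})
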