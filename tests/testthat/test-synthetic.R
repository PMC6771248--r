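test_that("lognormal moment matching is exact", {
  # degenerate: sd 0
  p0 <- lognormal_params(5, 0)
  expect_equal(p0$sigma, 0)
  expect_equal(p0$mu, log(5))
  # closed form: mean 1, sd 1 -> sigma^2 = ln 2
  expect_equal(lognormal_params(1, 1)$sigma^2, log(2))
  # round trip on the reported tumor dispersion
  p <- lognormal_params(6.29, 4.27)
  expect_equal(exp(p$mu + p$sigma^2 / 2), 6.29)
  expect_equal(sqrt((exp(p$sigma^2) - 1) * exp(2 * p$mu + p$sigma^2)), 4.27)
  expect_error(lognormal_params(0, 1), "positive")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- default_cohort_config(n_mice = 4)
  expect_identical(generate_biodist_cohort(cfg, seed = 3),
                   generate_biodist_cohort(cfg, seed = 3))
  a <- generate_pci_cohort(cfg, seed = 3)
  b <- generate_pci_cohort(cfg, seed = 3)
  expect_identical(a, b)
  expect_identical(generate_growth_cohort(cfg, seed = 3),
                   generate_growth_cohort(cfg, seed = 3))
  # different seed, different draws
  expect_false(identical(generate_biodist_cohort(cfg, seed = 4),
                         generate_biodist_cohort(cfg, seed = 3)))
})

test_that("noiseless cohort round-trips through quantification exactly", {
  spec <- data.frame(organ = c("Tumors", "Blood"), time_h = 24,
                     mean_pct_ia_per_g = c(6.29, 0.22),
                     sd_pct_ia_per_g = 0,
                     mass_g_mean = c(0.016, 0.2), mass_g_sd = 0)
  cfg <- cohort_config(3, "Tz-2", spec, injected_MBq = 10,
                       counting_efficiency = 1)
  meas <- generate_biodist_cohort(cfg, seed = 1)
  rec <- as_pct_ia_per_g(meas, lu177())
  expect_equal(rec$pct_ia_per_g[rec$organ == "Tumors"], rep(6.29, 3))
  expect_equal(rec$pct_ia_per_g[rec$organ == "Blood"], rep(0.22, 3))
})

test_that("counting-efficiency emulation inverts when declared to the reader", {
  spec <- data.frame(organ = "Tumors", time_h = 24,
                     mean_pct_ia_per_g = 6.29, sd_pct_ia_per_g = 0,
                     mass_g_mean = 0.016, mass_g_sd = 0)
  cfg <- cohort_config(2, "Tz-2", spec, counting_efficiency = 0.35)
  meas <- generate_biodist_cohort(cfg, seed = 1)
  rec <- as_pct_ia_per_g(meas, lu177(), counting_efficiency = 0.35)
  expect_equal(rec$pct_ia_per_g, rep(6.29, 2))
})

test_that("large biodist cohort recovers the configured moments", {
  spec <- data.frame(organ = "Tumors", time_h = 24,
                     mean_pct_ia_per_g = 6.29, sd_pct_ia_per_g = 4.27,
                     mass_g_mean = 0.016, mass_g_sd = 0.0016)
  cfg <- cohort_config(4000, "Tz-2", spec)
  meas <- generate_biodist_cohort(cfg, seed = 2)
  rec <- as_pct_ia_per_g(meas, lu177())
  se <- 4.27 / sqrt(4000)
  expect_lt(abs(mean(rec$pct_ia_per_g) - 6.29), 3 * se)
  expect_true(all(rec$pct_ia_per_g > 0))
  expect_true(all(meas$mass_g > 0))
})

test_that("PCI generator hits its targets exactly per animal", {
  regions <- pci_regions()
  cfg <- cohort_config(1, "Tz-2",
                       data.frame(organ = "Tumors", time_h = 24,
                                  mean_pct_ia_per_g = 1, sd_pct_ia_per_g = 0,
                                  mass_g_mean = 0.016, mass_g_sd = 0),
                       pci_group_specs = data.frame(
                         group = c("max", "none"), mean = c(39, 0.01),
                         sd = 0, n = c(1L, 1L)))
  pc <- generate_pci_cohort(cfg, seed = 1)
  totals <- vapply(pc$maps, pci_total, 0L)
  expect_equal(unname(totals[pc$groups == "max"]), 39L)  # all regions at 3
  expect_true(all(pc$maps[[which(pc$groups == "max")]]$region_scores == 3))
  expect_equal(unname(totals[pc$groups == "none"]), 0L)
  # group means recovered on a larger cohort
  cfg2 <- default_cohort_config()
  pc2 <- generate_pci_cohort(cfg2, seed = 8, n_per_group = 400)
  s <- group_pci_summary(pc2$maps, pc2$groups)
  prit <- s[s$group == "PRIT", ]
  expect_lt(abs(prit$mean_pci - 15.5), 3 * 2.3 / sqrt(400))
  expect_true(all(vapply(pc2$maps, pci_total, 0L) <= 39))
})

test_that("growth generator encodes the treatment rate multiplier", {
  cfg <- default_cohort_config(n_mice = 3)
  cfg$growth_specs$lognormal_cv <- 0
  gr <- generate_growth_cohort(cfg, seed = 1)
  r <- growth_ratio(gr, baseline_day = 4)
  g <- cfg$growth_specs$growth_rate_per_day
  days <- cfg$growth_specs$days
  ctrl <- r$per_group[r$per_group$group == "NaCl", ]
  expect_equal(ctrl$geo_mean_ratio, exp(g * (days - 4)))
  prit <- r$per_group[r$per_group$group == "PRIT", ]
  expect_equal(prit$geo_mean_ratio, exp(0.5 * g * (days - 4)))
  # multiplier 0: treated flux flat at baseline
  cfg$growth_specs$treatment_rate_multiplier <- 0
  gr0 <- generate_growth_cohort(cfg, seed = 1)
  flat <- gr0[gr0$group == "PRIT", ]
  expect_equal(unique(flat$total_flux), cfg$growth_specs$baseline_flux)
  # configured rate recovered by log-linear regression on noiseless data
  ctrl_rec <- gr[gr$group == "NaCl" & gr$mouse_id == "NaCl_g01", ]
  slope <- stats::coef(stats::lm(log(total_flux) ~ day, ctrl_rec))[["day"]]
  expect_equal(slope, g, tolerance = 1e-10)
})
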