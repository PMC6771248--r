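test_that("effective clearance rate fit handles canonical cases", {
  # flat tail: no clearance, flagged
  flat <- time_activity_curve("x", c(24, 48), c(0.5, 0.5))
  expect_warning(lam <- fit_effective_lambda(flat), "rising tail")
  expect_equal(lam, 0)
  # two-point formula on the reported tumor tail values
  tum <- time_activity_curve("Tumors", c(24, 144), c(6.29, 3.80) / 100)
  expect_equal(fit_effective_lambda(tum), log(6.29 / 3.80) / 120,
               tolerance = 1e-12)
  # exact recovery on a noiseless exponential, three points
  tt <- c(10, 50, 130)
  exact <- time_activity_curve("x", tt, 0.7 * exp(-0.01 * tt))
  expect_equal(fit_effective_lambda(exact, window = 3), 0.01,
               tolerance = 1e-10)
  # guards
  expect_error(fit_effective_lambda(
    time_activity_curve("x", c(1, 2), c(0, 1))), "non-positive")
  expect_error(fit_effective_lambda(
    time_activity_curve("x", 5, 1)), "at least two")
})

test_that("single measurement integrates to the closed-form exponential", {
  lu <- lu177()
  lam <- lu$lambda_phys_per_h
  # point at t = 0 decaying physically: A0 / lambda
  a0 <- 2e-3
  one <- time_activity_curve("x", 0, a0)
  for (scheme in c("trapezoid_tail", "single_point_tail")) {
    ca <- cumulated_activity(one, lu, scheme = scheme)
    expect_equal(ca$a_tilde_s_per_MBq, a0 / lam * 3600 * 1e6)
    expect_equal(ca$lambda_eff_per_h, lam)
  }
  # single point at t1 > 0: the A(t1) (t1 + 1/lambda) shortcut
  t1 <- 24
  ca <- cumulated_activity(time_activity_curve("x", t1, a0), lu,
                           scheme = "single_point_tail")
  expect_equal(ca$a_tilde_s_per_MBq, a0 * (t1 + 1 / lam) * 3600 * 1e6)
})

test_that("trapezoid-with-tail integral matches a dense reference grid", {
  lu <- lu177()
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:5, 1)
    tt <- sort(stats::runif(n, 2, 160))
    # bi-exponential shape with noise, strictly positive
    a <- 0.05 * (exp(-0.01 * tt) - exp(-0.2 * tt)) *
      stats::runif(n, 0.8, 1.25) + 1e-4
    tc <- time_activity_curve("x", tt, a)
    ca <- suppressWarnings(cumulated_activity(tc, lu))
    ref <- piecewise_reference_integral(tt, a, ca$lambda_eff_per_h)
    expect_equal(ca$a_tilde_s_per_MBq, ref, tolerance = 1e-3)
  }
})

test_that("integral is refinement-invariant and linear in activity", {
  lu <- lu177()
  tt <- c(24, 48, 144)
  a <- c(1.0e-3, 8.0e-4, 6.0e-4)
  tc <- time_activity_curve("x", tt, a)
  ca <- cumulated_activity(tc, lu)
  # insert a point lying exactly on the piecewise-linear segment
  tmid <- 36
  amid <- stats::approx(tt, a, tmid)$y
  tc2 <- time_activity_curve("x", c(24, 36, 48, 144), c(a[1], amid, a[2:3]))
  ca2 <- cumulated_activity(tc2, lu)
  expect_equal(ca2$a_tilde_s_per_MBq, ca$a_tilde_s_per_MBq, tolerance = 1e-12)
  # uniform scaling of the curve scales the integral
  ca5 <- cumulated_activity(time_activity_curve("x", tt, 5 * a), lu)
  expect_equal(ca5$a_tilde_s_per_MBq, 5 * ca$a_tilde_s_per_MBq)
  # and exceeds the inner trapezoid area alone
  inner <- sum(diff(tt) * (utils::head(a, -1) + utils::tail(a, -1)) / 2) *
    3600 * 1e6
  expect_gt(ca$a_tilde_s_per_MBq, inner)
})

test_that("tail rate is floored at physical decay, keeping the integral finite", {
  lu <- lu177()
  # rising tail: apparent accumulation cannot outlast physical decay
  rising <- time_activity_curve("x", c(24, 144), c(1e-3, 2e-3))
  ca <- suppressWarnings(cumulated_activity(rising, lu))
  expect_equal(ca$lambda_eff_per_h, lu$lambda_phys_per_h)
  expect_true(is.finite(ca$a_tilde_s_per_MBq))
  # clearance slower than physical decay is also floored
  slow <- time_activity_curve("x", c(24, 144), c(1e-3, 1e-3 * exp(-0.001 * 120)))
  ca2 <- cumulated_activity(slow, lu)
  expect_equal(ca2$lambda_eff_per_h, lu$lambda_phys_per_h)
  # faster clearance is kept as fitted
  fast <- time_activity_curve("x", c(24, 144), c(1e-3, 1e-3 * exp(-0.02 * 120)))
  expect_equal(cumulated_activity(fast, lu)$lambda_eff_per_h, 0.02,
               tolerance = 1e-10)
})

test_that("cohort and per-mouse curve construction split records correctly", {
  rec <- data.frame(
    mouse_id = rep(c("m1", "m2"), each = 2),
    organ = "Tumors",
    time_h = rep(c(24, 144), 2),
    pct_ia = c(0.10, 0.06, 0.14, 0.08),
    pct_ia_per_g = NA_real_
  )
  per_mouse <- build_tacs(rec, by = "mouse")
  expect_length(per_mouse, 2)
  expect_equal(per_mouse[[1]]$frac_ia, c(0.10, 0.06) / 100)
  cohort <- build_tacs(rec, by = "cohort")
  expect_length(cohort, 1)
  expect_equal(cohort[[1]]$frac_ia, c(0.12, 0.07) / 100)
})
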