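# Shared fixtures built in code.

# One-row counting measurement with sensible defaults.
make_measurement <- function(mouse_id = "m1", organ = "Tumors",
                             mass_g = 0.016, activity_Bq = 1e4,
                             time_h = 24, injected_MBq = 10, ...) {
  data.frame(mouse_id = mouse_id, organ = organ, mass_g = mass_g,
             activity_Bq = activity_Bq, time_h = time_h,
             injected_MBq = injected_MBq, ..., stringsAsFactors = FALSE)
}

# Dense-grid reference integral of the same piecewise model the
# trapezoid_tail scheme defines: linear ramp from the origin, linear
# interpolation between points, exponential tail at rate lambda_tail.
# Independent of the integrator implementation (pure approxfun + sums).
piecewise_reference_integral <- function(times_h, frac_ia, lambda_tail,
                                         n_grid = 2e5) {
  f <- stats::approxfun(c(0, times_h), c(0, frac_ia))
  tt <- seq(0, max(times_h), length.out = n_grid)
  dt <- tt[2] - tt[1]
  body <- sum((f(tt[-1]) + f(tt[-n_grid])) / 2) * dt
  tail <- frac_ia[length(frac_ia)] / lambda_tail  # exact exponential integral
  (body + tail) * 3600 * 1e6
}
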