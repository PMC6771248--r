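#' Time-activity curve for one source region
#'
#' Holds the fraction of injected activity present in a region at each
#' sampled time post injection. Fractions are dimensionless
#' (\code{pct_ia / 100}); times are hours and must be strictly increasing.
#'
#' @param organ Region label.
#' @param times_h Strictly increasing measurement times, hours post
#'   injection (all > 0; the curve is anchored at the origin by the
#'   integrator, not stored).
#' @param frac_ia Fraction of injected activity at each time (>= 0).
#' @return An object of class \code{tac}.
#' @export
#' @examples
#' time_activity_curve("Tumors", c(24, 48, 144), c(1.0e-3, 8.1e-4, 6.1e-4))
time_activity_curve <- function(organ, times_h, frac_ia) {
  stopifnot(length(times_h) == length(frac_ia), length(times_h) >= 1L)
  if (any(!is.finite(times_h)) || any(!is.finite(frac_ia)))
    stop("times and activities must be finite")
  if (any(diff(times_h) <= 0))
    stop("times_h must be strictly increasing")
  if (any(times_h < 0))
    stop("times_h must be non-negative (hours post injection)")
  if (any(frac_ia < 0))
    stop("frac_ia must be non-negative")
  structure(list(organ = organ, times_h = as.numeric(times_h),
                 frac_ia = as.numeric(frac_ia)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s: %d point(s)\n", x$organ, length(x$times_h)))
  print(data.frame(time_h = x$times_h, frac_ia = x$frac_ia))
  invisible(x)
}

#' Effective clearance rate from the tail of a time-activity curve
#'
#' Log-linear least-squares fit of \eqn{\log A(t)} over the last
#' \code{window} points; with a two-point window this reduces to the exact
#' formula \eqn{\lambda_{eff} = \ln(A_i/A_j)/(t_j - t_i)}. The returned rate
#' combines biological clearance and physical decay as observed in the
#' region. A non-positive rate (rising tail) is returned as-is with a
#' warning; callers integrating the tail must floor it at the physical
#' decay constant.
#'
#' @param curve A [time_activity_curve()].
#' @param window Number of trailing points to fit (>= 2; clipped to the
#'   curve length).
#' @return Effective decay constant in 1/h (may be <= 0 for a rising tail).
#' @export
#' @examples
#' tc <- time_activity_curve("Tumors", c(24, 144), c(6.29, 3.80) / 100 * 0.016)
#' fit_effective_lambda(tc)   # ~4.2e-3 per h
fit_effective_lambda <- function(curve, window = 2) {
  stopifnot(inherits(curve, "tac"))
  n <- length(curve$times_h)
  window <- min(max(2L, as.integer(window)), n)
  if (n < 2L)
    stop("need at least two points to fit a clearance rate")
  idx <- seq.int(n - window + 1L, n)
  a <- curve$frac_ia[idx]
  t <- curve$times_h[idx]
  if (any(a <= 0))
    stop("tail window contains non-positive activities; cannot fit log-linear rate")
  fit <- stats::lm.fit(cbind(1, t), log(a))
  lambda <- -unname(fit$coefficients[2])
  if (!is.finite(lambda))
    stop("log-linear fit failed")
  if (abs(lambda) < 1e-12) lambda <- 0   # numerically flat tail
  if (lambda <= 0)
    warning("rising tail: effective lambda <= 0; integrators floor it at the physical decay constant")
  lambda
}

#' Time-integrated (cumulated) activity of a region
#'
#' Computes the MIRD source term \eqn{\tilde A}, the time integral of the
#' region's activity per unit injected activity, in Bq s per MBq injected.
#'
#' Two schemes are provided. \code{trapezoid_tail}: a linear ramp from the
#' origin (0, 0) to the first measured point (the activity is zero at
#' injection for an i.p. administration), trapezoids between measured
#' points, and an analytic exponential tail \eqn{A_{last}/\lambda_{tail}}
#' beyond the last point. \code{single_point_tail}: the one-measurement
#' shortcut \eqn{\tilde A = A(t_1)(t_1 + 1/\lambda_{tail})}, i.e. a ramp to
#' the single point plus the exponential tail. In both schemes the tail rate
#' is \eqn{\lambda_{tail} = \max(\lambda_{eff}, \lambda_{phys})}: apparent
#' retention cannot outlast physical decay, and the floor keeps the integral
#' finite for any curve.
#'
#' @param curve A [time_activity_curve()].
#' @param nuclide A [nuclide_properties()] object supplying the physical
#'   floor.
#' @param scheme \code{"trapezoid_tail"} (default) or
#'   \code{"single_point_tail"}.
#' @param tail_window Trailing points used by [fit_effective_lambda()];
#'   default 2. Ignored for single-point curves, where the tail decays
#'   physically.
#' @return An object of class \code{cumulated_activity}: list with
#'   \code{organ}, \code{a_tilde_s_per_MBq}, \code{lambda_eff_per_h} (the
#'   floored tail rate actually used), and \code{scheme}.
#' @export
#' @examples
#' tc <- time_activity_curve("Tumors", c(24, 48, 144),
#'                           c(1.01e-3, 8.2e-4, 6.1e-4))
#' cumulated_activity(tc, lu177())
cumulated_activity <- function(curve, nuclide,
                               scheme = c("trapezoid_tail",
                                          "single_point_tail"),
                               tail_window = 2) {
  stopifnot(inherits(curve, "tac"), inherits(nuclide, "nuclide_properties"))
  scheme <- match.arg(scheme)
  t <- curve$times_h
  a <- curve$frac_ia
  n <- length(t)
  lam_phys <- nuclide$lambda_phys_per_h

  lam_eff <- if (n >= 2L && all(a > 0)) {
    suppressWarnings(fit_effective_lambda(curve, tail_window))
  } else {
    lam_phys
  }
  lam_tail <- max(lam_eff, lam_phys)

  if (scheme == "single_point_tail") {
    # one-measurement shortcut: conservative plateau up to t1, then tail
    area_h <- a[1] * (t[1] + 1 / lam_tail)
  } else {
    ramp <- 0.5 * t[1] * a[1]
    trap <- if (n > 1L)
      sum(0.5 * diff(t) * (utils::head(a, -1) + utils::tail(a, -1)))
    else 0
    area_h <- ramp + trap + a[n] / lam_tail
  }
  structure(
    list(organ = curve$organ,
         a_tilde_s_per_MBq = area_h * 3600 * 1e6,
         lambda_eff_per_h = lam_tail,
         scheme = scheme),
    class = "cumulated_activity"
  )
}

#' @export
print.cumulated_activity <- function(x, ...) {
  cat(sprintf("<cumulated activity> %s: %.4g Bq.s/MBq (tail lambda %.3e /h, %s)\n",
              x$organ, x$a_tilde_s_per_MBq, x$lambda_eff_per_h, x$scheme))
  invisible(x)
}

#' Build per-region time-activity curves from biodistribution records
#'
#' Groups %IA/g records by organ (and optionally mouse), converts the
#' whole-region percent injected activity to a fraction, and averages over
#' animals at each scheduled time when a cohort-level curve is requested.
#'
#' @param records Biodistribution records from [as_pct_ia_per_g()]; the
#'   \code{pct_ia} column (whole-region percent) is required, so organ
#'   masses must have been known.
#' @param by \code{"mouse"}: one curve per mouse x organ (longitudinal
#'   designs); \code{"cohort"}: one mean curve per organ, averaging
#'   \code{pct_ia} over animals at each time (cross-sectional designs).
#' @return A list of [time_activity_curve()] objects, named
#'   \code{organ} or \code{mouse_id.organ}.
#' @export
build_tacs <- function(records, by = c("mouse", "cohort")) {
  by <- match.arg(by)
  if (!all(c("organ", "time_h", "pct_ia") %in% names(records)))
    stop("records need columns organ, time_h, pct_ia")
  if (anyNA(records$pct_ia))
    stop("pct_ia has missing values; organ masses are required to build curves")
  if (by == "cohort") {
    agg <- stats::aggregate(pct_ia ~ organ + time_h, data = records, FUN = mean)
    split_keys <- agg$organ
    dat <- agg
  } else {
    if (!"mouse_id" %in% names(records))
      stop("records need mouse_id for per-mouse curves")
    dat <- records
    split_keys <- interaction(records$mouse_id, records$organ, drop = TRUE)
  }
  out <- lapply(split(dat, split_keys), function(g) {
    g <- g[order(g$time_h), ]
    tc <- time_activity_curve(as.character(g$organ[1]), g$time_h,
                              g$pct_ia / 100)
    if (by == "mouse") tc$mouse_id <- as.character(g$mouse_id[1])
    tc
  })
  out
}
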