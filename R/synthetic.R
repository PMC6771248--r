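#' Moment-matched lognormal parameters
#'
#' Returns the \eqn{(\mu, \sigma)} of the underlying normal such that the
#' lognormal has exactly the requested arithmetic mean and standard
#' deviation: \eqn{\sigma^2 = \ln(1 + sd^2/mean^2)},
#' \eqn{\mu = \ln(mean) - \sigma^2/2}. Used for strictly positive
#' quantities with large coefficients of variation, such as tumor %IA/g
#' where the dispersion approaches 70% of the mean and Gaussian draws
#' would go negative.
#'
#' @param mean Target arithmetic mean (> 0).
#' @param sd Target standard deviation (>= 0); 0 gives the degenerate
#'   point mass at \code{mean}.
#' @return List with \code{mu} and \code{sigma}.
#' @export
#' @examples
#' p <- lognormal_params(6.29, 4.27)
#' exp(p$mu + p$sigma^2 / 2)   # 6.29 back
lognormal_params <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive")
  if (!is.finite(sd) || sd < 0) stop("sd must be non-negative")
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

# Truncated-normal sampler (lower bound only), by rejection; deterministic
# under the caller's seed.
.rtruncnorm_pos <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x > lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Synthetic cohort configuration
#'
#' Bundles every parameter the synthetic generators need. The defaults
#' (see [default_cohort_config()]) reproduce the design of the real
#' pretargeting experiment: group sizes, harvest schedule, injected
#' activity, and organ-level %IA/g distributions taken from the reported
#' cohort statistics.
#'
#' @param n_mice Animals per group (>= 1).
#' @param tracer Tracer label.
#' @param organ_specs Data frame: \code{organ}, \code{time_h},
#'   \code{mean_pct_ia_per_g}, \code{sd_pct_ia_per_g}, \code{mass_g_mean},
#'   \code{mass_g_sd} — one row per organ x scheduled time.
#' @param injected_MBq Injected activity per animal, MBq.
#' @param counting_efficiency Counts-to-Bq efficiency emulated by the
#'   counter model (fraction in (0, 1]).
#' @param pci_group_specs Data frame: \code{group}, \code{mean}, \code{sd},
#'   \code{n} — target PCI distribution per treatment group.
#' @param growth_specs List: \code{baseline_flux} (photons/s),
#'   \code{growth_rate_per_day}, \code{treatment_rate_multiplier},
#'   \code{lognormal_cv}, \code{days} (imaging schedule, days
#'   post-treatment).
#' @return Object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_mice, tracer, organ_specs, injected_MBq = 10,
                          counting_efficiency = 1,
                          pci_group_specs = NULL, growth_specs = NULL) {
  stopifnot(n_mice >= 1)
  req <- c("organ", "time_h", "mean_pct_ia_per_g", "sd_pct_ia_per_g",
           "mass_g_mean", "mass_g_sd")
  miss <- setdiff(req, names(organ_specs))
  if (length(miss))
    stop("organ_specs lacks columns: ", paste(miss, collapse = ", "))
  with(organ_specs, {
    if (any(mean_pct_ia_per_g < 0) || any(sd_pct_ia_per_g < 0) ||
        any(mass_g_mean <= 0) || any(mass_g_sd < 0))
      stop("organ_specs means/SDs must be non-negative, masses positive")
  })
  if (!is.finite(injected_MBq) || injected_MBq <= 0)
    stop("injected_MBq must be positive")
  if (counting_efficiency <= 0 || counting_efficiency > 1)
    stop("counting_efficiency must be in (0, 1]")
  if (!is.null(pci_group_specs)) {
    if (any(pci_group_specs$mean > 39))
      stop("PCI group means cannot exceed the maximal score 39")
    if (any(pci_group_specs$mean < 0) || any(pci_group_specs$sd < 0))
      stop("PCI group specs must be non-negative")
  }
  structure(list(n_mice = as.integer(n_mice), tracer = tracer,
                 organ_specs = organ_specs, injected_MBq = injected_MBq,
                 counting_efficiency = counting_efficiency,
                 pci_group_specs = pci_group_specs,
                 growth_specs = growth_specs),
            class = "cohort_config")
}

#' Default synthetic-cohort configuration
#'
#' Pre-filled from the study conditions of the pretargeted Lu-177
#' experiment it emulates: 10 MBq injected i.p.; tumor %IA/g 6.29 +/- 4.27
#' at 24 h and 3.80 +/- 2.18 at 144 h with tumor mass 0.016 g; blood
#' 0.22 +/- 0.02 %IA/g at 24 h (0.2 g counting aliquot); main-organ masses
#' from the packaged S-value table with 10% relative spread; PCI group
#' targets 15.5 +/- 2.3 (PRIT), 30.0 +/- 2.3 (NaCl), 30.8 +/- 1.4
#' (Tz-only) with 6 animals per therapy group; exponential tumor growth
#' imaged on days 4-20.
#'
#' @param n_mice Animals per group; default 6.
#' @param tracer Tracer label; default \code{"Tz-2"}, the probe the
#'   emulated experiment selected for therapy.
#' @return A [cohort_config()].
#' @export
default_cohort_config <- function(n_mice = 6, tracer = "Tz-2") {
  organ_specs <- data.frame(
    organ = c("Tumors", "Tumors", "Blood"),
    time_h = c(24, 144, 24),
    mean_pct_ia_per_g = c(6.29, 3.80, 0.22),
    sd_pct_ia_per_g = c(4.27, 2.18, 0.02),
    mass_g_mean = c(0.016, 0.016, 0.2),
    mass_g_sd = c(0.0016, 0.0016, 0.02),
    stringsAsFactors = FALSE
  )
  pci <- data.frame(
    group = c("NaCl", "Tz-only", "PRIT"),
    mean = c(30.0, 30.8, 15.5),
    sd = c(2.3, 1.4, 2.3),
    n = c(6L, 6L, 6L),
    stringsAsFactors = FALSE
  )
  growth <- list(baseline_flux = 1e7, growth_rate_per_day = 0.25,
                 treatment_rate_multiplier = 0.5, lognormal_cv = 0.5,
                 days = c(4, 6, 13, 20))
  cohort_config(n_mice, tracer, organ_specs, injected_MBq = 10,
                counting_efficiency = 1, pci_group_specs = pci,
                growth_specs = growth)
}

#' Generate a synthetic gamma-counting cohort
#'
#' Draws, for every mouse x organ x scheduled time, an organ mass
#' (truncated normal, > 0) and a %IA/g value (moment-matched lognormal),
#' then converts back to the activity a gamma counter would report at the
#' harvest time — applying physical decay from injection to harvest and
#' the counting efficiency. This is the exact inverse of
#' [as_pct_ia_per_g()], so the quantification stage round-trips: in the
#' noiseless limit it recovers the configured means exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; fixed seed gives bit-identical tables.
#' @param nuclide Radionuclide used for the forward decay; default
#'   [lu177()].
#' @return Measurement data frame consumable by [as_pct_ia_per_g()] /
#'   [mird_fit()]: \code{mouse_id, organ, mass_g, activity_Bq, time_h,
#'   injected_MBq, tracer}, plus a \code{true_pct_ia_per_g} column holding
#'   the simulated truth.
#' @export
#' @examples
#' meas <- generate_biodist_cohort(default_cohort_config(n_mice = 3), seed = 1)
#' head(meas)
generate_biodist_cohort <- function(config, seed, nuclide = lu177()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  specs <- config$organ_specs
  ids <- sprintf("m%04d", seq_len(config$n_mice))
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    mass <- .rtruncnorm_pos(config$n_mice, sp$mass_g_mean, sp$mass_g_sd)
    pct <- if (sp$sd_pct_ia_per_g == 0 || sp$mean_pct_ia_per_g == 0) {
      rep(sp$mean_pct_ia_per_g, config$n_mice)
    } else {
      p <- lognormal_params(sp$mean_pct_ia_per_g, sp$sd_pct_ia_per_g)
      stats::rlnorm(config$n_mice, p$mu, p$sigma)
    }
    a_inj_bq <- pct / 100 * config$injected_MBq * 1e6 * mass
    a_meas <- a_inj_bq * decay_factor(nuclide, -sp$time_h) *
      config$counting_efficiency
    rows[[i]] <- data.frame(
      mouse_id = ids, organ = sp$organ, mass_g = mass,
      activity_Bq = a_meas, time_h = sp$time_h,
      injected_MBq = config$injected_MBq, tracer = config$tracer,
      true_pct_ia_per_g = pct, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mouse_id, out$organ, out$time_h), ]
  rownames(out) <- NULL
  out
}

# Distribute an integer total over 13 regions with per-region cap 3, by
# uniform random increments over the regions still below the cap.
.allocate_pci <- function(target, regions) {
  scores <- stats::setNames(integer(length(regions)), regions)
  cap <- 3L * length(regions)
  if (target > cap) stop("infeasible PCI target > ", cap)
  for (i in seq_len(target)) {
    avail <- which(scores < 3L)
    pick <- if (length(avail) == 1L) avail else avail[sample.int(length(avail), 1L)]
    scores[pick] <- scores[pick] + 1L
  }
  scores
}

#' Generate a synthetic PCI cohort
#'
#' For each treatment group draws per-animal target totals from a normal
#' truncated to [0, 39], rounds them, and distributes each total over the
#' 13 scoring regions by constrained random allocation (each region capped
#' at 3). The emitted map's [pci_total()] equals the drawn (rounded)
#' target exactly.
#'
#' @param config A [cohort_config()] with \code{pci_group_specs}; the
#'   per-group \code{n} column sets group sizes.
#' @param seed Integer seed.
#' @param n_per_group Optional override of every group's size.
#' @return List: \code{maps} (list of [pci_map()]), \code{groups}
#'   (character vector aligned with \code{maps}).
#' @export
#' @examples
#' pc <- generate_pci_cohort(default_cohort_config(), seed = 1)
#' group_pci_summary(pc$maps, pc$groups)
generate_pci_cohort <- function(config, seed, n_per_group = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$pci_group_specs
  if (is.null(specs)) stop("config has no pci_group_specs")
  set.seed(as.integer(seed))
  regions <- pci_regions()
  maps <- list()
  groups <- character(0)
  k <- 0L
  for (i in seq_len(nrow(specs))) {
    n <- if (is.null(n_per_group)) specs$n[i] else n_per_group
    targets <- round(.rtruncnorm_pos(n, specs$mean[i], specs$sd[i],
                                     lower = -0.5, upper = 39.49))
    targets <- pmin(pmax(as.integer(targets), 0L), 39L)
    for (t in targets) {
      k <- k + 1L
      maps[[k]] <- pci_map(sprintf("%s_m%04d", specs$group[i], k),
                           .allocate_pci(t, regions), regions)
      groups[k] <- specs$group[i]
    }
  }
  list(maps = maps, groups = groups)
}

#' Generate a synthetic tumor-growth cohort
#'
#' Exponential growth of the bioluminescence flux with multiplicative
#' lognormal measurement noise:
#' \deqn{flux(d) = F_0 \exp(r \, g \, d) \cdot \epsilon, \quad
#'       \epsilon \sim LN(\cdot, cv)}
#' where the rate multiplier \eqn{g} applies to the PRIT group only
#' (\eqn{g = 1} for controls). The imaging schedule and group labels come
#' from the configuration.
#'
#' @param config A [cohort_config()] with \code{growth_specs}.
#' @param seed Integer seed.
#' @return Data frame: \code{mouse_id}, \code{group}, \code{day},
#'   \code{total_flux}.
#' @export
generate_growth_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  gs <- config$growth_specs
  if (is.null(gs)) stop("config has no growth_specs")
  set.seed(as.integer(seed))
  groups <- c("NaCl", "Tz-only", "PRIT")
  cv <- gs$lognormal_cv
  p <- if (cv > 0) lognormal_params(1, cv) else list(mu = 0, sigma = 0)
  rows <- list()
  for (g in groups) {
    mult <- if (g == "PRIT") gs$treatment_rate_multiplier else 1
    for (m in seq_len(config$n_mice)) {
      id <- sprintf("%s_g%02d", g, m)
      flux <- gs$baseline_flux *
        exp(gs$growth_rate_per_day * mult * gs$days) *
        stats::rlnorm(length(gs$days), p$mu, p$sigma)
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = id, group = g, day = gs$days, total_flux = flux,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
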