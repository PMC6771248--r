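KEV_TO_J <- 1.602176634e-16

#' Self S-value entry
#'
#' One row of an S-value table: the absorbed dose to a region per unit
#' cumulated activity in that same region (Gy per Bq s), together with the
#' reference mass the value was computed for and its provenance.
#'
#' @param organ Region label.
#' @param s_gy_per_bq_s Self S-value, Gy/(Bq s); > 0.
#' @param ref_mass_g Reference mass, g; > 0.
#' @param provenance One of \code{"tabulated"}, \code{"local_deposition"},
#'   \code{"monte_carlo"}.
#' @return A one-row data frame of class \code{s_value}.
#' @export
s_value_entry <- function(organ, s_gy_per_bq_s, ref_mass_g,
                          provenance = c("tabulated", "local_deposition",
                                         "monte_carlo")) {
  provenance <- match.arg(provenance)
  if (!is.finite(s_gy_per_bq_s) || s_gy_per_bq_s <= 0)
    stop("s_gy_per_bq_s must be positive")
  if (!is.finite(ref_mass_g) || ref_mass_g <= 0)
    stop("ref_mass_g must be positive")
  structure(
    data.frame(organ = organ, s_gy_per_bq_s = s_gy_per_bq_s,
               ref_mass_g = ref_mass_g, provenance = provenance,
               stringsAsFactors = FALSE),
    class = c("s_value", "data.frame")
  )
}

#' Packaged mouse self S-value table for Lu-177
#'
#' Self S-factors (Gy/Bq s) and reference organ masses for the main mouse
#' organs and a small peritoneal tumor sphere, from full Monte Carlo
#' electron transport in the same mouse model. Seven regions: Heart, Lungs,
#' Liver, Kidneys, Spleen, Brain, Tumors. Paired kidneys are a single
#' region with combined mass.
#'
#' @return Data frame with columns \code{organ}, \code{s_gy_per_bq_s},
#'   \code{ref_mass_g}, \code{provenance}.
#' @export
#' @examples
#' s_value_table()
s_value_table <- function() {
  path <- system.file("extdata", "s_values_lu177_mouse.csv",
                      package = "mirdose", mustWork = TRUE)
  df <- read_s_values(path)
  df$provenance <- "tabulated"
  df
}

#' Read / write S-value CSV files
#'
#' @param path CSV with columns \code{organ}, \code{s_gy_per_bq_s},
#'   \code{ref_mass_g} (an optional \code{provenance} column is kept).
#' @return Data frame of S-value rows.
#' @export
read_s_values <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("organ", "s_gy_per_bq_s", "ref_mass_g")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (any(df$s_gy_per_bq_s <= 0) || any(df$ref_mass_g <= 0))
    stop(sprintf("%s: S-values and masses must be positive", path))
  df
}

#' @rdname read_s_values
#' @param svalues S-value data frame.
#' @param header_comment Optional provenance comment written as a
#'   \code{#}-prefixed first line.
#' @export
write_s_values <- function(svalues, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(svalues, con, row.names = FALSE)
  invisible(path)
}

#' Analytic self S-value in the local energy deposition limit
#'
#' When the mean electron range is small compared to the region, all
#' emitted beta energy is absorbed where it is emitted (absorbed fraction
#' 1) and the self S-value reduces to mean energy per decay divided by
#' region mass:
#' \deqn{S = \bar E \, / \, m \quad [\mathrm{Gy\,Bq^{-1}\,s^{-1}}]}
#' with \eqn{\bar E} in joules and \eqn{m} in kg. Because real transport
#' lets some energy escape, this is an upper bound on the true electron
#' self S-value of any region of the same mass.
#'
#' @param mean_energy_keV Mean beta energy per decay, keV; > 0.
#' @param mass_g Region mass in grams; > 0.
#' @param organ Label for the returned entry.
#' @return A [s_value_entry()] with provenance \code{"local_deposition"}.
#' @export
#' @examples
#' local_deposition_s(133.3, 0.016)   # ~1.335e-9 Gy/Bq/s (small tumor)
local_deposition_s <- function(mean_energy_keV, mass_g, organ = "region") {
  if (!is.finite(mean_energy_keV) || mean_energy_keV <= 0)
    stop("mean_energy_keV must be positive")
  if (!is.finite(mass_g) || mass_g <= 0)
    stop("mass_g must be positive")
  s <- mean_energy_keV * KEV_TO_J / (mass_g * 1e-3)
  s_value_entry(organ, s, mass_g, "local_deposition")
}

#' Spherical source/target geometry
#'
#' A homogeneous sphere of soft tissue. Mass, radius and density are kept
#' consistent: any two determine the third, and if all three are supplied
#' they must agree within 5% (the supplied mass wins for dose
#' normalisation, matching the convention of quoting a nominal diameter
#' alongside a measured mass).
#'
#' @param radius_mm Sphere radius in mm.
#' @param mass_g Sphere mass in grams.
#' @param density_g_per_cm3 Tissue density; default 1.0 (soft tissue).
#'   When radius and mass are both supplied without an explicit density,
#'   the density is derived from them; when all three are supplied they
#'   must agree within 5%.
#' @return Object of class \code{sphere_geometry} with all three fields
#'   filled.
#' @export
#' @examples
#' sphere_geometry(mass_g = 0.016)              # tumor sphere, r ~ 1.56 mm
#' sphere_geometry(radius_mm = 1.5, mass_g = 0.015) # density derived, 1.06
sphere_geometry <- function(radius_mm = NULL, mass_g = NULL,
                            density_g_per_cm3 = 1.0) {
  density_given <- !missing(density_g_per_cm3)
  if (!is.finite(density_g_per_cm3) || density_g_per_cm3 <= 0)
    stop("density must be positive")
  vol_from_r <- function(r_mm) 4 / 3 * pi * (r_mm / 10)^3   # cm^3
  if (is.null(radius_mm) && is.null(mass_g))
    stop("supply radius_mm or mass_g")
  if (is.null(radius_mm))
    radius_mm <- 10 * (3 * mass_g / (4 * pi * density_g_per_cm3))^(1 / 3)
  if (is.null(mass_g))
    mass_g <- vol_from_r(radius_mm) * density_g_per_cm3
  if (radius_mm <= 0 || mass_g <= 0)
    stop("radius and mass must be positive")
  if (!density_given)
    density_g_per_cm3 <- mass_g / vol_from_r(radius_mm)
  implied <- vol_from_r(radius_mm) * density_g_per_cm3
  if (abs(implied - mass_g) / mass_g > 0.05)
    stop(sprintf(
      "inconsistent geometry: radius %.3g mm and density %.3g imply %.4g g, supplied %.4g g (> 5%% apart)",
      radius_mm, density_g_per_cm3, implied, mass_g))
  structure(list(radius_mm = radius_mm, mass_g = mass_g,
                 density_g_per_cm3 = density_g_per_cm3),
            class = "sphere_geometry")
}

#' @export
print.sphere_geometry <- function(x, ...) {
  cat(sprintf("<sphere> r = %.3g mm, m = %.4g g, rho = %g g/cm3\n",
              x$radius_mm, x$mass_g, x$density_g_per_cm3))
  invisible(x)
}

# Distance from a point at radius r (mm) inside a sphere of radius R to the
# surface along a direction with cosine mu to the outward radial vector.
.chord_to_surface <- function(r, mu, R) {
  -r * mu + sqrt(pmax(R^2 - r^2 * (1 - mu^2), 0))
}

#' Monte Carlo absorbed fraction for a uniform source in a sphere
#'
#' Straight-track estimator: each history starts uniformly inside the
#' sphere, travels in an isotropic direction, and deposits its energy
#' uniformly along a straight track of the given length
#' (continuous-slowing-down, no scattering, no bremsstrahlung — adequate
#' when the range is a fraction of the sphere diameter). The absorbed
#' fraction is the expected fraction of track length lying inside the
#' sphere.
#'
#' @param geom A [sphere_geometry()].
#' @param track_length_mm Electron track (range) length in mm; >= 0. Zero
#'   means point deposition, absorbed fraction exactly 1.
#' @param n_histories Number of histories; >= 1.
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @return List with \code{phi} (estimate), \code{se} (standard error) and
#'   \code{n_histories}.
#' @seealso [sphere_absorbed_fraction_quad()] for the deterministic
#'   quadrature of the same geometry.
#' @export
#' @examples
#' g <- sphere_geometry(mass_g = 0.016)
#' sphere_absorbed_fraction_mc(g, 0.2, n_histories = 1e5, seed = 1)
sphere_absorbed_fraction_mc <- function(geom, track_length_mm,
                                        n_histories = 1e6, seed = 1) {
  stopifnot(inherits(geom, "sphere_geometry"))
  if (!is.finite(track_length_mm) || track_length_mm < 0)
    stop("track_length_mm must be >= 0")
  n <- as.integer(n_histories)
  if (n < 1L) stop("n_histories must be >= 1")
  if (track_length_mm == 0)
    return(list(phi = 1, se = 0, n_histories = n))
  R <- geom$radius_mm
  set.seed(as.integer(seed))
  r <- R * stats::runif(n)^(1 / 3)       # uniform in volume
  mu <- stats::runif(n, -1, 1)           # isotropic direction
  d <- .chord_to_surface(r, mu, R)
  frac <- pmin(d, track_length_mm) / track_length_mm
  list(phi = mean(frac),
       se = stats::sd(frac) / sqrt(n),
       n_histories = n)
}

#' Deterministic absorbed fraction by numerical quadrature
#'
#' Integrates the same straight-track geometry as
#' [sphere_absorbed_fraction_mc()] on a fine midpoint grid over source
#' radius (volume-weighted) and direction cosine. Used as the reference the
#' stochastic estimator is checked against.
#'
#' @inheritParams sphere_absorbed_fraction_mc
#' @param n_r,n_mu Grid resolution in radius and direction cosine.
#' @return Absorbed fraction (scalar).
#' @export
sphere_absorbed_fraction_quad <- function(geom, track_length_mm,
                                          n_r = 800, n_mu = 800) {
  stopifnot(inherits(geom, "sphere_geometry"))
  if (!is.finite(track_length_mm) || track_length_mm < 0)
    stop("track_length_mm must be >= 0")
  if (track_length_mm == 0) return(1)
  R <- geom$radius_mm
  r <- (seq_len(n_r) - 0.5) / n_r * R
  mu <- -1 + (seq_len(n_mu) - 0.5) / n_mu * 2
  w_r <- 3 * r^2 / R^3 * (R / n_r)          # volume weight, sums to ~1
  d <- .chord_to_surface(rep(r, times = n_mu),
                         rep(mu, each = n_r), R)
  frac <- matrix(pmin(d, track_length_mm) / track_length_mm,
                 nrow = n_r, ncol = n_mu)
  sum(w_r * rowMeans(frac))
}

#' Monte Carlo self S-value for a small sphere
#'
#' Combines the straight-track absorbed fraction with the local-deposition
#' S-value: \eqn{S = \phi \cdot \bar E / m}. In \code{"mean_energy"} mode a
#' single track length — the nuclide's mean range in soft tissue — carries
#' the mean beta energy. In \code{"sampled_spectrum"} mode each history
#' draws an energy from a simplified allowed-shape beta spectrum bounded by
#' the endpoint energy and converts it to a track length through
#' \code{range_map}; the S-value is then the energy-weighted mean of the
#' per-history absorbed fractions.
#'
#' @param geom A [sphere_geometry()].
#' @param nuclide A [nuclide_properties()] object.
#' @param n_histories Histories for the stochastic estimate.
#' @param seed Integer seed.
#' @param mode \code{"mean_energy"} (default) or \code{"sampled_spectrum"}.
#' @param range_map Function keV -> mm used in spectrum mode; the default
#'   scales the nuclide's mean range with energy as \eqn{E^{1.7}}, the
#'   approximate CSDA power law for sub-MeV electrons in water.
#' @param organ Label for the returned entry.
#' @return A [s_value_entry()] (provenance \code{"monte_carlo"}) with
#'   attributes \code{phi} and \code{phi_se}.
#' @export
mc_s_value <- function(geom, nuclide, n_histories = 1e6, seed = 1,
                       mode = c("mean_energy", "sampled_spectrum"),
                       range_map = NULL, organ = "sphere") {
  stopifnot(inherits(geom, "sphere_geometry"),
            inherits(nuclide, "nuclide_properties"))
  mode <- match.arg(mode)
  if (mode == "mean_energy") {
    mc <- sphere_absorbed_fraction_mc(geom, nuclide$mean_range_soft_tissue_mm,
                                      n_histories, seed)
    base <- local_deposition_s(nuclide$mean_beta_energy_keV, geom$mass_g)
    out <- s_value_entry(organ, mc$phi * base$s_gy_per_bq_s, geom$mass_g,
                         "monte_carlo")
    attr(out, "phi") <- mc$phi
    attr(out, "phi_se") <- mc$se
    return(out)
  }
  if (is.null(range_map)) {
    r0 <- nuclide$mean_range_soft_tissue_mm
    e0 <- nuclide$mean_beta_energy_keV
    range_map <- function(e_keV) r0 * (e_keV / e0)^1.7
  }
  n <- as.integer(n_histories)
  set.seed(as.integer(seed))
  e <- .sample_beta_spectrum(n, nuclide$max_beta_energy_keV)
  R <- geom$radius_mm
  r <- R * stats::runif(n)^(1 / 3)
  mu <- stats::runif(n, -1, 1)
  d <- .chord_to_surface(r, mu, R)
  len <- range_map(e)
  frac <- ifelse(len <= 0, 1, pmin(d, len) / len)
  e_dep_keV <- mean(e * frac)
  s <- e_dep_keV * KEV_TO_J / (geom$mass_g * 1e-3)
  out <- s_value_entry(organ, s, geom$mass_g, "monte_carlo")
  attr(out, "phi") <- e_dep_keV / mean(e)
  attr(out, "phi_se") <- stats::sd(e * frac) / sqrt(n) / mean(e)
  out
}

# Simplified allowed-shape beta spectrum, N(E) ~ sqrt(E) (Emax - E)^2,
# sampled by rejection. Ignores the Fermi Coulomb correction.
.sample_beta_spectrum <- function(n, emax_keV) {
  dens <- function(e) sqrt(e) * (emax_keV - e)^2
  # mode of the density at Emax/5
  peak <- dens(emax_keV / 5)
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out))
    e <- stats::runif(m, 0, emax_keV)
    keep <- stats::runif(m) * peak < dens(e)
    out <- c(out, e[keep])
  }
  out[seq_len(n)]
}
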