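#' Physical properties of a beta-emitting radionuclide
#'
#' Container for the decay and emission constants the dosimetry pipeline
#' needs: physical half-life, mean and maximal beta energy, and the mean
#' electron range in soft tissue. The derived decay constant is stored per
#' hour, the internal time unit of the package.
#'
#' @param name Nuclide label, e.g. \code{"Lu-177"}.
#' @param half_life_days Physical half-life in days (> 0).
#' @param mean_beta_energy_keV Mean energy of the emitted beta spectrum, keV.
#' @param max_beta_energy_keV Maximal (endpoint) beta energy, keV; must
#'   exceed the mean energy.
#' @param mean_range_soft_tissue_mm Mean electron range in soft tissue, mm.
#'
#' @return An object of class \code{nuclide_properties}: a list with the
#'   supplied fields plus \code{lambda_phys_per_h}, the physical decay
#'   constant \eqn{\lambda = \ln 2 / T_{1/2}} in 1/h.
#' @seealso [lu177()] for the packaged lutetium-177 entry, [decay_factor()].
#' @export
#' @examples
#' lu <- nuclide_properties("Lu-177", 6.65, 133.3, 498.3, 0.2)
#' lu$lambda_phys_per_h
nuclide_properties <- function(name, half_life_days, mean_beta_energy_keV,
                               max_beta_energy_keV,
                               mean_range_soft_tissue_mm = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(half_life_days) || half_life_days <= 0)
    stop("half_life_days must be a positive finite number")
  if (!is.finite(mean_beta_energy_keV) || mean_beta_energy_keV <= 0)
    stop("mean_beta_energy_keV must be positive")
  if (!is.finite(max_beta_energy_keV) ||
      max_beta_energy_keV <= mean_beta_energy_keV)
    stop("max_beta_energy_keV must exceed mean_beta_energy_keV")
  half_life_h <- half_life_days * 24
  structure(
    list(
      name = name,
      half_life_days = half_life_days,
      half_life_h = half_life_h,
      mean_beta_energy_keV = mean_beta_energy_keV,
      max_beta_energy_keV = max_beta_energy_keV,
      mean_range_soft_tissue_mm = mean_range_soft_tissue_mm,
      lambda_phys_per_h = log(2) / half_life_h
    ),
    class = "nuclide_properties"
  )
}

#' @export
print.nuclide_properties <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %g d (lambda = %.4e /h), ", x$name,
              x$half_life_days, x$lambda_phys_per_h))
  cat(sprintf("E_beta mean/max = %g/%g keV, mean range %g mm\n",
              x$mean_beta_energy_keV, x$max_beta_energy_keV,
              x$mean_range_soft_tissue_mm))
  invisible(x)
}

#' Load a nuclide from the packaged table
#'
#' The package ships a small nuclide table (\code{inst/extdata/nuclides.csv});
#' \code{lu177()} returns its lutetium-177 row as a
#' \code{nuclide_properties} object.
#'
#' @param name Nuclide name to look up in the packaged table.
#' @return A [nuclide_properties()] object.
#' @export
#' @examples
#' lu177()
load_nuclide <- function(name = "Lu-177") {
  path <- system.file("extdata", "nuclides.csv", package = "mirdose",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("nuclide not found in packaged table: ", name)
  nuclide_properties(row$name, row$half_life_days, row$mean_beta_energy_keV,
                     row$max_beta_energy_keV, row$mean_range_soft_tissue_mm)
}

#' @rdname load_nuclide
#' @export
lu177 <- function() load_nuclide("Lu-177")

#' Physical decay factor over a time offset
#'
#' Returns \eqn{\exp(\lambda \, \Delta t)} for the nuclide's physical decay
#' constant. A positive \code{delta_t_h} corrects a measured activity
#' backwards in time (e.g. back to injection, factor > 1); a negative value
#' decays an activity forward.
#'
#' @param nuclide A [nuclide_properties()] object.
#' @param delta_t_h Time offset(s) in hours; any finite real, vectorised.
#' @return Dimensionless factor(s) \eqn{\exp(\lambda \Delta t)}.
#' @export
#' @examples
#' decay_factor(lu177(), 0)                 # 1
#' decay_factor(lu177(), 6.65 * 24)         # 2: one half-life back
decay_factor <- function(nuclide, delta_t_h) {
  stopifnot(inherits(nuclide, "nuclide_properties"))
  if (!all(is.finite(delta_t_h)))
    stop("delta_t_h must be finite")
  exp(nuclide$lambda_phys_per_h * delta_t_h)
}
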