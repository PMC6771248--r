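#' Convert gamma-counting measurements to percent injected activity per gram
#'
#' Reduces raw organ counting data to the standard biodistribution quantity
#' %IA/g. Each measurement row holds the harvested organ mass, the measured
#' activity (already converted from counts with the counter's efficiency
#' factor), the harvest time post injection, and the injected activity.
#' With \code{decay_correct = TRUE} (default) the measured activity is
#' corrected for physical decay back to the injection time, so that values
#' from different harvest times are comparable:
#' \deqn{\%IA/g = 100 \cdot A_{meas} e^{\lambda t} / (A_{inj} \, m)}
#'
#' @param measurements A data frame with columns \code{mouse_id},
#'   \code{organ}, \code{mass_g}, \code{activity_Bq}, \code{time_h},
#'   \code{injected_MBq} (see [read_counting_csv()]).
#' @param nuclide A [nuclide_properties()] object.
#' @param decay_correct Correct for physical decay between injection and
#'   measurement? Default \code{TRUE}.
#' @param counting_efficiency Multiplicative counts-to-Bq efficiency already
#'   applied to \code{activity_Bq}; supply a value < 1 here only if
#'   \code{activity_Bq} still holds raw counter readings to be divided by it.
#'
#' @return A data frame of biodistribution records: \code{mouse_id},
#'   \code{organ}, \code{time_h}, \code{pct_ia_per_g} and \code{pct_ia}
#'   (whole-region percent injected activity, \code{pct_ia_per_g * mass_g}).
#' @export
#' @examples
#' m <- data.frame(mouse_id = "m1", organ = "Tumors", mass_g = 0.1,
#'                 activity_Bq = 1e5, time_h = 0, injected_MBq = 10)
#' as_pct_ia_per_g(m, lu177())   # 1% of IA in 0.1 g -> 10 %IA/g
as_pct_ia_per_g <- function(measurements, nuclide, decay_correct = TRUE,
                            counting_efficiency = 1) {
  req <- c("mouse_id", "organ", "mass_g", "activity_Bq", "time_h",
           "injected_MBq")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  stopifnot(inherits(nuclide, "nuclide_properties"))
  if (!is.finite(counting_efficiency) || counting_efficiency <= 0)
    stop("counting_efficiency must be positive")
  with(measurements, {
    if (any(!is.finite(mass_g) | mass_g <= 0))
      stop("mass_g must be positive for every row")
    if (any(!is.finite(injected_MBq) | injected_MBq <= 0))
      stop("injected_MBq must be positive for every row")
    if (any(!is.finite(activity_Bq) | activity_Bq < 0))
      stop("activity_Bq must be non-negative")
    if (any(!is.finite(time_h) | time_h < 0))
      stop("time_h must be >= 0 (hours post injection)")
  })
  a <- measurements$activity_Bq / counting_efficiency
  if (decay_correct)
    a <- a * decay_factor(nuclide, measurements$time_h)
  pct_g <- 100 * a / (measurements$injected_MBq * 1e6) / measurements$mass_g
  out <- data.frame(
    mouse_id = measurements$mouse_id,
    organ = measurements$organ,
    time_h = measurements$time_h,
    pct_ia_per_g = pct_g,
    pct_ia = pct_g * measurements$mass_g,
    stringsAsFactors = FALSE
  )
  if ("tracer" %in% names(measurements)) out$tracer <- measurements$tracer
  out
}

#' Read a gamma-counting CSV
#'
#' Expects the fixed lowercase header \code{mouse_id, organ, mass_g,
#' activity_Bq, time_h, injected_MBq} (an optional \code{tracer} column is
#' carried through). Malformed files raise an error naming the offending
#' column.
#'
#' @param path Path to the CSV file.
#' @return A data frame of organ measurements.
#' @export
read_counting_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("mouse_id", "organ", "mass_g", "activity_Bq", "time_h",
           "injected_MBq")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  for (col in c("mass_g", "activity_Bq", "time_h", "injected_MBq")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("%s: column '%s' is not numeric (first bad line: %d)",
                   path, col, bad + 1L))
    }
  }
  df
}

#' Write biodistribution records to CSV
#'
#' @param records Data frame from [as_pct_ia_per_g()].
#' @param path Output path.
#' @param header_comment Optional comment line (prefixed with \code{#})
#'   recording provenance such as seed and scheme.
#' @return \code{path}, invisibly.
#' @export
write_biodist_csv <- function(records, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}
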