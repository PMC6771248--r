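#' Absorbed dose from cumulated activity and self S-value
#'
#' The MIRD product \eqn{D = \tilde A \times S} for one source/target
#' region: cumulated activity per MBq injected (Bq s/MBq) times the self
#' S-value (Gy per Bq s) gives Gy per MBq injected. Both inputs must refer
#' to the same region.
#'
#' @param a_tilde A [cumulated_activity()] object.
#' @param s An [s_value_entry()] (one row) for the same organ.
#' @return A one-row data frame: \code{organ}, \code{dose_gy_per_MBq},
#'   \code{a_tilde_s_per_MBq}, \code{s_gy_per_bq_s}.
#' @export
#' @examples
#' tc <- time_activity_curve("Tumors", 24, 1e-3)
#' at <- cumulated_activity(tc, lu177())
#' absorbed_dose(at, s_value_table()[7, ])
absorbed_dose <- function(a_tilde, s) {
  stopifnot(inherits(a_tilde, "cumulated_activity"))
  if (nrow(as.data.frame(s)) != 1L)
    stop("s must be a single S-value row")
  s <- as.data.frame(s)
  if (!identical(as.character(a_tilde$organ), as.character(s$organ)))
    stop(sprintf("organ mismatch: cumulated activity is '%s', S-value is '%s'",
                 a_tilde$organ, s$organ))
  data.frame(organ = a_tilde$organ,
             dose_gy_per_MBq = a_tilde$a_tilde_s_per_MBq * s$s_gy_per_bq_s,
             a_tilde_s_per_MBq = a_tilde$a_tilde_s_per_MBq,
             s_gy_per_bq_s = s$s_gy_per_bq_s,
             stringsAsFactors = FALSE)
}

#' Scale per-MBq doses to an administered activity
#'
#' Absorbed dose is linear in injected activity, so a Gy/MBq dose table
#' scales multiplicatively to the therapy administration; the standard
#' deviation of a linearly scaled variable scales by the same factor.
#'
#' @param doses Data frame with \code{dose_gy_per_MBq} and optionally
#'   \code{sd_gy_per_MBq} columns (e.g. from [cohort_dose_table()]).
#' @param administered_MBq Administered activity in MBq; > 0.
#' @return The input with added columns \code{dose_gy} and (when SD is
#'   present) \code{sd_gy}, plus an \code{administered_MBq} attribute.
#' @export
#' @examples
#' tab <- data.frame(organ = "Tumors", dose_gy_per_MBq = 0.592,
#'                   sd_gy_per_MBq = 0.522)
#' scale_to_administration(tab, 40)   # 23.68 +/- 20.88 Gy
scale_to_administration <- function(doses, administered_MBq) {
  if (!is.finite(administered_MBq) || administered_MBq <= 0)
    stop("administered_MBq must be positive")
  if (!"dose_gy_per_MBq" %in% names(doses))
    stop("doses must have a dose_gy_per_MBq column")
  doses$dose_gy <- doses$dose_gy_per_MBq * administered_MBq
  if ("sd_gy_per_MBq" %in% names(doses))
    doses$sd_gy <- doses$sd_gy_per_MBq * administered_MBq
  attr(doses, "administered_MBq") <- administered_MBq
  doses
}

#' Cohort dose summary table
#'
#' Aggregates per-mouse absorbed doses into mean and sample (n-1) standard
#' deviation per organ (and per tracer when present), in the deterministic
#' order of the packaged S-value table followed by tracer label. A single
#' animal yields SD 0 with \code{n_mice = 1}.
#'
#' @param per_mouse Data frame with columns \code{organ},
#'   \code{dose_gy_per_MBq} and optionally \code{tracer} and
#'   \code{mouse_id}.
#' @param organ_order Character vector fixing organ ordering; defaults to
#'   the packaged S-value table's organs (unknown organs are appended
#'   alphabetically).
#' @return Data frame: \code{organ}, (\code{tracer}),
#'   \code{dose_gy_per_MBq}, \code{sd_gy_per_MBq}, \code{n_mice}.
#' @export
cohort_dose_table <- function(per_mouse, organ_order = NULL) {
  if (!nrow(per_mouse)) stop("no per-mouse doses supplied")
  if (!all(c("organ", "dose_gy_per_MBq") %in% names(per_mouse)))
    stop("per_mouse needs organ and dose_gy_per_MBq columns")
  keys <- "organ"
  if ("tracer" %in% names(per_mouse)) keys <- c(keys, "tracer")
  f <- interaction(per_mouse[keys], drop = TRUE)
  rows <- lapply(split(per_mouse, f), function(g) {
    out <- g[1, keys, drop = FALSE]
    out$dose_gy_per_MBq <- mean(g$dose_gy_per_MBq)
    out$sd_gy_per_MBq <- if (nrow(g) > 1) stats::sd(g$dose_gy_per_MBq) else 0
    out$n_mice <- nrow(g)
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (is.null(organ_order)) organ_order <- s_value_table()$organ
  extra <- sort(setdiff(unique(tab$organ), organ_order))
  lev <- c(organ_order, extra)
  ord <- order(match(tab$organ, lev),
               if ("tracer" %in% keys) tab$tracer else seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Fit the MIRD dosimetry model to a biodistribution experiment
#'
#' The package's central estimator: takes raw gamma-counting measurements
#' (or pre-computed %IA/g records), builds time-activity curves per region,
#' integrates them to cumulated activities with an exponential tail floored
#' at the physical decay constant, and multiplies by self S-values to
#' obtain absorbed doses per organ in Gy per MBq injected, summarised over
#' mice.
#'
#' @param measurements Counting table (columns \code{mouse_id, organ,
#'   mass_g, activity_Bq, time_h, injected_MBq}, optional \code{tracer});
#'   alternatively pass biodistribution records via \code{records}.
#' @param svalues S-value table (default: the packaged mouse table). Organs
#'   without a matching S-value row are dropped with a message.
#' @param nuclide Radionuclide; default [lu177()].
#' @param scheme Integration scheme, see [cumulated_activity()].
#' @param curve_by \code{"mouse"}: integrate each animal's own curve, then
#'   average doses (longitudinal data); \code{"cohort"}: integrate the
#'   cohort-mean curve (cross-sectional designs where each animal
#'   contributes one time point).
#' @param decay_correct Decay-correct measurements to injection time.
#' @param counting_efficiency Counts-to-Bq efficiency, see
#'   [as_pct_ia_per_g()].
#' @param tail_window Points used for the tail-rate fit.
#' @param records Optional pre-computed %IA/g records (from
#'   [as_pct_ia_per_g()]); supply exactly one of \code{measurements} /
#'   \code{records}.
#'
#' @return An object of class \code{mird_fit} with components
#'   \code{doses} (cohort table), \code{per_mouse}, \code{tacs},
#'   \code{cumulated}, \code{records}, and the call settings. Methods:
#'   \code{print}, \code{summary}, \code{coef} (named Gy/MBq vector),
#'   \code{predict} (dose at an administered activity), \code{plot}.
#' @export
#' @examples
#' cfg <- default_cohort_config(n_mice = 4)
#' meas <- generate_biodist_cohort(cfg, seed = 7)
#' fit <- mird_fit(meas)
#' coef(fit)
#' predict(fit, administered_MBq = 40)
mird_fit <- function(measurements = NULL, svalues = s_value_table(),
                     nuclide = lu177(),
                     scheme = c("trapezoid_tail", "single_point_tail"),
                     curve_by = c("mouse", "cohort"),
                     decay_correct = TRUE, counting_efficiency = 1,
                     tail_window = 2, records = NULL) {
  scheme <- match.arg(scheme)
  curve_by <- match.arg(curve_by)
  if (is.null(measurements) == is.null(records))
    stop("supply exactly one of measurements or records")
  if (is.null(records))
    records <- as_pct_ia_per_g(measurements, nuclide,
                               decay_correct = decay_correct,
                               counting_efficiency = counting_efficiency)
  known <- unique(svalues$organ)
  drop <- setdiff(unique(records$organ), known)
  if (length(drop))
    message("no S-value for: ", paste(drop, collapse = ", "),
            " (dropped from dose table)")
  rec <- records[records$organ %in% known, , drop = FALSE]
  if (!nrow(rec)) stop("no measured organ matches the S-value table")

  tacs <- build_tacs(rec, by = curve_by)
  cums <- lapply(tacs, cumulated_activity, nuclide = nuclide,
                 scheme = scheme, tail_window = tail_window)

  smap <- svalues[match(vapply(cums, `[[`, "", "organ"), svalues$organ), ]
  per <- do.call(rbind, Map(function(cm, i) {
    d <- absorbed_dose(cm, smap[i, ])
    d
  }, cums, seq_along(cums)))
  if (curve_by == "mouse") {
    per$mouse_id <- vapply(tacs, `[[`, "", "mouse_id")
    tr <- unique(rec[c("mouse_id", if ("tracer" %in% names(rec)) "tracer")])
    if ("tracer" %in% names(tr))
      per$tracer <- tr$tracer[match(per$mouse_id, tr$mouse_id)]
  }
  rownames(per) <- NULL
  doses <- cohort_dose_table(per, organ_order = svalues$organ)
  structure(
    list(doses = doses, per_mouse = per, tacs = tacs, cumulated = cums,
         records = records, nuclide = nuclide, svalues = svalues,
         scheme = scheme, curve_by = curve_by,
         decay_correct = decay_correct, call = match.call()),
    class = "mird_fit"
  )
}

#' @export
print.mird_fit <- function(x, digits = 3, ...) {
  cat(sprintf("MIRD dosimetry fit (%s, curves per %s, nuclide %s)\n",
              x$scheme, x$curve_by, x$nuclide$name))
  cat(sprintf("%d region curve(s), %d animal(s)\n\n",
              length(x$tacs),
              length(unique(x$records$mouse_id))))
  print(format(x$doses, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.mird_fit <- function(object, ...) {
  stats::setNames(object$doses$dose_gy_per_MBq,
                  if ("tracer" %in% names(object$doses))
                    paste(object$doses$organ, object$doses$tracer, sep = ":")
                  else object$doses$organ)
}

#' @export
summary.mird_fit <- function(object, administered_MBq = NULL, ...) {
  out <- list(fit = object,
              doses = object$doses,
              lambda_tail = vapply(object$cumulated, `[[`, 0,
                                   "lambda_eff_per_h"))
  if (!is.null(administered_MBq))
    out$therapy <- scale_to_administration(object$doses, administered_MBq)
  class(out) <- "summary.mird_fit"
  out
}

#' @export
print.summary.mird_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("\ntail rates: %.3e - %.3e /h (physical floor %.3e /h)\n",
              min(x$lambda_tail), max(x$lambda_tail),
              x$fit$nuclide$lambda_phys_per_h))
  if (!is.null(x$therapy)) {
    cat(sprintf("\nscaled to %g MBq administered:\n",
                attr(x$therapy, "administered_MBq")))
    print(format(x$therapy, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Predict absorbed doses for an administered activity
#'
#' @param object A [mird_fit()] object.
#' @param administered_MBq Administered activity in MBq (default 1, i.e.
#'   the per-MBq table itself).
#' @param ... Unused.
#' @return Dose table in Gy for the administration, via
#'   [scale_to_administration()].
#' @export
predict.mird_fit <- function(object, administered_MBq = 1, ...) {
  scale_to_administration(object$doses, administered_MBq)
}

#' Plot a dosimetry fit
#'
#' Left panel: region time-activity curves (fraction of injected activity,
#' log scale). Right panel: cohort mean absorbed dose per organ with SD
#' error bars.
#'
#' @param x A [mird_fit()] object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mird_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  all_t <- unlist(lapply(x$tacs, `[[`, "times_h"))
  all_a <- unlist(lapply(x$tacs, `[[`, "frac_ia"))
  pos <- all_a[all_a > 0]
  graphics::plot(NA, xlim = range(0, all_t), ylim = range(pos),
                 log = "y", xlab = "time post injection (h)",
                 ylab = "fraction of injected activity", main = "TACs")
  for (i in seq_along(x$tacs)) {
    tc <- x$tacs[[i]]
    graphics::lines(tc$times_h, pmax(tc$frac_ia, min(pos)), col = i, type = "b",
                    pch = 16, cex = 0.6)
  }
  d <- x$doses
  lab <- if ("tracer" %in% names(d)) paste(d$organ, d$tracer) else d$organ
  bp <- graphics::barplot(d$dose_gy_per_MBq, names.arg = lab, las = 2,
                          ylab = "absorbed dose (Gy/MBq)",
                          main = "Cohort doses", ...)
  graphics::arrows(bp, pmax(d$dose_gy_per_MBq - d$sd_gy_per_MBq, 0),
                   bp, d$dose_gy_per_MBq + d$sd_gy_per_MBq,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
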