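#' Peritoneal carcinomatosis index region grid
#'
#' Thirteen abdominopelvic regions (nine quadrants plus four small-bowel
#' segments), each scored 0-3 by largest lesion size, giving a total index
#' of 0-39. The exact rodent-adapted region names vary between labs, so
#' region ids are free-form labels: any 13-region dialect works as long as
#' ids are used consistently.
#'
#' @return Character vector of 13 default region ids.
#' @export
pci_regions <- function() {
  c("central", "right_upper", "epigastrium", "left_upper", "left_flank",
    "left_lower", "pelvis", "right_lower", "right_flank",
    "upper_jejunum", "lower_jejunum", "upper_ileum", "lower_ileum")
}

#' Per-animal lesion score map
#'
#' @param mouse_id Animal identifier.
#' @param region_scores Named integer vector/list of lesion-size scores in
#'   \{0, 1, 2, 3\}; names are region ids from \code{regions}. Missing
#'   regions count as 0.
#' @param regions Valid region ids (default [pci_regions()]); at most 13.
#' @return Object of class \code{pci_map}.
#' @export
#' @examples
#' pci_map("m1", c(central = 2, pelvis = 3, left_flank = 1))
pci_map <- function(mouse_id, region_scores = integer(),
                    regions = pci_regions()) {
  if (length(regions) > 13L)
    stop("at most 13 regions in the scoring grid")
  scores <- unlist(region_scores)
  if (length(scores)) {
    if (is.null(names(scores)) || any(!nzchar(names(scores))))
      stop("region_scores must be named by region id")
    unknown <- setdiff(names(scores), regions)
    if (length(unknown))
      stop("unknown region id(s): ", paste(unknown, collapse = ", "))
    if (any(!scores %in% 0:3))
      stop("lesion scores must be integers in {0, 1, 2, 3}")
  }
  full <- stats::setNames(integer(length(regions)), regions)
  full[names(scores)] <- as.integer(scores)
  structure(list(mouse_id = mouse_id, region_scores = full,
                 regions = regions),
            class = "pci_map")
}

#' Total peritoneal carcinomatosis index of one animal
#'
#' Sum of the per-region lesion-size scores; ranges 0 (no visible lesion)
#' to 39 (all 13 regions at the maximal score). Tumor-bearing animals in
#' practice score at least 1.
#'
#' @param map A [pci_map()].
#' @return Integer total score.
#' @export
#' @examples
#' pci_total(pci_map("m1", c(central = 2, left_flank = 3, right_flank = 1)))
pci_total <- function(map) {
  stopifnot(inherits(map, "pci_map"))
  sum(map$region_scores)
}

#' @export
print.pci_map <- function(x, ...) {
  nz <- x$region_scores[x$region_scores > 0]
  cat(sprintf("<pci_map> %s: total %d (%d region(s) involved)\n",
              x$mouse_id, pci_total(x), length(nz)))
  if (length(nz)) print(nz)
  invisible(x)
}

#' Group summaries of PCI scores
#'
#' Per-group mean and dispersion of the total index, in deterministic
#' (alphabetical) group order.
#'
#' @param maps List of [pci_map()] objects.
#' @param groups Character vector assigning each map to a treatment group.
#' @param dispersion \code{"sd"} (sample standard deviation, default) or
#'   \code{"sem"} (standard error of the mean).
#' @return Data frame: \code{group}, \code{mean_pci}, \code{dispersion},
#'   \code{n}.
#' @export
group_pci_summary <- function(maps, groups, dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  stopifnot(length(maps) == length(groups), length(maps) >= 1L)
  totals <- vapply(maps, pci_total, 0L)
  rows <- lapply(sort(unique(as.character(groups))), function(g) {
    x <- totals[groups == g]
    if (!length(x)) stop("empty group: ", g)
    s <- if (length(x) > 1) stats::sd(x) else 0
    if (dispersion == "sem") s <- s / sqrt(length(x))
    data.frame(group = g, mean_pci = mean(x), dispersion = s, n = length(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "dispersion") <- dispersion
  out
}

#' Normalised tumor-growth trajectories from bioluminescence flux
#'
#' Divides each animal's total flux by its own baseline measurement, which
#' cancels per-mouse calibration constants, and summarises each group by
#' the geometric mean of the ratios (flux is log-normally dispersed).
#' Measurements after the linearity cut-off day are excluded; animals
#' without a baseline measurement are dropped with a warning.
#'
#' @param records Data frame: \code{mouse_id}, \code{group}, \code{day},
#'   \code{total_flux} (photons/s, >= 0).
#' @param baseline_day Day whose flux normalises each mouse (must be > 0
#'   flux).
#' @param max_day Last day included; default 20, beyond which the
#'   bioluminescence signal is no longer linear in tumor burden.
#' @return List with \code{per_mouse} (records plus \code{ratio}) and
#'   \code{per_group} (\code{group}, \code{day}, \code{geo_mean_ratio},
#'   \code{n}).
#' @export
growth_ratio <- function(records, baseline_day = NULL, max_day = 20) {
  req <- c("mouse_id", "group", "day", "total_flux")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("growth records lack columns: ", paste(miss, collapse = ", "))
  if (any(records$total_flux < 0)) stop("total_flux must be non-negative")
  records <- records[records$day <= max_day, , drop = FALSE]
  if (is.null(baseline_day)) baseline_day <- min(records$day)
  base <- records[records$day == baseline_day, c("mouse_id", "total_flux")]
  names(base)[2] <- "baseline_flux"
  keep_ids <- base$mouse_id[base$baseline_flux > 0]
  dropped <- setdiff(unique(records$mouse_id), keep_ids)
  if (length(dropped))
    warning("dropped mice without positive baseline flux: ",
            paste(dropped, collapse = ", "))
  rec <- merge(records[records$mouse_id %in% keep_ids, ], base,
               by = "mouse_id")
  rec$ratio <- rec$total_flux / rec$baseline_flux
  grp <- stats::aggregate(ratio ~ group + day, data = rec,
                          FUN = function(x) exp(mean(log(pmax(x, .Machine$double.xmin)))))
  names(grp)[names(grp) == "ratio"] <- "geo_mean_ratio"
  ngrp <- stats::aggregate(ratio ~ group + day, data = rec, FUN = length)
  grp$n <- ngrp$ratio
  grp <- grp[order(grp$group, grp$day), ]
  rownames(grp) <- NULL
  list(per_mouse = rec[order(rec$mouse_id, rec$day), ], per_group = grp)
}

#' Read / write PCI score CSVs
#'
#' Long format: one row per mouse x region with columns \code{mouse_id},
#' \code{region_id}, \code{score}.
#'
#' @param path CSV path.
#' @param regions Valid region ids.
#' @return List of [pci_map()] objects (one per mouse).
#' @export
read_pci_csv <- function(path, regions = pci_regions()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("mouse_id", "region_id", "score")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  lapply(split(df, df$mouse_id), function(g)
    pci_map(g$mouse_id[1], stats::setNames(g$score, g$region_id), regions))
}

#' @rdname read_pci_csv
#' @param maps List of [pci_map()] objects.
#' @export
write_pci_csv <- function(maps, path) {
  rows <- lapply(maps, function(m)
    data.frame(mouse_id = m$mouse_id, region_id = names(m$region_scores),
               score = unname(m$region_scores), stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
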