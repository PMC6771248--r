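#' Pipeline run configuration
#'
#' One run works either from real input CSVs or from a synthetic cohort
#' configuration — exactly one of the two. The seed is recorded in every
#' output header so runs are reproducible byte for byte.
#'
#' @param counting_csv,pci_csv,growth_csv Paths to real input CSVs
#'   (optional).
#' @param synthetic A [cohort_config()] for simulated inputs (optional).
#' @param nuclide_name Nuclide looked up in the packaged table.
#' @param scheme Integration scheme, see [cumulated_activity()].
#' @param decay_correct Decay-correct to injection time.
#' @param curve_by Curve construction, see [mird_fit()].
#' @param administered_MBq Therapy activity for the scaled dose columns;
#'   \code{NULL} for per-MBq only.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for any synthetic generation.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(counting_csv = NULL, pci_csv = NULL,
                       growth_csv = NULL, synthetic = NULL,
                       nuclide_name = "Lu-177",
                       scheme = "trapezoid_tail", decay_correct = TRUE,
                       curve_by = "mouse", administered_MBq = NULL,
                       out_dir = ".", seed = 1) {
  real <- !is.null(counting_csv) || !is.null(pci_csv) || !is.null(growth_csv)
  if (real && !is.null(synthetic))
    stop("supply either real input CSVs or a synthetic config, not both")
  if (!real && is.null(synthetic))
    stop("supply real input CSVs or a synthetic config")
  structure(list(counting_csv = counting_csv, pci_csv = pci_csv,
                 growth_csv = growth_csv, synthetic = synthetic,
                 nuclide_name = nuclide_name, scheme = scheme,
                 decay_correct = decay_correct, curve_by = curve_by,
                 administered_MBq = administered_MBq,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [run_config()]; a
#' \code{synthetic:} mapping with \code{n_mice}, \code{tracer},
#' \code{organ_specs} (list of records), \code{injected_MBq},
#' \code{counting_efficiency}, \code{pci_group_specs} and
#' \code{growth_specs} builds a [cohort_config()]; \code{synthetic:
#' default} uses [default_cohort_config()].
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- y$synthetic
  if (!is.null(syn)) {
    syn <- if (identical(syn, "default")) {
      default_cohort_config()
    } else {
      os <- do.call(rbind, lapply(syn$organ_specs, as.data.frame))
      pci <- if (!is.null(syn$pci_group_specs))
        do.call(rbind, lapply(syn$pci_group_specs, as.data.frame))
      cohort_config(syn$n_mice %||% 6, syn$tracer %||% "Tz-2", os,
                    injected_MBq = syn$injected_MBq %||% 10,
                    counting_efficiency = syn$counting_efficiency %||% 1,
                    pci_group_specs = pci,
                    growth_specs = syn$growth_specs)
    }
  }
  run_config(counting_csv = y$counting_csv, pci_csv = y$pci_csv,
             growth_csv = y$growth_csv, synthetic = syn,
             nuclide_name = y$nuclide_name %||% "Lu-177",
             scheme = y$scheme %||% "trapezoid_tail",
             decay_correct = y$decay_correct %||% TRUE,
             curve_by = y$curve_by %||% "mouse",
             administered_MBq = y$administered_MBq,
             out_dir = y$out_dir %||% ".", seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.out_header <- function(config) {
  sprintf("mirdose %s | seed %d | scheme %s | decay_correct %s",
          as.character(utils::packageVersion("mirdose")),
          config$seed, config$scheme, config$decay_correct)
}

# Atomic CSV write: build in a temp file, rename into place, so a failure
# leaves no partial output.
.write_atomic <- function(df, path, header) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, "w")
  writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

.ensure_outdir <- function(config) {
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  config$out_dir
}

#' Pipeline commands
#'
#' Thin deterministic drivers over the package's functions, one per
#' pipeline stage; each writes CSV outputs whose first line records the
#' tool version, seed and scheme. \code{cmd_simulate} emits synthetic
#' counting, PCI and growth tables; \code{cmd_biodist} quantifies %IA/g;
#' \code{cmd_dose} fits the dosimetry model and writes the dose table;
#' \code{cmd_pci} writes group PCI summaries; \code{cmd_report} writes a
#' combined dose report (S-value, reference mass, mean and SD per tracer,
#' and — when an administered activity is configured — the scaled therapy
#' dose), as CSV and as a markdown table.
#'
#' @param config A [run_config()].
#' @return Named character vector of the files written, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$synthetic)) stop("cmd_simulate needs a synthetic config")
  dir <- .ensure_outdir(config)
  h <- .out_header(config)
  meas <- generate_biodist_cohort(config$synthetic, config$seed,
                                  load_nuclide(config$nuclide_name))
  files <- c(counting = file.path(dir, "counting.csv"))
  .write_atomic(meas[setdiff(names(meas), "true_pct_ia_per_g")],
                files[["counting"]], h)
  if (!is.null(config$synthetic$pci_group_specs)) {
    pc <- generate_pci_cohort(config$synthetic, config$seed)
    rows <- do.call(rbind, Map(function(m, g) {
      data.frame(mouse_id = m$mouse_id, group = g,
                 region_id = names(m$region_scores),
                 score = unname(m$region_scores), stringsAsFactors = FALSE)
    }, pc$maps, pc$groups))
    files["pci"] <- file.path(dir, "pci.csv")
    .write_atomic(rows, files[["pci"]], h)
  }
  if (!is.null(config$synthetic$growth_specs)) {
    gr <- generate_growth_cohort(config$synthetic, config$seed)
    files["growth"] <- file.path(dir, "growth.csv")
    .write_atomic(gr, files[["growth"]], h)
  }
  invisible(files)
}

.load_measurements <- function(config) {
  if (!is.null(config$counting_csv)) {
    read_counting_csv(config$counting_csv)
  } else if (!is.null(config$synthetic)) {
    generate_biodist_cohort(config$synthetic, config$seed,
                            load_nuclide(config$nuclide_name))
  } else stop("no counting input configured")
}

#' @rdname cmd_simulate
#' @export
cmd_biodist <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- .ensure_outdir(config)
  nuc <- load_nuclide(config$nuclide_name)
  rec <- as_pct_ia_per_g(.load_measurements(config), nuc,
                         decay_correct = config$decay_correct)
  path <- file.path(dir, "biodist.csv")
  .write_atomic(rec, path, .out_header(config))
  invisible(c(biodist = path))
}

#' @rdname cmd_simulate
#' @export
cmd_dose <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- .ensure_outdir(config)
  fit <- mird_fit(.load_measurements(config),
                  nuclide = load_nuclide(config$nuclide_name),
                  scheme = config$scheme, curve_by = config$curve_by,
                  decay_correct = config$decay_correct)
  tab <- fit$doses
  if (!is.null(config$administered_MBq))
    tab <- scale_to_administration(tab, config$administered_MBq)
  path <- file.path(dir, "dose.csv")
  .write_atomic(tab, path, .out_header(config))
  invisible(c(dose = path))
}

#' @rdname cmd_simulate
#' @export
cmd_pci <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- .ensure_outdir(config)
  if (!is.null(config$pci_csv)) {
    df <- utils::read.csv(config$pci_csv, stringsAsFactors = FALSE,
                          comment.char = "#")
    if (!all(c("mouse_id", "region_id", "score") %in% names(df)))
      stop(config$pci_csv, ": needs mouse_id, region_id, score columns")
    grp_col <- if ("group" %in% names(df)) df$group[!duplicated(df$mouse_id)]
               else rep("all", length(unique(df$mouse_id)))
    maps <- lapply(split(df, df$mouse_id), function(g)
      pci_map(g$mouse_id[1], stats::setNames(g$score, g$region_id)))
    groups <- grp_col[match(names(maps), unique(df$mouse_id))]
  } else if (!is.null(config$synthetic)) {
    pc <- generate_pci_cohort(config$synthetic, config$seed)
    maps <- pc$maps; groups <- pc$groups
  } else stop("no PCI input configured")
  summ <- group_pci_summary(maps, groups)
  path <- file.path(dir, "pci_summary.csv")
  .write_atomic(summ, path, .out_header(config))
  invisible(c(pci_summary = path))
}

#' @rdname cmd_simulate
#' @export
cmd_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- .ensure_outdir(config)
  fit <- mird_fit(.load_measurements(config),
                  nuclide = load_nuclide(config$nuclide_name),
                  scheme = config$scheme, curve_by = config$curve_by,
                  decay_correct = config$decay_correct)
  sv <- fit$svalues
  tab <- merge(sv[c("organ", "s_gy_per_bq_s", "ref_mass_g")], fit$doses,
               by = "organ", sort = FALSE)
  tab <- tab[match(intersect(sv$organ, tab$organ), tab$organ), ]
  if (!is.null(config$administered_MBq))
    tab <- scale_to_administration(tab, config$administered_MBq)
  path <- file.path(dir, "dose_report.csv")
  .write_atomic(tab, path, .out_header(config))
  md <- file.path(dir, "dose_report.md")
  writeLines(format_markdown_table(tab), md)
  invisible(c(report = path, report_md = md))
}

#' Render a data frame as a markdown pipe table
#'
#' @param df Data frame; numeric columns are formatted with
#'   \code{signif(digits)}.
#' @param digits Significant digits.
#' @return Character vector of markdown lines.
#' @export
format_markdown_table <- function(df, digits = 4) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(signif(col, digits), trim = TRUE)
    else as.character(col)
  }, character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
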