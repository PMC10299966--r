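#' Read and validate a country-year estimate panel
#'
#' Reads a delimited country-panel file (comma by default), optionally
#' renames columns through a user mapping, fills missing bound columns from
#' the point estimates (with a warning), and validates every row against the
#' estimate invariants via [validate_panel()]. All violations are collected
#' and reported together with row numbers; a file with any violation is
#' rejected.
#'
#' @param path path to the delimited file; a header row is required.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(mmr = "MatMort")`.
#' @param sep field separator, default comma.
#' @param year_range allowed year range, passed to [validate_panel()].
#' @return validated panel data frame with attribute `rows_read`.
#' @export
read_panel <- function(path, column_map = NULL, sep = ",",
                       year_range = c(1950, 2030)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  panel <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    if (is.null(names(column_map))) {
      stop("`column_map` must be named: canonical_name = \"file column\"",
           call. = FALSE)
    }
    for (canon in names(column_map)) {
      from <- column_map[[canon]]
      if (!from %in% names(panel)) {
        stop(sprintf("column_map refers to missing column \"%s\"", from),
             call. = FALSE)
      }
      names(panel)[names(panel) == from] <- canon
    }
  }
  missing_core <- setdiff(c("country_id", "year", "mmr", "sbr", "nmr"),
                          names(panel))
  if (length(missing_core)) {
    stop("panel file lacks required column(s): ",
         paste(missing_core, collapse = ", "), call. = FALSE)
  }
  for (ind in c("mmr", "sbr", "nmr")) {
    for (side in c("_lower", "_upper")) {
      bc <- paste0(ind, side)
      if (!bc %in% names(panel)) {
        warning(sprintf("column %s absent: defaulting to the point estimate",
                        bc), call. = FALSE)
        panel[[bc]] <- panel[[ind]]
      }
    }
  }
  num_cols <- setdiff(panel_columns(), c("country_id", "year"))
  for (cn in c("year", num_cols)) {
    if (!is.numeric(panel[[cn]])) {
      suppressWarnings(conv <- as.numeric(panel[[cn]]))
      bad <- which(is.na(conv) & !is.na(panel[[cn]]) &
                     nzchar(trimws(panel[[cn]])))
      if (length(bad)) {
        stop(sprintf("malformed numeric in column %s, row(s): %s", cn,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      panel[[cn]] <- conv
    }
  }
  validate_panel(panel, year_range = year_range)
  structure(panel, rows_read = nrow(panel))
}

#' Read phase thresholds from a YAML file
#'
#' Loads a thresholds file with two four-element lists, `mmr_knots` and
#' `sbn_knots`, and validates them as a [phase_thresholds()] object. Invalid
#' files (wrong length, non-decreasing values) are rejected at load, before
#' any computation.
#'
#' @param path path to the YAML file.
#' @return a `phase_thresholds` object.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (!all(c("mmr_knots", "sbn_knots") %in% names(y))) {
    stop("thresholds file must define mmr_knots and sbn_knots",
         call. = FALSE)
  }
  phase_thresholds(as.numeric(y$mmr_knots), as.numeric(y$sbn_knots))
}

#' Run the full transition analysis and assemble a report bundle
#'
#' Orchestrates the pipeline on an in-memory panel: classifies every
#' country-year, tabulates phase counts per year, summarises transitions
#' between the first and last year, computes the knot ratios, the
#' uncertainty sensitivity, phase profiles for every requested covariate,
#' and wealth-equity summaries. The result is deterministic given its
#' inputs. With `outdir` set, each table is written as a CSV and a
#' machine-readable JSON summary (with provenance: package version,
#' thresholds, row counts) is written alongside.
#'
#' @param panel validated country-year estimate panel.
#' @param covariates optional long-format covariate table.
#' @param quintiles optional wealth-quintile coverage table.
#' @param thresholds a [phase_thresholds()] object.
#' @param variant estimate variant to classify, default `"point"`.
#' @param mode SBN combination mode, see [combine_sbn()].
#' @param ipi_tolerance linearity tolerance of the inequality patterns
#'   index, percentage points.
#' @param outdir optional directory to write the report files into.
#' @return list of class `transition_report`: `phase_counts`,
#'   `assignments`, `transitions` (when the panel spans two or more years),
#'   `knot_ratios`, `uncertainty` (per year), `profiles`, `equity`, and
#'   `provenance`.
#' @export
run_report <- function(panel, covariates = NULL, quintiles = NULL,
                       thresholds = phase_thresholds(),
                       variant = "point",
                       mode = c("approximate", "exact"),
                       ipi_tolerance = 5, outdir = NULL) {
  mode <- match.arg(mode)
  thresholds <- as_phase_thresholds(thresholds)
  validate_panel(panel)
  years <- sort(unique(panel$year))
  assignments <- classify_phases(panel, thresholds, variant = variant,
                                 mode = mode)
  counts <- as.data.frame(summary(assignments)$counts)
  names(counts) <- c("year", "phase", "n")

  transitions <- NULL
  if (length(years) >= 2) {
    t0 <- assignments[assignments$year == years[1], ]
    t1 <- assignments[assignments$year == years[length(years)], ]
    rec <- transition_records(t0, t1)
    transitions <- list(year_t0 = years[1], year_t1 = years[length(years)],
                        matrix = transition_matrix(t0, t1),
                        summary = progression_summary(rec))
  }

  has_bounds <- all(c("mmr_lower", "mmr_upper") %in% names(panel)) &&
    !anyNA(panel[c("mmr_lower", "mmr_upper", "sbr_lower", "sbr_upper",
                   "nmr_lower", "nmr_upper")])
  uncertainty <- if (has_bounds) {
    lapply(stats::setNames(years, years), function(y) {
      sp <- uncertainty_phase_span(panel, thresholds, year = y, mode = mode)
      list(mean_span = sp$mean_span, n = sp$n)
    })
  }

  profiles <- NULL
  if (!is.null(covariates)) {
    inds <- unique(covariates$indicator)
    profiles <- do.call(rbind, lapply(inds, function(ind) {
      do.call(rbind, lapply(years, function(y) {
        prof <- phase_summaries(covariates, assignments, ind, year = y)
        cbind(year = y, as.data.frame(prof))
      }))
    }))
    rownames(profiles) <- NULL
  }

  equity <- NULL
  if (!is.null(quintiles)) {
    ib <- quintiles[quintiles$indicator == "institutional_birth", ,
                    drop = FALSE]
    ineq <- if (nrow(ib)) inequality_pattern_index(ib, ipi_tolerance)
    csec <- if (any(quintiles$indicator == "csec")) {
      csec_quintile_summary(quintiles, assignments)
    }
    equity <- list(institutional_birth = ineq, csec_by_phase = csec)
  }

  report <- structure(
    list(phase_counts = counts,
         assignments = assignments,
         transitions = transitions,
         knot_ratios = knot_ratios(thresholds),
         uncertainty = uncertainty,
         profiles = profiles,
         equity = equity,
         provenance = list(
           package = "mortrans",
           version = as.character(utils::packageVersion("mortrans")),
           thresholds = unclass(thresholds),
           variant = variant, mode = mode,
           n_rows = nrow(panel), years = years)),
    class = "transition_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(x, name) {
    utils::write.csv(x, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  out(report$phase_counts, "phase_counts")
  out(as.data.frame(report$assignments), "assignments")
  out(report$knot_ratios, "knot_ratios")
  if (!is.null(report$transitions)) {
    out(as.data.frame.matrix(report$transitions$matrix), "transition_matrix")
  }
  if (!is.null(report$profiles)) out(report$profiles, "profiles")
  if (!is.null(report$equity$institutional_birth)) {
    out(report$equity$institutional_birth, "equity_institutional_birth")
  }
  if (!is.null(report$equity$csec_by_phase)) {
    out(report$equity$csec_by_phase, "equity_csec_by_phase")
  }
  summary_json <- list(
    provenance = report$provenance,
    phase_counts = report$phase_counts,
    knot_ratios = report$knot_ratios,
    uncertainty = report$uncertainty,
    progression = if (!is.null(report$transitions)) {
      unclass(report$transitions$summary)
    })
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.transition_report <- function(x, ...) {
  cat("Mortality transition report\n")
  cat(sprintf("  %d country-years classified (variant = %s, mode = %s)\n",
              x$provenance$n_rows, x$provenance$variant, x$provenance$mode))
  tab <- stats::xtabs(n ~ year + phase, data = x$phase_counts)
  print(tab)
  if (!is.null(x$transitions)) print(x$transitions$summary)
  invisible(x)
}
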