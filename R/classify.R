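#' Classify one mortality indicator against four decreasing knots
#'
#' Assigns the phase implied by a single indicator: phase 1 while the value
#' is at or above the first knot, phase k while it lies in `[knots[k],
#' knots[k-1])`, and phase 5 once it is below the fourth knot. Values exactly
#' at a knot stay in the higher-mortality phase: a country has reached the
#' next phase only when the indicator has dropped *below* the threshold
#' (phase 1 is ">= 700", phase 5 is "< 20" on the maternal scale).
#'
#' @param value non-negative rate(s), on the same scale as `knots`.
#' @param knots strictly decreasing positive numeric of length 4.
#' @return integer phase(s) in 1--5; `NA` values propagate.
#' @examples
#' classify_indicator(c(700, 650, 19.99), c(700, 300, 100, 20))  # 1 2 5
#' @export
classify_indicator <- function(value, knots) {
  check_knots(knots, "knots")
  if (any(value < 0, na.rm = TRUE)) {
    stop("`value` must be non-negative", call. = FALSE)
  }
  # phase = 1 + number of knots the value has fallen strictly below
  out <- 5L - findInterval(value, sort(knots))
  out[is.na(value)] <- NA_integer_
  as.integer(out)
}

#' Classify countries into transition phases
#'
#' Applies the dual-threshold rule to a country-year panel: each country's
#' maternal mortality ratio and combined stillbirth-plus-neonatal rate are
#' classified separately against their knot vectors, and the country's phase
#' is the minimum of the two -- it has reached a phase only when *both*
#' indicators have passed the required thresholds.
#'
#' The `variant` selects which estimate is classified: the point estimate or
#' the lower/upper uncertainty bound. Because lower bounds mean lower
#' mortality, the phase under `"lower"` is always at least the phase under
#' `"point"`, which is at least the phase under `"upper"`.
#'
#' Rows with a missing value in any required column are excluded (never
#' imputed); their count is reported via a message and the `n_dropped`
#' attribute.
#'
#' @param panel country-year estimate data frame (see [validate_panel()] for
#'   the column contract; bound columns are only required for the bound
#'   variants).
#' @param thresholds a [phase_thresholds()] object.
#' @param variant which estimate to classify: `"point"` (default),
#'   `"lower"`, or `"upper"`.
#' @param mode how stillbirth and neonatal rates are combined; see
#'   [combine_sbn()].
#' @return a `phase_assignment` data frame with columns `country_id`,
#'   `year`, `phase_mmr`, `phase_sbn`, `phase`, `variant`, and attributes
#'   `thresholds`, `mode`, `n_dropped`.
#' @examples
#' panel <- data.frame(country_id = "A", year = 2020,
#'                     mmr = 650, sbr = 40, nmr = 45)
#' classify_phases(panel)  # phase_mmr 2, phase_sbn 1, phase 1
#' @export
classify_phases <- function(panel,
                            thresholds = phase_thresholds(),
                            variant = c("point", "lower", "upper"),
                            mode = c("approximate", "exact")) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  thresholds <- as_phase_thresholds(thresholds)
  suffix <- switch(variant, point = "", lower = "_lower", upper = "_upper")
  cols <- paste0(c("mmr", "sbr", "nmr"), suffix)
  missing_cols <- setdiff(c("country_id", "year", cols), names(panel))
  if (length(missing_cols)) {
    stop(sprintf("panel lacks column(s) required for variant \"%s\": %s",
                 variant, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  keep <- stats::complete.cases(panel[cols])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    bad <- panel[!keep, c("country_id", "year")]
    message(sprintf(
      "classify_phases: %d row(s) dropped for missing %s estimates (%s)",
      n_dropped, variant,
      paste(utils::head(paste(bad$country_id, bad$year), 5), collapse = ", ")))
  }
  used <- panel[keep, , drop = FALSE]
  mmr <- used[[cols[1]]]
  sbn <- combine_sbn(used[[cols[2]]], used[[cols[3]]], mode = mode)
  phase_mmr <- classify_indicator(mmr, thresholds$mmr_knots)
  phase_sbn <- classify_indicator(sbn, thresholds$sbn_knots)
  out <- data.frame(country_id = used$country_id,
                    year = used$year,
                    phase_mmr = phase_mmr,
                    phase_sbn = phase_sbn,
                    phase = pmin(phase_mmr, phase_sbn),
                    variant = variant,
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("phase_assignment", "data.frame"),
            thresholds = thresholds, mode = mode, n_dropped = n_dropped)
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat(sprintf("Phase assignments (%d country-years, variant = %s)\n",
              nrow(x), unique(x$variant)))
  print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.phase_assignment <- function(object, ...) {
  tab <- table(year = object$year,
               phase = factor(object$phase, levels = 1:5))
  structure(list(counts = tab, n = nrow(object),
                 n_dropped = attr(object, "n_dropped")),
            class = "summary.phase_assignment")
}

#' @export
print.summary.phase_assignment <- function(x, ...) {
  cat(sprintf("Phase distribution over %d classified country-years", x$n))
  if (isTRUE(x$n_dropped > 0)) cat(sprintf(" (%d dropped)", x$n_dropped))
  cat("\n")
  print(x$counts)
  invisible(x)
}

#' Sensitivity of phase classification to estimate uncertainty
#'
#' Reclassifies every country in a given year under the lower and upper
#' uncertainty bounds of its estimates and measures, per country, how many
#' phases separate the two classifications (lower-bound phase minus
#' upper-bound phase; non-negative because lower bounds mean lower
#' mortality). The mean span over countries summarises how sensitive the
#' phase map is to estimate uncertainty -- about half a phase for the UN
#' estimate intervals.
#'
#' @param panel country-year estimate panel carrying both bounds.
#' @param thresholds a [phase_thresholds()] object.
#' @param year the calendar year to analyse.
#' @param mode combination mode, see [combine_sbn()].
#' @return list with `per_country` (data frame: `country_id`, `phase_lower`,
#'   `phase_upper`, `span`), `mean_span` (unrounded; round to one decimal
#'   for display), `n` countries compared, and `n_excluded` countries that
#'   lacked a bound.
#' @export
uncertainty_phase_span <- function(panel,
                                   thresholds = phase_thresholds(),
                                   year,
                                   mode = c("approximate", "exact")) {
  mode <- match.arg(mode)
  rows <- panel[!is.na(panel$year) & panel$year == year, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop(sprintf("panel has no rows for year %s", year), call. = FALSE)
  }
  lo <- classify_phases(rows, thresholds, variant = "lower", mode = mode)
  hi <- classify_phases(rows, thresholds, variant = "upper", mode = mode)
  merged <- merge(lo[c("country_id", "phase")],
                  hi[c("country_id", "phase")],
                  by = "country_id", suffixes = c("_lower", "_upper"))
  merged$span <- merged$phase_lower - merged$phase_upper
  if (nrow(merged) == 0) {
    stop("no country carries both bounds for the requested year",
         call. = FALSE)
  }
  n_excluded <- nrow(rows) - nrow(merged)
  if (n_excluded > 0) {
    message(sprintf("uncertainty_phase_span: %d country(ies) excluded for missing bounds",
                    n_excluded))
  }
  list(per_country = merged,
       mean_span = mean(merged$span),
       n = nrow(merged),
       n_excluded = n_excluded)
}
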