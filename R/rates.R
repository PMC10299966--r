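#' Combine stillbirth and neonatal mortality into one rate
#'
#' Maternal deaths are several orders of magnitude rarer than stillbirths and
#' neonatal deaths, so the transition model keeps maternal mortality separate
#' but merges the stillbirth rate (per 1000 total births) and the neonatal
#' mortality rate (per 1000 livebirths) into a single stillbirth-plus-neonatal
#' (SBN) rate per 1000 total births.
#'
#' Two conventions are available. `"approximate"` (the default) is the simple
#' sum `sbr + nmr`, which treats the two denominators as interchangeable; the
#' model's published knots behave as such sums (a neonatal threshold of 45
#' and a stillbirth contribution of 35 giving the phase-1 knot of 80).
#' `"exact"` rescales neonatal deaths from livebirths to total births before
#' adding: `sbr + nmr * (1 - sbr / 1000)`. The two differ by at most
#' `sbr * nmr / 1000`, under 4% of the total at the highest observed rates.
#'
#' @param sbr stillbirths per 1000 total births; `0 <= sbr < 1000`.
#' @param nmr neonatal deaths per 1000 livebirths; `nmr >= 0`.
#' @param mode `"approximate"` (simple sum, default) or `"exact"`
#'   (denominator-adjusted).
#' @return stillbirths plus neonatal deaths per 1000 total births, vectorised
#'   over `sbr` and `nmr`.
#' @examples
#' combine_sbn(35, 45)                  # 80, the phase-1/2 knot
#' combine_sbn(35, 45, mode = "exact")  # 78.425
#' @export
combine_sbn <- function(sbr, nmr, mode = c("approximate", "exact")) {
  mode <- match.arg(mode)
  if (any(sbr < 0, na.rm = TRUE)) {
    stop("`sbr` must be non-negative", call. = FALSE)
  }
  if (any(sbr >= 1000, na.rm = TRUE)) {
    stop("`sbr` must be below 1000 per 1000 total births", call. = FALSE)
  }
  if (any(nmr < 0, na.rm = TRUE)) {
    stop("`nmr` must be non-negative", call. = FALSE)
  }
  if (mode == "exact") sbr + nmr * (1 - sbr / 1000) else sbr + nmr
}

#' Ratio of stillbirth and neonatal deaths to maternal deaths
#'
#' Computes the dimensionless ratio of stillbirth-plus-neonatal deaths to
#' maternal deaths, the quantity that rises from about 11 at the phase 1/2
#' knot to 75 at the phase 4/5 knot as mortality declines. Because SBN is
#' per 1000 total births and MMR per 100,000 livebirths, the ratio is
#' `100 * sbn / mmr` under the approximation total births ~ livebirths. When
#' the livebirth share of total births is known, pass it as `lb_frac` to
#' correct the denominator (the error of omitting it is below 4% even at a
#' stillbirth rate of 35 per 1000).
#'
#' A zero `mmr` makes the ratio undefined. With scalar input this is an
#' error; with vector input the affected elements are returned as `NA` with
#' a warning giving the count, so one degenerate row cannot abort a
#' multi-country run.
#'
#' @param sbn stillbirths plus neonatal deaths per 1000 total births.
#' @param mmr maternal deaths per 100,000 livebirths.
#' @param lb_frac livebirths as a fraction of total births (default 1).
#' @return the unrounded ratio, vectorised; `NA` where `mmr` is 0 (vector
#'   input only).
#' @examples
#' sbn_to_mmr_ratio(55, 300)  # 18.33..., the phase-3/4 knot ratio
#' sbn_to_mmr_ratio(15, 20)   # 75, the phase-4/5 knot ratio
#' @export
sbn_to_mmr_ratio <- function(sbn, mmr, lb_frac = 1) {
  if (any(sbn < 0, na.rm = TRUE)) {
    stop("`sbn` must be non-negative", call. = FALSE)
  }
  if (any(mmr < 0, na.rm = TRUE)) {
    stop("`mmr` must be non-negative", call. = FALSE)
  }
  zero <- !is.na(mmr) & mmr == 0
  if (length(mmr) == 1L && length(sbn) == 1L && zero) {
    stop("`mmr` is 0: the SBN:MMR ratio is undefined", call. = FALSE)
  }
  out <- 100 * sbn / (mmr * lb_frac)
  if (any(zero)) {
    out[zero] <- NA_real_
    warning(sprintf("%d element(s) with mmr = 0: ratio undefined, set to NA",
                    sum(zero)), call. = FALSE)
  }
  out
}

#' Ratio of stillbirths to neonatal deaths
#'
#' The stillbirth-to-neonatal-death ratio, with both counts expressed per
#' total birth: `sbr / (nmr * (1 - sbr / 1000))`. Empirically this ratio
#' sits in a narrow band (roughly 0.7 to 1.1) and is only weakly related to
#' the mortality level, which is what justifies folding the two indicators
#' into one combined rate.
#'
#' @param sbr stillbirths per 1000 total births.
#' @param nmr neonatal deaths per 1000 livebirths; a zero makes the ratio
#'   undefined (error for scalar input, `NA` with a warning for vectors).
#' @return the ratio, vectorised.
#' @examples
#' sb_to_nn_ratio(30, 30)  # 1.031: equal rates, denominator adjustment
#' @export
sb_to_nn_ratio <- function(sbr, nmr) {
  if (any(sbr < 0, na.rm = TRUE) || any(sbr >= 1000, na.rm = TRUE)) {
    stop("`sbr` must be in [0, 1000)", call. = FALSE)
  }
  if (any(nmr < 0, na.rm = TRUE)) {
    stop("`nmr` must be non-negative", call. = FALSE)
  }
  zero <- !is.na(nmr) & nmr == 0
  if (length(nmr) == 1L && length(sbr) == 1L && zero) {
    stop("`nmr` is 0: the stillbirth:neonatal ratio is undefined",
         call. = FALSE)
  }
  out <- sbr / (nmr * (1 - sbr / 1000))
  if (any(zero)) {
    out[zero] <- NA_real_
    warning(sprintf("%d element(s) with nmr = 0: ratio undefined, set to NA",
                    sum(zero)), call. = FALSE)
  }
  out
}

# canonical column names of a country-year estimate panel
panel_columns <- function() {
  c("country_id", "year",
    "mmr", "mmr_lower", "mmr_upper",
    "sbr", "sbr_lower", "sbr_upper",
    "nmr", "nmr_lower", "nmr_upper")
}

#' Validate a country-year estimate panel
#'
#' Checks every row of a mortality panel against the estimate invariants:
#' for each indicator `lower <= point <= upper` and all values non-negative;
#' stillbirth and neonatal rates below 1000; year inside `year_range`; no
#' duplicated (country, year) pair. All violations are collected and
#' reported together with their row numbers; a panel with any violation is
#' rejected rather than silently repaired.
#'
#' @param panel data frame with columns `country_id`, `year`, and for each
#'   of `mmr`, `sbr`, `nmr` the point estimate plus `_lower` and `_upper`
#'   bounds. An optional `livebirths` column must be non-negative.
#' @param year_range allowed calendar-year range, default 1950--2030.
#' @return the panel, invisibly, if valid; otherwise an error listing every
#'   offending row and field.
#' @export
validate_panel <- function(panel, year_range = c(1950, 2030)) {
  required <- panel_columns()
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      problems <<- c(problems, sprintf("row %d: %s", which(rows), msg))
    }
  }
  for (ind in c("mmr", "sbr", "nmr")) {
    pt <- panel[[ind]]
    lo <- panel[[paste0(ind, "_lower")]]
    hi <- panel[[paste0(ind, "_upper")]]
    note(!is.na(pt) & pt < 0, sprintf("%s is negative", ind))
    note(!is.na(lo) & lo < 0, sprintf("%s_lower is negative", ind))
    note(!is.na(lo) & !is.na(pt) & lo > pt,
         sprintf("%s_lower exceeds the point estimate", ind))
    note(!is.na(hi) & !is.na(pt) & hi < pt,
         sprintf("%s_upper is below the point estimate", ind))
    if (ind != "mmr") {
      note(!is.na(pt) & pt >= 1000, sprintf("%s is not below 1000", ind))
    }
  }
  note(is.na(panel$year) | panel$year < year_range[1] |
         panel$year > year_range[2],
       sprintf("year outside [%d, %d]", year_range[1], year_range[2]))
  if ("livebirths" %in% names(panel)) {
    note(!is.na(panel$livebirths) & panel$livebirths < 0,
         "livebirths is negative")
  }
  dup <- duplicated(panel[c("country_id", "year")])
  note(dup, "duplicate (country_id, year)")
  if (length(problems)) {
    stop("invalid panel:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(panel)
}
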