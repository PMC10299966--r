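#' Pair phase assignments at two time points into transition records
#'
#' Matches countries classified at two time points and records each one's
#' starting phase, ending phase, and signed phase change. Countries present
#' at only one time point are excluded and counted, never imputed; a
#' duplicated country within either set is an error.
#'
#' @param t0,t1 phase assignments (from [classify_phases()] or any data
#'   frame with `country_id` and `phase` columns) at the earlier and later
#'   time points.
#' @return data frame with `country_id`, `phase_t0`, `phase_t1`, `delta`
#'   (in -4..4), and attribute `n_unmatched`.
#' @export
transition_records <- function(t0, t1) {
  for (nm in list(list(t0, "t0"), list(t1, "t1"))) {
    x <- nm[[1]]
    if (!all(c("country_id", "phase") %in% names(x))) {
      stop(sprintf("`%s` needs country_id and phase columns", nm[[2]]),
           call. = FALSE)
    }
    if (anyDuplicated(x$country_id)) {
      stop(sprintf("duplicate country_id in `%s`: %s", nm[[2]],
                   paste(unique(x$country_id[duplicated(x$country_id)]),
                         collapse = ", ")),
           call. = FALSE)
    }
  }
  merged <- merge(data.frame(country_id = t0$country_id, phase_t0 = t0$phase),
                  data.frame(country_id = t1$country_id, phase_t1 = t1$phase),
                  by = "country_id")
  merged$delta <- merged$phase_t1 - merged$phase_t0
  n_unmatched <- (nrow(t0) - nrow(merged)) + (nrow(t1) - nrow(merged))
  if (n_unmatched > 0) {
    message(sprintf("transition_records: %d assignment(s) had no match at the other time point",
                    n_unmatched))
  }
  structure(merged, n_unmatched = n_unmatched)
}

#' Transition matrix between phases at two time points
#'
#' Tabulates matched countries into a 5x5 count matrix indexed by starting
#' phase (rows) and ending phase (columns). The matrix total equals the
#' number of countries classified at both time points; diagonal cells are
#' countries that stayed in phase, the upper triangle progressions, the
#' lower triangle regressions.
#'
#' @inheritParams transition_records
#' @return 5x5 integer matrix with dimnames `phase_t0`, `phase_t1` and
#'   attribute `n_unmatched`.
#' @examples
#' t0 <- data.frame(country_id = c("A", "B", "C"), phase = c(1, 2, 5))
#' t1 <- data.frame(country_id = c("A", "B", "C"), phase = c(2, 2, 4))
#' transition_matrix(t0, t1)
#' @export
transition_matrix <- function(t0, t1) {
  rec <- transition_records(t0, t1)
  tab <- table(phase_t0 = factor(rec$phase_t0, levels = 1:5),
               phase_t1 = factor(rec$phase_t1, levels = 1:5))
  m <- unclass(tab)
  structure(m, n_unmatched = attr(rec, "n_unmatched"))
}

#' Summarise progression, two-phase advances, and regression
#'
#' Counts, among eligible countries, how many progressed at least one phase
#' (`delta >= 1`), advanced exactly two phases, advanced two or more, and
#' regressed (`delta < 0`) between the two time points, with the
#' corresponding proportions of the eligible denominator. Proportions are
#' exact internally; the print method rounds to whole percent.
#'
#' Eligibility defaults to countries below phase 5 at the start -- a country
#' already in the final phase cannot progress, so including it deflates the
#' progression proportion. `"all_phases"` keeps every matched country in the
#' denominator.
#'
#' @param records transition records from [transition_records()], or a data
#'   frame with `phase_t0` and `delta` columns.
#' @param eligibility `"below_phase5"` (default: phases 1--4 at t0) or
#'   `"all_phases"`.
#' @return a `progression_summary` list: `n_eligible`, `n_progressed_ge1`,
#'   `n_progressed_eq2`, `n_progressed_ge2`, `n_regressed`, and proportions
#'   `prop_progressed_ge1`, `prop_progressed_eq2`, `prop_regressed`.
#' @examples
#' rec <- data.frame(country_id = letters[1:5], phase_t0 = c(2, 2, 3, 4, 1),
#'                   phase_t1 = c(3, 4, 5, 3, 1))
#' rec$delta <- rec$phase_t1 - rec$phase_t0
#' progression_summary(rec)
#' @export
progression_summary <- function(records,
                                eligibility = c("below_phase5", "all_phases")) {
  eligibility <- match.arg(eligibility)
  if (!all(c("phase_t0", "delta") %in% names(records))) {
    stop("`records` needs phase_t0 and delta columns", call. = FALSE)
  }
  eligible <- if (eligibility == "below_phase5") {
    records[records$phase_t0 < 5, , drop = FALSE]
  } else {
    records
  }
  n <- nrow(eligible)
  if (n == 0) stop("no eligible countries", call. = FALSE)
  out <- list(eligibility = eligibility,
              n_eligible = n,
              n_progressed_ge1 = sum(eligible$delta >= 1),
              n_progressed_eq2 = sum(eligible$delta == 2),
              n_progressed_ge2 = sum(eligible$delta >= 2),
              n_regressed = sum(eligible$delta < 0))
  out$prop_progressed_ge1 <- out$n_progressed_ge1 / n
  out$prop_progressed_eq2 <- out$n_progressed_eq2 / n
  out$prop_regressed <- out$n_regressed / n
  structure(out, class = "progression_summary")
}

#' @export
print.progression_summary <- function(x, ...) {
  cat(sprintf("Phase progression among %d eligible countries (%s at t0)\n",
              x$n_eligible,
              if (x$eligibility == "below_phase5") "phases 1-4" else "all phases"))
  cat(sprintf("  progressed >= 1 phase: %d (%.0f%%)\n",
              x$n_progressed_ge1, 100 * x$prop_progressed_ge1))
  cat(sprintf("  advanced exactly 2:    %d (%.0f%%)\n",
              x$n_progressed_eq2, 100 * x$prop_progressed_eq2))
  cat(sprintf("  regressed:             %d (%.0f%%)\n",
              x$n_regressed, 100 * x$prop_regressed))
  invisible(x)
}
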