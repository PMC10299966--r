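#' Absolute richest-poorest coverage gap
#'
#' The difference in coverage between the richest (q5) and poorest (q1)
#' wealth quintiles, in percentage points. Negative when the poorest exceed
#' the richest (a reversed gradient).
#'
#' @param cov data frame of quintile coverage with columns `q1`..`q5` (in
#'   percent), or a numeric vector of the five quintile values
#'   poorest-to-richest.
#' @return q5 - q1 in percentage points, one value per row.
#' @examples
#' quintile_gap(data.frame(q1 = 30, q2 = 40, q3 = 50, q4 = 60, q5 = 80))
#' @export
quintile_gap <- function(cov) {
  cov <- as_quintile_df(cov)
  cov$q5 - cov$q1
}

as_quintile_df <- function(cov) {
  if (is.numeric(cov) && is.null(dim(cov))) {
    if (length(cov) != 5L) {
      stop("a quintile vector must have exactly 5 values (poorest to richest)",
           call. = FALSE)
    }
    cov <- as.data.frame(as.list(stats::setNames(cov, paste0("q", 1:5))))
  }
  qcols <- paste0("q", 1:5)
  if (!all(qcols %in% names(cov))) {
    stop("quintile coverage needs columns q1..q5", call. = FALSE)
  }
  bad <- vapply(qcols, function(cn) any(cov[[cn]] < 0 | cov[[cn]] > 100,
                                        na.rm = TRUE), logical(1))
  if (any(bad)) {
    stop("quintile coverage must lie in [0, 100]; offending column(s): ",
         paste(qcols[bad], collapse = ", "), call. = FALSE)
  }
  cov
}

#' Inequality patterns index and top/bottom/linear classification
#'
#' The inequality patterns index (IPI) compares the richest quintile's
#' excess over the national mean with the poorest quintile's shortfall:
#' `ipi = (q5 - mean) - (mean - q1) = q5 + q1 - 2 * mean`, in percentage
#' points. A clearly positive index marks *top* inequality (the richest
#' pull away from everyone else), a clearly negative one *bottom* inequality
#' (the poorest are left behind), and an index within `tolerance` of zero a
#' *linear* gradient. The default tolerance is 5 percentage points.
#'
#' When the national mean is absent it is computed as the unweighted mean of
#' the five quintiles, with a message (true national means are
#' livebirth-weighted; pass `national_mean` when weights are available).
#'
#' @param cov quintile coverage: data frame with `q1`..`q5` and optionally
#'   `national_mean`, or a numeric vector of five values.
#' @param tolerance half-width of the "linear" band in percentage points.
#' @return data frame with one row per input row: `gap` (q5 - q1), `ipi`,
#'   and `pattern` (`"top"`, `"bottom"`, or `"linear"`).
#' @examples
#' inequality_pattern_index(data.frame(q1 = 10, q2 = 20, q3 = 30, q4 = 40,
#'                                     q5 = 90, national_mean = 35))
#' @export
inequality_pattern_index <- function(cov, tolerance = 5) {
  cov <- as_quintile_df(cov)
  if (!"national_mean" %in% names(cov) || all(is.na(cov$national_mean))) {
    message("inequality_pattern_index: national_mean absent; using the unweighted quintile mean")
    cov$national_mean <- rowMeans(cov[paste0("q", 1:5)])
  } else if (anyNA(cov$national_mean)) {
    miss <- is.na(cov$national_mean)
    message(sprintf("inequality_pattern_index: %d missing national_mean value(s) replaced by the unweighted quintile mean",
                    sum(miss)))
    cov$national_mean[miss] <- rowMeans(cov[miss, paste0("q", 1:5), drop = FALSE])
  }
  ipi <- cov$q5 + cov$q1 - 2 * cov$national_mean
  pattern <- ifelse(ipi > tolerance, "top",
                    ifelse(ipi < -tolerance, "bottom", "linear"))
  out <- data.frame(gap = cov$q5 - cov$q1, ipi = ipi, pattern = pattern)
  keep <- intersect(c("country_id", "year", "indicator"), names(cov))
  if (length(keep)) out <- cbind(cov[keep], out)
  out
}

#' Caesarean section rates by wealth quintile and transition phase
#'
#' Phase-conditional medians (and IQRs) of caesarean section rates in the
#' poorest and richest wealth quintiles, computed with the same
#' median/quartile machinery as [phase_summaries()]. Caesarean rates enter
#' as coverage per 100 livebirths in the quintile table.
#'
#' @param quintiles quintile coverage rows for caesarean section: columns
#'   `country_id`, `year`, `indicator`, `q1`..`q5`.
#' @param assignments phase assignments (see [classify_phases()]).
#' @param indicator which indicator rows to use, default `"csec"`.
#' @param year optional calendar-year restriction.
#' @param quartile_type quantile algorithm, as in [phase_summaries()].
#' @return data frame with columns `phase`, `quintile` (`"poorest"` /
#'   `"richest"`), `n`, `median`, `q1`, `q3`.
#' @export
csec_quintile_summary <- function(quintiles, assignments,
                                  indicator = "csec", year = NULL,
                                  quartile_type = 7) {
  rows <- quintiles[quintiles$indicator == indicator, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop(sprintf("no \"%s\" rows in the quintile table", indicator),
         call. = FALSE)
  }
  as_quintile_df(rows)
  long <- function(col, label) {
    data.frame(country_id = rows$country_id, year = rows$year,
               indicator = label, value = rows[[col]])
  }
  out <- lapply(c(poorest = "q1", richest = "q5"), function(col) {
    lab <- if (col == "q1") "poorest" else "richest"
    prof <- phase_summaries(long(col, lab), assignments, lab,
                            year = year, quartile_type = quartile_type)
    data.frame(phase = prof$phase, quintile = lab, n = prof$n,
               median = prof$median, q1 = prof$q1, q3 = prof$q3)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$phase, res$quintile), ]
}
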