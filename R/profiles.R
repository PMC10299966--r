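#' Phase-conditional covariate summaries (median and IQR)
#'
#' For one covariate, pools the countries assigned to each transition phase
#' and reports the unweighted country median and interquartile range --
#' the reference distribution against which an individual country can be
#' benchmarked. Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7) by default; the type is exposed so alternative
#' conventions can be compared. Missing covariate values are dropped and
#' counted; a phase with no contributing country is absent from the output,
#' not reported as zero.
#'
#' @param covariates long-format data frame with columns `country_id`,
#'   `year`, `indicator`, `value`.
#' @param assignments phase assignments with `country_id`, `year`, `phase`
#'   (see [classify_phases()]).
#' @param indicator name of the covariate to summarise; an unknown name is
#'   an error listing what is available.
#' @param year optional: restrict both tables to one calendar year.
#' @param quartile_type quantile algorithm, passed to [stats::quantile()].
#' @return data frame of phase profiles: `phase`, `indicator`, `n`,
#'   `median`, `q1`, `q3`, plus attribute `n_dropped` (missing values
#'   removed).
#' @export
phase_summaries <- function(covariates, assignments, indicator,
                            year = NULL, quartile_type = 7) {
  need <- c("country_id", "year", "indicator", "value")
  if (!all(need %in% names(covariates))) {
    stop("`covariates` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  available <- unique(covariates$indicator)
  if (!indicator %in% available) {
    stop(sprintf("unknown indicator \"%s\"; available: %s", indicator,
                 paste(sort(available), collapse = ", ")),
         call. = FALSE)
  }
  cov <- covariates[covariates$indicator == indicator, , drop = FALSE]
  if (!is.null(year)) {
    cov <- cov[cov$year == year, , drop = FALSE]
    assignments <- assignments[assignments$year == year, , drop = FALSE]
  }
  merged <- merge(cov, as.data.frame(assignments)[c("country_id", "year", "phase")],
                  by = c("country_id", "year"))
  n_dropped <- sum(is.na(merged$value))
  merged <- merged[!is.na(merged$value), , drop = FALSE]
  if (nrow(merged) == 0) {
    stop(sprintf("no non-missing \"%s\" values match the assignments", indicator),
         call. = FALSE)
  }
  qs <- function(v) {
    q <- stats::quantile(v, probs = c(0.25, 0.5, 0.75),
                         type = quartile_type, names = FALSE)
    c(n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  }
  by_phase <- split(merged$value, merged$phase)
  stats_m <- t(vapply(by_phase, qs, numeric(4)))
  out <- data.frame(phase = as.integer(names(by_phase)),
                    indicator = indicator,
                    n = as.integer(stats_m[, "n"]),
                    median = stats_m[, "median"],
                    q1 = stats_m[, "q1"],
                    q3 = stats_m[, "q3"],
                    row.names = NULL)
  structure(out[order(out$phase), ], n_dropped = n_dropped)
}

#' Benchmark a country's value against a phase profile
#'
#' Flags whether a covariate value is typical for a transition phase --
#' inside the phase's interquartile range -- or lies above or below it.
#' `tolerance` widens the band multiplicatively (0.1 stretches it to
#' `[q1 * 0.9, q3 * 1.1]`) for a more forgiving notion of "typical".
#'
#' @param value covariate value(s) to benchmark.
#' @param profile one phase's profile: a list or one-row data frame with
#'   `q1` and `q3` (as produced by [phase_summaries()]).
#' @param tolerance fractional widening of the IQR band, default 0.
#' @return character vector: `"typical"`, `"above_iqr"`, or `"below_iqr"`.
#' @examples
#' prof <- list(q1 = 2.0, median = 2.8, q3 = 3.5)  # phase-3 fertility
#' benchmark_country(4.0, prof)  # "above_iqr"
#' @export
benchmark_country <- function(value, profile, tolerance = 0) {
  if (!all(c("q1", "q3") %in% names(profile))) {
    stop("`profile` needs q1 and q3", call. = FALSE)
  }
  q1 <- as.numeric(profile$q1[1])
  q3 <- as.numeric(profile$q3[1])
  if (is.na(q1) || is.na(q3) || q1 > q3) {
    stop("invalid profile: require q1 <= q3", call. = FALSE)
  }
  lo <- q1 * (1 - tolerance)
  hi <- q3 * (1 + tolerance)
  ifelse(value > hi, "above_iqr", ifelse(value < lo, "below_iqr", "typical"))
}

#' Aggregate causes of death into the three transition cause groups
#'
#' Collapses a cause-of-death table into the three broad groups that
#' structure the transition: infectious causes including abortion
#' complications (group 1), causes tied to the health and nutritional
#' status of the woman or baby such as indirect maternal causes,
#' prematurity, and growth restriction (group 2), and peripartum
#' complications (group 3); anything else is "other". Shares are
#' renormalised to sum to 100, so the input may be death counts or percents.
#'
#' @param cause_table named numeric vector (cause -> deaths or percent) or a
#'   data frame with columns `cause` and `deaths`.
#' @param mapping data frame with columns `cause` and `group` (values among
#'   `"1"`, `"2"`, `"3"`, `"other"`); see [default_cod_mapping()].
#' @param mode `"strict"` (default): an unmapped cause is an error naming
#'   the cause. `"lenient"`: unmapped causes are routed to "other" with a
#'   message.
#' @return named numeric vector `group1_infectious`,
#'   `group2_health_nutrition`, `group3_peripartum`, `other`, in percent
#'   summing to 100.
#' @examples
#' cod_group_shares(c(sepsis = 24, prematurity = 41, intrapartum = 26,
#'                    congenital = 9),
#'                  default_cod_mapping("neonatal"))
#' @export
cod_group_shares <- function(cause_table, mapping,
                             mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (is.data.frame(cause_table)) {
    deaths <- cause_table$deaths
    names(deaths) <- cause_table$cause
    cause_table <- deaths
  }
  if (is.null(names(cause_table)) || any(!nzchar(names(cause_table)))) {
    stop("`cause_table` must have cause names", call. = FALSE)
  }
  if (any(cause_table < 0, na.rm = TRUE)) {
    stop("cause-of-death values must be non-negative", call. = FALSE)
  }
  if (!all(c("cause", "group") %in% names(mapping))) {
    stop("`mapping` needs cause and group columns", call. = FALSE)
  }
  grp <- as.character(mapping$group[match(names(cause_table), mapping$cause)])
  unmapped <- is.na(grp)
  if (any(unmapped)) {
    if (mode == "strict") {
      stop("unmapped cause(s): ",
           paste(names(cause_table)[unmapped], collapse = ", "),
           call. = FALSE)
    }
    message(sprintf("cod_group_shares: %d unmapped cause(s) routed to \"other\"",
                    sum(unmapped)))
    grp[unmapped] <- "other"
  }
  total <- sum(cause_table)
  if (total <= 0) stop("cause-of-death table sums to zero", call. = FALSE)
  share <- function(g) 100 * sum(cause_table[grp == g]) / total
  c(group1_infectious = share("1"),
    group2_health_nutrition = share("2"),
    group3_peripartum = share("3"),
    other = share("other"))
}

#' Default cause-of-death group mappings
#'
#' Loads the editable cause-to-group mapping shipped with the package for
#' maternal deaths, stillbirths, or neonatal deaths. Maternal: abortion
#' complications and sepsis are infectious (group 1), indirect causes are
#' health/nutrition (group 2), haemorrhage, hypertensive disorders, and
#' obstructed labour are peripartum (group 3). Neonatal: infections group 1,
#' prematurity and growth restriction group 2, intrapartum events group 3.
#' Stillbirth causes follow the same logic. Users may edit the files under
#' `inst/extdata/` or supply their own mapping to [cod_group_shares()].
#'
#' @param which `"maternal"`, `"neonatal"`, or `"stillbirth"`.
#' @return data frame with columns `cause`, `group`.
#' @export
default_cod_mapping <- function(which = c("maternal", "neonatal", "stillbirth")) {
  which <- match.arg(which)
  path <- system.file("extdata", sprintf("cod_mapping_%s.csv", which),
                      package = "mortrans", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Abortion policy permissiveness score
#'
#' Scores a national abortion policy from the five legal grounds on which
#' abortion may be permitted (by default: to save the woman's life, to
#' preserve physical health, to preserve mental health, in cases of rape or
#' incest or fetal impairment, and on request). The score is the weighted
#' share of permitted grounds on a 0--100 scale: 0 means abortion is not
#' legally permitted in any circumstances, 100 that it is available on
#' request. Weights default to equal.
#'
#' @param permitted logical vector of length 5: is each ground permitted?
#'   Names, if present, label the grounds.
#' @param weights positive weights for the five grounds, default equal.
#' @return score in percent, 0--100.
#' @examples
#' abortion_score(c(TRUE, TRUE, TRUE, FALSE, FALSE))  # 60
#' @export
abortion_score <- function(permitted, weights = NULL) {
  if (length(permitted) != 5L || anyNA(permitted) || !is.logical(permitted)) {
    stop("`permitted` must be a logical vector of exactly 5 grounds",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, 5)
  if (length(weights) != 5L || any(weights <= 0)) {
    stop("`weights` must be 5 positive values", call. = FALSE)
  }
  100 * sum(weights[permitted]) / sum(weights)
}
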