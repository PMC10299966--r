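#' Phase thresholds for the mortality transition model
#'
#' Constructs and validates the pair of four-knot threshold vectors that
#' define the five transition phases. The defaults are the model's published
#' knots: maternal mortality ratios of 700, 300, 100, and 20 deaths per
#' 100,000 livebirths, and combined stillbirth-plus-neonatal mortality of
#' 80, 55, 30, and 15 per 1000 total births. Knot k separates phase k from
#' phase k + 1; a country is in phase 1 while either indicator is at or
#' above knot 1, and in phase 5 once both are below knot 4.
#'
#' Custom knots are accepted (for example the neonatal-only alternative of
#' 45, 30, 15, and 5 per 1000 livebirths used where stillbirth data are
#' unreliable) as long as each vector is strictly decreasing, positive, and
#' of length four.
#'
#' @param mmr_knots numeric length-4, strictly decreasing, maternal deaths
#'   per 100,000 livebirths.
#' @param sbn_knots numeric length-4, strictly decreasing, stillbirths plus
#'   neonatal deaths per 1000 total births.
#' @return an object of class `phase_thresholds`: a list with elements
#'   `mmr_knots` and `sbn_knots`.
#' @examples
#' phase_thresholds()
#' phase_thresholds(mmr_knots = c(1000, 300, 100, 50),
#'                  sbn_knots = c(90, 60, 35, 20))
#' @export
phase_thresholds <- function(mmr_knots = c(700, 300, 100, 20),
                             sbn_knots = c(80, 55, 30, 15)) {
  check_knots(mmr_knots, "mmr_knots")
  check_knots(sbn_knots, "sbn_knots")
  structure(list(mmr_knots = as.numeric(mmr_knots),
                 sbn_knots = as.numeric(sbn_knots)),
            class = "phase_thresholds")
}

check_knots <- function(knots, name) {
  if (!is.numeric(knots) || length(knots) != 4L || anyNA(knots)) {
    stop(sprintf("`%s` must be a numeric vector of exactly 4 values", name),
         call. = FALSE)
  }
  if (any(knots <= 0)) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  if (any(diff(knots) >= 0)) {
    stop(sprintf("`%s` must be strictly decreasing", name), call. = FALSE)
  }
  invisible(knots)
}

as_phase_thresholds <- function(x) {
  if (inherits(x, "phase_thresholds")) return(x)
  if (is.list(x) && all(c("mmr_knots", "sbn_knots") %in% names(x))) {
    return(phase_thresholds(x$mmr_knots, x$sbn_knots))
  }
  stop("expected a `phase_thresholds` object or a list with mmr_knots and sbn_knots",
       call. = FALSE)
}

#' @export
print.phase_thresholds <- function(x, ...) {
  cat("Five-phase mortality transition thresholds\n")
  cat("  MMR knots (per 100,000 livebirths):",
      paste(format(x$mmr_knots), collapse = ", "), "\n")
  cat("  SBN knots (per 1000 total births): ",
      paste(format(x$sbn_knots), collapse = ", "), "\n")
  kr <- knot_ratios(x)
  cat("  SBN:MMR knot ratios:",
      paste(kr$ratio_rounded, collapse = ", "), "\n")
  invisible(x)
}

#' Stillbirth+neonatal to maternal mortality ratios at the transition knots
#'
#' At each of the four knots the combined stillbirth-plus-neonatal mortality
#' and the maternal mortality ratio imply a dimensionless ratio of stillbirth
#' and neonatal deaths to maternal deaths. Under the default thresholds these
#' are 11, 18, 30, and 75 after rounding: the burden shifts strongly towards
#' stillbirths and neonatal deaths as countries move through the transition.
#' For instance the second knot (SBN 55 per 1000 births, MMR 300 per
#' 100,000 livebirths) gives 100 * 55 / 300 = 18.3, printed as 18.
#'
#' @param thresholds a [phase_thresholds()] object.
#' @return data frame with one row per knot: `knot` (1--4, separating phase
#'   k from k+1), `mmr_knot`, `sbn_knot`, `ratio` (unrounded), and
#'   `ratio_rounded` (nearest integer, halves away from zero).
#' @examples
#' knot_ratios(phase_thresholds())
#' @export
knot_ratios <- function(thresholds = phase_thresholds()) {
  thresholds <- as_phase_thresholds(thresholds)
  r <- sbn_to_mmr_ratio(thresholds$sbn_knots, thresholds$mmr_knots)
  data.frame(knot = 1:4,
             mmr_knot = thresholds$mmr_knots,
             sbn_knot = thresholds$sbn_knots,
             ratio = r,
             ratio_rounded = round_half_away(r))
}

# round to nearest integer, halves away from zero (not banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
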