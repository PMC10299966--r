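#' Configuration for the synthetic country-panel generator
#'
#' Bundles and validates every parameter of [generate_panel()]. The
#' defaults emulate the structure of the UN country estimates and the
#' survey-derived coverage tables that the transition analysis consumes:
#' correlated declining mortality indicators, stillbirth-to-neonatal-death
#' ratios in the 0.7--1.1 band, phase-graded covariates, and wealth-quintile
#' coverage that shifts from top inequality in the high-mortality phases to
#' near-linear gradients once coverage saturates.
#'
#' @param n_per_phase integer length 5: countries to generate per intended
#'   baseline phase.
#' @param years calendar years of the panel (default 2000 and 2020).
#' @param arr annual rate of reduction of both mortality indicators, in
#'   percent per year, per phase (applied between consecutive panel years
#'   for countries that do not change phase).
#' @param arr_noise_sd lognormal standard deviation of the multiplicative
#'   noise on each between-year decline factor.
#' @param half_width uncertainty half-width as a fraction of the point
#'   estimate: bounds are `point * (1 -/+ half_width)`.
#' @param sb_nn_range range of the stillbirth-to-neonatal-death ratio used
#'   to split the combined rate into its two components; must sit inside
#'   (0, 5).
#' @param progression_prob per-phase probability that a country advances one
#'   phase over one between-year interval (0 for phase 5, which cannot
#'   advance).
#' @param covariates named list of covariate specifications, each a list
#'   with `type` (`"rate"` for positive indicators like fertility,
#'   `"coverage"` for percentages), `median` (length 5, per phase), and
#'   `iqr` (length 5 target interquartile widths).
#' @param inequality_regime per-phase wealth-inequality regime for
#'   institutional-birth coverage: `"top"`, `"bottom"`, or `"linear"`.
#' @param inequality_gap per-phase richest-poorest gap in percentage points.
#' @param quintile_noise_sd per-quintile Gaussian noise, percentage points.
#' @param csec_poorest,csec_richest per-phase median caesarean rates (per
#'   100 livebirths) in the poorest and richest quintiles.
#' @param margin interior margin, as a fraction of the phase box width, kept
#'   between sampled baseline values and the phase's bounding knots (so the
#'   intended phase is recovered exactly; set 0 to stress-test boundaries).
#' @param seed integer seed; a fixed seed makes [generate_panel()] output
#'   bit-identical.
#' @return a validated `generator_config` list.
#' @seealso [default_published_config()] for the ready-made configuration whose
#'   covariate gradients match the published phase profiles.
#' @export
generator_config <- function(n_per_phase = rep(20L, 5),
                             years = c(2000, 2020),
                             arr = rep(2.5, 5),
                             arr_noise_sd = 0.05,
                             half_width = 0.3,
                             sb_nn_range = c(0.7, 1.1),
                             progression_prob = c(0.63, 0.63, 0.63, 0.63, 0),
                             covariates = default_covariate_spec(),
                             inequality_regime = c("top", "top", "bottom",
                                                   "linear", "linear"),
                             inequality_gap = c(50, 45, 35, 7, 3),
                             quintile_noise_sd = 1.5,
                             csec_poorest = c(0.5, 1.5, 4, 15, 20),
                             csec_richest = c(3, 10, 28, 30, 32),
                             margin = 0.1,
                             seed = 1L) {
  cfg <- list(n_per_phase = as.integer(n_per_phase), years = sort(years),
              arr = arr, arr_noise_sd = arr_noise_sd,
              half_width = half_width, sb_nn_range = sb_nn_range,
              progression_prob = progression_prob, covariates = covariates,
              inequality_regime = inequality_regime,
              inequality_gap = inequality_gap,
              quintile_noise_sd = quintile_noise_sd,
              csec_poorest = csec_poorest, csec_richest = csec_richest,
              margin = margin, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(length(cfg$n_per_phase) == 5, all(cfg$n_per_phase >= 0))
  if (sum(cfg$n_per_phase) == 0) {
    stop("config generates zero countries", call. = FALSE)
  }
  if (length(cfg$years) < 1 || anyDuplicated(cfg$years)) {
    stop("`years` must be distinct calendar years", call. = FALSE)
  }
  stopifnot(length(cfg$arr) == 5, all(cfg$arr >= 0), all(cfg$arr < 100))
  stopifnot(cfg$half_width >= 0, cfg$half_width < 1)
  if (length(cfg$sb_nn_range) != 2 || cfg$sb_nn_range[1] <= 0 ||
      cfg$sb_nn_range[2] >= 5 || diff(cfg$sb_nn_range) < 0) {
    stop("`sb_nn_range` must be an increasing pair inside (0, 5)",
         call. = FALSE)
  }
  if (length(cfg$progression_prob) != 5 ||
      any(cfg$progression_prob < 0 | cfg$progression_prob > 1)) {
    stop("`progression_prob` must be 5 probabilities in [0, 1]",
         call. = FALSE)
  }
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    if (!cv$type %in% c("rate", "coverage") ||
        length(cv$median) != 5 || length(cv$iqr) != 5 ||
        any(cv$median <= 0) || any(cv$iqr < 0)) {
      stop(sprintf("invalid covariate spec for \"%s\"", nm), call. = FALSE)
    }
  }
  stopifnot(all(cfg$inequality_regime %in% c("top", "bottom", "linear")),
            length(cfg$inequality_regime) == 5,
            length(cfg$inequality_gap) == 5, all(cfg$inequality_gap >= 0),
            cfg$margin >= 0, cfg$margin < 0.5,
            length(cfg$csec_poorest) == 5, length(cfg$csec_richest) == 5)
  invisible(cfg)
}

#' Per-phase covariate gradients matching the published phase profiles
#'
#' The default covariate specification: total fertility rate medians of
#' 6.1, 5.4, 2.8, 2.2, and 1.5 children per woman across phases 1--5 with
#' the published interquartile widths, and coverage medians rising across
#' the transition -- first antenatal visit 66 to 98%, four or more visits
#' 44 to 94%, institutional births 36 to 99%, caesarean section 2 to 25%.
#' Intermediate coverage values between the published phase-1 and phase-5
#' endpoints follow a monotone gradient.
#'
#' @return named list of covariate specifications (see [generator_config()]).
#' @export
default_covariate_spec <- function() {
  list(
    tfr = list(type = "rate",
               median = c(6.1, 5.4, 2.8, 2.2, 1.5),
               iqr = c(1.1, 1.8, 1.5, 1.1, 0.4)),
    anc1 = list(type = "coverage",
                median = c(66, 80, 90, 95, 98),
                iqr = c(15, 12, 8, 5, 2)),
    anc4 = list(type = "coverage",
                median = c(44, 55, 70, 85, 94),
                iqr = c(15, 15, 12, 8, 5)),
    institutional_birth = list(type = "coverage",
                               median = c(36, 55, 75, 92, 99),
                               iqr = c(20, 20, 15, 8, 2)),
    csec = list(type = "coverage",
                median = c(2, 4, 10, 18, 25),
                iqr = c(1, 2, 4, 6, 8))
  )
}

#' Ready-made generator configuration mirroring the published gradients
#'
#' Returns a [generator_config()] whose covariate medians equal the
#' published phase medians (fertility 6.1 to 1.5 children per woman,
#' institutional births 36 to 99%, first antenatal visit 66 to 98%, four or
#' more visits 44 to 94%, caesarean section 2 to 25%), with 50 countries per
#' phase so that end-to-end runs on synthetic data reproduce the qualitative
#' phase gradients with stable medians.
#'
#' @param n_per_phase countries per phase, default 50 each.
#' @param seed integer seed.
#' @param ... further arguments passed to [generator_config()].
#' @return a `generator_config`.
#' @export
default_published_config <- function(n_per_phase = rep(50L, 5), seed = 1L, ...) {
  generator_config(n_per_phase = n_per_phase, seed = seed, ...)
}

# mortality "boxes" per intended phase: [low, high) ranges bounded by the
# transition knots, with outer caps closing the open ends
phase_boxes <- function(thresholds = phase_thresholds(),
                        mmr_cap = 1200, sbn_cap = 130,
                        mmr_floor = 2, sbn_floor = 2) {
  mk <- thresholds$mmr_knots
  sk <- thresholds$sbn_knots
  list(mmr = cbind(low = c(mk, mmr_floor), high = c(mmr_cap, mk)),
       sbn = cbind(low = c(sk, sbn_floor), high = c(sbn_cap, sk)))
}

# uniform draw inside a phase box shrunk by `margin` of its width per side
draw_in_box <- function(n, box_row, margin) {
  w <- box_row["high"] - box_row["low"]
  stats::runif(n, box_row["low"] + margin * w, box_row["high"] - margin * w)
}

# clamp values into the shrunk box (keeps non-progressing countries in phase)
clamp_to_box <- function(x, box_row, margin) {
  w <- box_row["high"] - box_row["low"]
  pmin(pmax(x, box_row["low"] + margin * w), box_row["high"] - margin * w)
}

# split a combined SBN rate (simple-sum convention) into SBR and NMR so that
# the exact stillbirth:neonatal ratio sbr / (nmr * (1 - sbr/1000)) equals rho:
# solve (rho/1000) s^2 - (rho (1 + sbn/1000) + 1) s + rho sbn = 0 for the
# root below sbn
split_sbn <- function(sbn, rho) {
  a <- rho / 1000
  b <- -(rho * (1 + sbn / 1000) + 1)
  cc <- rho * sbn
  sbr <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  cbind(sbr = sbr, nmr = sbn - sbr)
}

rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 100) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

regime_offsets <- function(regime) {
  switch(regime,
         top    = c(-0.35, -0.30, -0.20, -0.05, 0.90),
         bottom = c(-0.90, 0.05, 0.20, 0.30, 0.35),
         linear = c(-0.50, -0.25, 0.00, 0.25, 0.50))
}

#' Generate a synthetic country panel with known phase structure
#'
#' Simulates a country-year panel whose statistical structure matches what
#' the transition analysis assumes, together with the ground truth needed to
#' validate every pipeline stage. For each country an intended baseline
#' phase is fixed and its maternal and combined stillbirth-plus-neonatal
#' rates are drawn uniformly inside that phase's threshold box, shrunk by an
#' interior margin so classification recovers the intended phase exactly.
#' The combined rate is split into stillbirth and neonatal components so the
#' stillbirth-to-neonatal ratio lies in the configured band; uncertainty
#' bounds are symmetric multiples of the point estimate. In later years a
#' country either advances one phase (with the configured per-phase
#' probability, redrawing its rates in the next box) or declines along the
#' configured annual rate of reduction with lognormal noise, clamped to its
#' phase box. Covariates are drawn around the phase medians (lognormal for
#' positive rates, truncated normal on \[0, 100\] for coverage), and
#' wealth-quintile coverage follows the phase's inequality regime.
#'
#' One integer seed drives one random stream per output table, so adding a
#' table never perturbs the others, and a fixed seed makes the output
#' bit-identical.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_panel` with elements `panel` (the
#'   country-year mortality estimates), `covariates` (long format),
#'   `quintiles` (institutional-birth and caesarean coverage by wealth
#'   quintile), and `truth` (intended phase per country-year).
#' @examples
#' synth <- generate_panel(generator_config(n_per_phase = rep(3L, 5)))
#' summary(classify_phases(synth$panel))
#' @export
generate_panel <- function(config = generator_config()) {
  validate_generator_config(config)
  boxes <- phase_boxes()
  n_total <- sum(config$n_per_phase)
  base_phase <- rep(1:5, times = config$n_per_phase)
  ids <- sprintf("C%03d", seq_len(n_total))
  years <- config$years
  n_years <- length(years)

  ## stream 1: mortality panel + phase paths -------------------------------
  set.seed(config$seed + 101L)
  phase_path <- matrix(NA_integer_, n_total, n_years)
  phase_path[, 1] <- base_phase
  if (n_years > 1) {
    for (j in 2:n_years) {
      p <- phase_path[, j - 1]
      adv <- stats::runif(n_total) < config$progression_prob[p] & p < 5L
      phase_path[, j] <- p + as.integer(adv)
    }
  }
  mmr <- sbn <- matrix(NA_real_, n_total, n_years)
  for (p in 1:5) {
    idx <- which(base_phase == p)
    if (!length(idx)) next
    mmr[idx, 1] <- draw_in_box(length(idx), boxes$mmr[p, ], config$margin)
    sbn[idx, 1] <- draw_in_box(length(idx), boxes$sbn[p, ], config$margin)
  }
  if (n_years > 1) {
    for (j in 2:n_years) {
      dt <- years[j] - years[j - 1]
      moved <- phase_path[, j] != phase_path[, j - 1]
      for (p in 1:5) {
        idx <- which(moved & phase_path[, j] == p)
        if (length(idx)) {
          mmr[idx, j] <- draw_in_box(length(idx), boxes$mmr[p, ], config$margin)
          sbn[idx, j] <- draw_in_box(length(idx), boxes$sbn[p, ], config$margin)
        }
      }
      stay <- which(!moved)
      if (length(stay)) {
        p <- phase_path[stay, j]
        fac <- (1 - config$arr[p] / 100)^dt *
          exp(stats::rnorm(length(stay), 0, config$arr_noise_sd))
        fac2 <- (1 - config$arr[p] / 100)^dt *
          exp(stats::rnorm(length(stay), 0, config$arr_noise_sd))
        m_new <- mmr[stay, j - 1] * fac
        s_new <- sbn[stay, j - 1] * fac2
        for (k in seq_along(stay)) {
          mmr[stay[k], j] <- clamp_to_box(m_new[k], boxes$mmr[p[k], ],
                                          config$margin)
          sbn[stay[k], j] <- clamp_to_box(s_new[k], boxes$sbn[p[k], ],
                                          config$margin)
        }
      }
    }
  }
  rho <- matrix(stats::runif(n_total * n_years, config$sb_nn_range[1],
                             config$sb_nn_range[2]), n_total, n_years)
  livebirths <- round(stats::runif(n_total, 1e5, 5e6))

  rows <- expand.grid(i = seq_len(n_total), j = seq_len(n_years))
  split <- split_sbn(sbn[cbind(rows$i, rows$j)], rho[cbind(rows$i, rows$j)])
  h <- config$half_width
  panel <- data.frame(
    country_id = ids[rows$i],
    year = years[rows$j],
    mmr = mmr[cbind(rows$i, rows$j)],
    sbr = split[, "sbr"],
    nmr = split[, "nmr"],
    livebirths = livebirths[rows$i],
    stringsAsFactors = FALSE)
  for (ind in c("mmr", "sbr", "nmr")) {
    panel[[paste0(ind, "_lower")]] <- panel[[ind]] * (1 - h)
    panel[[paste0(ind, "_upper")]] <- panel[[ind]] * (1 + h)
  }
  panel <- panel[order(panel$year, panel$country_id),
                 c(panel_columns(), "livebirths")]
  rownames(panel) <- NULL
  truth <- data.frame(country_id = ids[rows$i], year = years[rows$j],
                      phase = phase_path[cbind(rows$i, rows$j)],
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$year, truth$country_id), ]
  rownames(truth) <- NULL

  ## stream 2: covariates ---------------------------------------------------
  set.seed(config$seed + 202L)
  cov_list <- lapply(names(config$covariates), function(nm) {
    cv <- config$covariates[[nm]]
    p <- truth$phase
    value <- if (cv$type == "rate") {
      sigma <- cv$iqr[p] / (1.349 * cv$median[p])
      cv$median[p] * exp(stats::rnorm(nrow(truth), 0, sigma))
    } else {
      rtrunc_norm(nrow(truth), cv$median[p], pmax(cv$iqr[p] / 1.349, 1e-6))
    }
    data.frame(country_id = truth$country_id, year = truth$year,
               indicator = nm, value = value, stringsAsFactors = FALSE)
  })
  covariates <- do.call(rbind, cov_list)
  rownames(covariates) <- NULL

  ## stream 3: wealth-quintile coverage -------------------------------------
  set.seed(config$seed + 303L)
  inst <- covariates[covariates$indicator == "institutional_birth", ]
  inst <- inst[match(paste(truth$country_id, truth$year),
                     paste(inst$country_id, inst$year)), ]
  p <- truth$phase
  off <- t(vapply(config$inequality_regime[p], regime_offsets, numeric(5)))
  qmat <- inst$value + off * config$inequality_gap[p] +
    matrix(stats::rnorm(nrow(truth) * 5, 0, config$quintile_noise_sd),
           ncol = 5)
  qmat <- pmin(pmax(qmat, 0), 100)
  quintiles_ib <- data.frame(country_id = truth$country_id, year = truth$year,
                             indicator = "institutional_birth",
                             q1 = qmat[, 1], q2 = qmat[, 2], q3 = qmat[, 3],
                             q4 = qmat[, 4], q5 = qmat[, 5],
                             national_mean = rowMeans(qmat),
                             stringsAsFactors = FALSE)
  cs_q1 <- rtrunc_norm(nrow(truth), config$csec_poorest[p], 1)
  cs_q5 <- rtrunc_norm(nrow(truth), config$csec_richest[p], 2)
  cs <- matrix(sapply(0:4, function(k) cs_q1 + (cs_q5 - cs_q1) * k / 4),
               ncol = 5)
  cs[, 2:4] <- pmin(pmax(cs[, 2:4] +
                           matrix(stats::rnorm(nrow(truth) * 3, 0, 0.5),
                                  ncol = 3), 0), 100)
  quintiles_cs <- data.frame(country_id = truth$country_id, year = truth$year,
                             indicator = "csec",
                             q1 = cs[, 1], q2 = cs[, 2], q3 = cs[, 3],
                             q4 = cs[, 4], q5 = cs[, 5],
                             national_mean = rowMeans(cs),
                             stringsAsFactors = FALSE)
  quintiles <- rbind(quintiles_ib, quintiles_cs)
  rownames(quintiles) <- NULL

  structure(list(panel = panel, covariates = covariates,
                 quintiles = quintiles, truth = truth,
                 config = config),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("Synthetic country panel: %d countries x %d year(s)\n",
              length(unique(x$panel$country_id)),
              length(unique(x$panel$year))))
  cat(sprintf("  panel: %d rows; covariates: %d rows (%s); quintiles: %d rows\n",
              nrow(x$panel), nrow(x$covariates),
              paste(unique(x$covariates$indicator), collapse = ", "),
              nrow(x$quintiles)))
  cat("  intended phases at baseline:",
      paste(table(x$truth$phase[x$truth$year == min(x$truth$year)]),
            collapse = " / "), "\n")
  invisible(x)
}
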