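# brute-force classification oracle, independent of classify_phases(): walk
# up from phase 1 and stop at the first knot either indicator has not yet
# fallen strictly below
oracle_phase <- function(mmr, sbn, th = phase_thresholds()) {
  phase <- 1L
  for (k in 1:4) {
    if (mmr < th$mmr_knots[k] && sbn < th$sbn_knots[k]) {
      phase <- k + 1L
    } else {
      break
    }
  }
  phase
}

# minimal valid country-year panel; bounds default to the point estimates
make_panel <- function(mmr, sbr, nmr, year = 2020,
                       country_id = sprintf("C%02d", seq_along(mmr)),
                       half_width = 0) {
  data.frame(country_id = country_id, year = year,
             mmr = mmr, mmr_lower = mmr * (1 - half_width),
             mmr_upper = mmr * (1 + half_width),
             sbr = sbr, sbr_lower = sbr * (1 - half_width),
             sbr_upper = sbr * (1 + half_width),
             nmr = nmr, nmr_lower = nmr * (1 - half_width),
             nmr_upper = nmr * (1 + half_width),
             stringsAsFactors = FALSE)
}

# random valid estimates spanning the whole mortality range
random_estimates <- function(n, half_width = 0.3) {
  mmr <- exp(runif(n, log(2), log(1500)))
  sbr <- exp(runif(n, log(0.5), log(60)))
  nmr <- exp(runif(n, log(0.5), log(60)))
  make_panel(mmr, sbr, nmr, country_id = sprintf("R%04d", seq_len(n)),
             half_width = half_width)
}
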