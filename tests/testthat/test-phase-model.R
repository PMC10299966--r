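test_that("thresholds are validated at construction", {
  expect_s3_class(phase_thresholds(), "phase_thresholds")
  expect_error(phase_thresholds(mmr_knots = c(700, 300, 100)), "exactly 4")
  expect_error(phase_thresholds(mmr_knots = c(700, 300, 300, 100)),
               "strictly decreasing")
  expect_error(phase_thresholds(sbn_knots = c(80, 55, 30, 0)),
               "strictly positive")
})

test_that("knot ratios reproduce the published 11/18/30/75 sequence", {
  kr <- knot_ratios(phase_thresholds())
  expect_equal(kr$ratio, c(100 * 80 / 700, 100 * 55 / 300, 30, 75))
  expect_equal(kr$ratio_rounded, c(11, 18, 30, 75))
  expect_true(all(diff(kr$ratio) > 0))
})

test_that("knot ratios follow direct arithmetic on custom thresholds", {
  kr <- knot_ratios(phase_thresholds(mmr_knots = c(800, 400, 200, 40)))
  expect_equal(kr$ratio, c(10, 13.75, 15, 37.5))
  # homogeneity: proportional knot vectors give identical ratios everywhere
  kr10 <- knot_ratios(phase_thresholds(mmr_knots = c(800, 400, 200, 40) / 10,
                                       sbn_knots = c(80, 55, 30, 15) / 10))
  kr1 <- knot_ratios(phase_thresholds(mmr_knots = c(800, 400, 200, 40),
                                      sbn_knots = c(80, 55, 30, 15)))
  expect_equal(kr10$ratio, kr1$ratio)
})

test_that("single-indicator classification keeps knot values in the higher-mortality phase", {
  mk <- phase_thresholds()$mmr_knots
  expect_equal(classify_indicator(700, mk), 1L)
  expect_equal(classify_indicator(19.99, mk), 5L)
  expect_equal(classify_indicator(c(750, 699.99, 300, 100, 20, 0), mk),
               c(1L, 2L, 2L, 3L, 4L, 5L))
  sk <- phase_thresholds()$sbn_knots
  expect_equal(classify_indicator(55, sk), 2L)
  expect_error(classify_indicator(-1, mk), "non-negative")
})

test_that("the dual-threshold min rule holds a country back until both indicators pass", {
  pa <- classify_phases(make_panel(650, 40, 45))  # sbn 85 still phase 1
  expect_equal(pa$phase_mmr, 2L)
  expect_equal(pa$phase_sbn, 1L)
  expect_equal(pa$phase, 1L)
  expect_equal(classify_phases(make_panel(10, 4, 6))$phase, 5L)
  # both exactly at the phase-2/3 knot: neither has passed below it
  expect_equal(classify_phases(make_panel(300, 20, 35))$phase, 2L)
})

test_that("classification agrees exactly with the brute-force oracle on a knot-spanning grid", {
  th <- phase_thresholds()
  mmr_grid <- sort(c(seq(1, 1400, length.out = 60), th$mmr_knots,
                     th$mmr_knots - 1e-9, th$mmr_knots + 1e-9))
  sbn_grid <- sort(c(seq(0.5, 120, length.out = 60), th$sbn_knots,
                     th$sbn_knots - 1e-9, th$sbn_knots + 1e-9))
  grid <- expand.grid(mmr = mmr_grid, sbn = sbn_grid)
  # sbr = 0 makes the panel's combined rate equal the grid's sbn exactly
  panel <- make_panel(grid$mmr, 0, grid$sbn,
                      country_id = sprintf("G%05d", seq_len(nrow(grid))))
  got <- classify_phases(panel, th)$phase
  want <- mapply(oracle_phase, grid$mmr, grid$sbn,
                 MoreArgs = list(th = th))
  expect_identical(got, as.integer(want))
  # the grid covers all 25 indicator-phase combinations
  pa <- classify_phases(panel, th)
  expect_equal(nrow(unique(pa[c("phase_mmr", "phase_sbn")])), 25L)
})

test_that("lowering either indicator never lowers the phase", {
  set.seed(21)
  panel <- random_estimates(300)
  base <- classify_phases(panel)$phase
  less_mmr <- panel
  less_mmr$mmr <- panel$mmr * 0.8
  less_nmr <- panel
  less_nmr$nmr <- panel$nmr * 0.8
  expect_true(all(classify_phases(less_mmr)$phase >= base))
  expect_true(all(classify_phases(less_nmr)$phase >= base))
})

test_that("bound variants order phases as lower >= point >= upper", {
  set.seed(22)
  panel <- random_estimates(500)
  lo <- classify_phases(panel, variant = "lower")$phase
  pt <- classify_phases(panel, variant = "point")$phase
  hi <- classify_phases(panel, variant = "upper")$phase
  expect_true(all(lo >= pt))
  expect_true(all(pt >= hi))
})

test_that("rows with missing estimates are dropped and counted, not imputed", {
  panel <- make_panel(c(100, 200, 300), c(10, 20, 30), c(15, 25, 35))
  panel$nmr[2] <- NA
  expect_message(pa <- classify_phases(panel), "1 row\\(s\\) dropped")
  expect_equal(nrow(pa), 2L)
  expect_equal(attr(pa, "n_dropped"), 1L)
  panel$mmr_lower <- NULL
  expect_error(classify_phases(panel, variant = "lower"), "mmr_lower")
})

test_that("uncertainty span is zero for degenerate intervals and averages knot crossings", {
  # bounds equal to the point estimates: no reclassification possible
  flat <- make_panel(c(150, 40), c(12, 5), c(18, 6), half_width = 0)
  sp <- uncertainty_phase_span(flat, year = 2020)
  expect_equal(sp$mean_span, 0)
  # one country straddles the 100-per-100,000 knot, the other does not
  two <- make_panel(c(110, 200), c(5, 5), c(10, 10))
  two$mmr_lower <- c(90, 190)
  two$mmr_upper <- c(130, 210)
  sp2 <- uncertainty_phase_span(two, year = 2020)
  expect_equal(sort(sp2$per_country$span), c(0L, 1L))
  expect_equal(sp2$mean_span, 0.5)
  expect_error(uncertainty_phase_span(two, year = 1999), "no rows")
})

test_that("wide uncertainty intervals produce a positive mean phase span", {
  set.seed(23)
  panel <- random_estimates(300, half_width = 0.3)
  sp <- uncertainty_phase_span(panel, year = 2020)
  expect_gt(sp$mean_span, 0)
  expect_equal(sp$n, 300L)
})
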