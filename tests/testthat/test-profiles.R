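make_cov <- function(values, phases, indicator = "tfr", year = 2020) {
  n <- length(values)
  list(cov = data.frame(country_id = sprintf("P%02d", 1:n), year = year,
                        indicator = indicator, value = values),
       asg = data.frame(country_id = sprintf("P%02d", 1:n), year = year,
                        phase = phases))
}

test_that("phase summaries use linear-interpolation quartiles", {
  x <- make_cov(c(1, 2, 3, 4, 5), rep(2, 5))
  prof <- phase_summaries(x$cov, x$asg, "tfr")
  expect_equal(prof$median, 3)
  expect_equal(prof$q1, 2)
  expect_equal(prof$q3, 4)
  expect_equal(prof$n, 5L)
  # a lone country collapses the whole profile to its value
  one <- make_cov(4.2, 3)
  p1 <- phase_summaries(one$cov, one$asg, "tfr")
  expect_equal(unlist(p1[c("median", "q1", "q3")], use.names = FALSE),
               rep(4.2, 3))
})

test_that("phase summaries are permutation-invariant and scale-equivariant", {
  set.seed(41)
  vals <- rlnorm(40, 1, 0.4)
  phases <- sample(1:5, 40, replace = TRUE)
  x <- make_cov(vals, phases)
  prof <- phase_summaries(x$cov, x$asg, "tfr")
  perm <- sample(40)
  xp <- make_cov(vals[perm], phases[perm])
  xp$cov$country_id <- sprintf("P%02d", perm)
  xp$asg$country_id <- sprintf("P%02d", perm)
  expect_equal(phase_summaries(xp$cov, xp$asg, "tfr"), prof,
               ignore_attr = TRUE)
  xs <- make_cov(vals * 3, phases)
  profs <- phase_summaries(xs$cov, xs$asg, "tfr")
  expect_equal(profs$median, prof$median * 3)
  expect_equal(profs$q1, prof$q1 * 3)
  expect_equal(profs$q3, prof$q3 * 3)
})

test_that("empty phases are absent and missing values are counted", {
  x <- make_cov(c(1, 2, NA, 4), c(1, 1, 1, 3))
  prof <- phase_summaries(x$cov, x$asg, "tfr")
  expect_equal(prof$phase, c(1L, 3L))
  expect_equal(attr(prof, "n_dropped"), 1L)
  expect_error(phase_summaries(x$cov, x$asg, "gdp"), "available.*tfr")
})

test_that("benchmarking flags values against the phase IQR", {
  prof <- list(q1 = 2.0, median = 2.8, q3 = 3.5)
  expect_equal(benchmark_country(2.8, prof), "typical")
  expect_equal(benchmark_country(3.5, prof), "typical")
  expect_equal(benchmark_country(3.5 + 1e-9, prof), "above_iqr")
  # a fertility rate of 4.0 is atypically high for that profile
  expect_equal(benchmark_country(4.0, prof), "above_iqr")
  expect_equal(benchmark_country(1.0, prof), "below_iqr")
  # multiplicative tolerance widens the band
  expect_equal(benchmark_country(3.8, prof, tolerance = 0.1), "typical")
})

test_that("the profile median is always typical", {
  set.seed(42)
  for (i in 1:20) {
    v <- sort(rlnorm(9, 0, 1))
    prof <- list(q1 = v[3], median = v[5], q3 = v[7])
    expect_equal(benchmark_country(prof$median, prof), "typical")
  }
})

test_that("cause-of-death shares reproduce the neonatal phase-1 breakdown", {
  shares <- cod_group_shares(
    c(sepsis = 24, prematurity = 41, intrapartum = 26, congenital = 9),
    default_cod_mapping("neonatal"))
  expect_equal(unname(shares), c(24, 41, 26, 9))
  expect_equal(names(shares), c("group1_infectious", "group2_health_nutrition",
                                "group3_peripartum", "other"))
  # single mapped cause takes the whole distribution
  only <- cod_group_shares(c(prematurity = 7), default_cod_mapping("neonatal"))
  expect_equal(unname(only), c(0, 100, 0, 0))
})

test_that("cause shares renormalise, stay order-invariant, and sum to 100", {
  mapping <- default_cod_mapping("maternal")
  tab <- c(haemorrhage = 30, sepsis = 20, indirect = 25,
           abortion_complications = 10, hypertensive_disorders = 15)
  a <- cod_group_shares(tab, mapping)
  b <- cod_group_shares(tab[c(3, 5, 1, 2, 4)], mapping)
  expect_equal(a, b)
  set.seed(43)
  for (i in 1:25) {
    w <- runif(length(tab), 0, 50)
    names(w) <- names(tab)
    expect_equal(sum(cod_group_shares(w, mapping)), 100, tolerance = 1e-6)
  }
})

test_that("unmapped causes error in strict mode and route to other when lenient", {
  mapping <- default_cod_mapping("neonatal")
  tab <- c(prematurity = 50, mystery_cause = 50)
  expect_error(cod_group_shares(tab, mapping), "mystery_cause")
  expect_message(len <- cod_group_shares(tab, mapping, mode = "lenient"),
                 "routed")
  expect_equal(unname(len["other"]), 50)
  expect_error(cod_group_shares(c(a = 0, b = 0), mapping, "lenient"),
               "sums to zero")
})

test_that("abortion score counts permitted grounds on a 0-100 scale", {
  expect_equal(abortion_score(rep(FALSE, 5)), 0)
  expect_equal(abortion_score(rep(TRUE, 5)), 100)
  expect_equal(abortion_score(c(TRUE, TRUE, TRUE, FALSE, FALSE)), 60)
  expect_error(abortion_score(c(TRUE, FALSE)), "exactly 5")
  # monotone: permitting one more ground never lowers the score
  set.seed(44)
  for (i in 1:20) {
    g <- sample(c(TRUE, FALSE), 5, replace = TRUE)
    w <- runif(5, 0.5, 2)
    if (all(g)) g[1] <- FALSE
    g2 <- g
    g2[which(!g)[1]] <- TRUE
    expect_gte(abortion_score(g2, w), abortion_score(g, w))
  }
})
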