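test_that("generator configuration is validated", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_per_phase = rep(0L, 5)), "zero countries")
  expect_error(generator_config(sb_nn_range = c(1.1, 0.7)), "increasing")
  expect_error(generator_config(progression_prob = rep(2, 5)),
               "probabilities")
  cfg <- default_published_config()
  expect_equal(cfg$covariates$tfr$median[1], 6.1)
  expect_equal(cfg$covariates$institutional_birth$median[5], 99)
  expect_equal(cfg$covariates$anc1$median[c(1, 5)], c(66, 98))
  expect_equal(cfg$covariates$anc4$median[c(1, 5)], c(44, 94))
  expect_equal(cfg$covariates$csec$median[c(1, 5)], c(2, 25))
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- generator_config(n_per_phase = rep(4L, 5), seed = 123L)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$quintiles, b$quintiles)
  expect_identical(a$truth, b$truth)
  c2 <- generate_panel(generator_config(n_per_phase = rep(4L, 5),
                                        seed = 124L))
  expect_false(identical(a$panel, c2$panel))
})

test_that("generated panels satisfy the estimate invariants", {
  s <- generate_panel(generator_config(n_per_phase = rep(8L, 5), seed = 2L))
  expect_silent(validate_panel(s$panel))
  for (ind in c("mmr", "sbr", "nmr")) {
    expect_true(all(s$panel[[paste0(ind, "_lower")]] <= s$panel[[ind]]))
    expect_true(all(s$panel[[ind]] <= s$panel[[paste0(ind, "_upper")]]))
  }
  expect_true(all(s$covariates$value > 0))
  qcols <- paste0("q", 1:5)
  expect_true(all(as.matrix(s$quintiles[qcols]) >= 0 &
                    as.matrix(s$quintiles[qcols]) <= 100))
})

test_that("stillbirth:neonatal ratios land inside the configured band", {
  s <- generate_panel(generator_config(n_per_phase = rep(10L, 5), seed = 3L))
  r <- sb_to_nn_ratio(s$panel$sbr, s$panel$nmr)
  expect_true(all(r > 0.7 & r < 1.1))
  narrow <- generate_panel(generator_config(n_per_phase = rep(10L, 5),
                                            sb_nn_range = c(0.9, 0.95),
                                            seed = 3L))
  rn <- sb_to_nn_ratio(narrow$panel$sbr, narrow$panel$nmr)
  expect_true(all(rn > 0.9 & rn < 0.95))
})

test_that("baseline classification recovers every intended phase", {
  s <- generate_panel(generator_config(n_per_phase = rep(10L, 5), seed = 4L))
  pa <- as.data.frame(classify_phases(s$panel))
  m <- merge(pa, s$truth, by = c("country_id", "year"),
             suffixes = c("_got", "_true"))
  base <- m[m$year == min(m$year), ]
  expect_equal(mean(base$phase_got == base$phase_true), 1)
  # later years too: progressors are redrawn inside their new phase box
  expect_equal(mean(m$phase_got == m$phase_true), 1)
})

test_that("combined mortality declines over time for non-progressing countries", {
  s <- generate_panel(generator_config(n_per_phase = rep(10L, 5),
                                       progression_prob = rep(0, 5),
                                       seed = 8L))
  w <- reshape(s$panel[c("country_id", "year", "mmr")],
               idvar = "country_id", timevar = "year", direction = "wide")
  expect_true(all(w$mmr.2020 <= w$mmr.2000))
})

test_that("the ratio of stillbirth+neonatal to maternal deaths rises as mortality falls", {
  s <- generate_panel(default_published_config(n_per_phase = rep(30L, 5),
                                           seed = 9L))
  sbn <- combine_sbn(s$panel$sbr, s$panel$nmr)
  ratio <- sbn_to_mmr_ratio(sbn, s$panel$mmr)
  med <- tapply(ratio, s$truth$phase[match(paste(s$panel$country_id, s$panel$year),
                                           paste(s$truth$country_id, s$truth$year))],
                median)
  expect_true(all(diff(med) > 0))
})
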