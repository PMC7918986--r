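test_that("concentration conversions match the molar-volume arithmetic", {
  # 1 ppb of benzene at 25 C: 78.11 g/mol over 24.45 L/mol, per 1000
  expect_equal(convert_concentration(1, "ppb", "ug_m3"),
               78.11 / 24.45 * 1000 / 1000)
  expect_equal(convert_concentration(1, "ppm", "ug_m3", "0C"),
               78.11 / 22.414 * 1000)
  # exact inverses
  x <- c(0.3, 3.24, 55)
  back <- convert_concentration(convert_concentration(x, "ppb", "ug_m3"),
                                "ug_m3", "ppb")
  expect_equal(back, x, tolerance = 1e-12)
  expect_equal(convert_concentration(0, "ppm", "ug_m3"), 0)
  expect_error(convert_concentration(1, "ppm", "mg_L"),
               class = "pumprisk_validation_error")
})

test_that("deterministic risk equals the hand-multiplied chain", {
  p <- risk_params() # as-printed: UR 2.2e-6 per ug/m3, ED/AT = 15/70
  # GM concentration, 3.08-minute fill, twice a month
  got <- deterministic_risk(p, 3.24 / 1000, 3.08 / 60 * 24)
  want <- 1e6 * 2.2e-6 * (3.24 / 1000 * 78.11 / 24.45 * 1000) *
    ((3.08 / 60) * 24 / 8760) * (15 / 70)
  expect_equal(got, want)
  expect_lt(abs(want - 6.86e-4), 1e-6) # order of magnitude sanity

  expect_equal(deterministic_risk(p, 0, 100), 0)
  # multiplicative linearity in UR, ED/AT and concentration
  p2 <- risk_params(unit_risk = 4.4e-6)
  expect_equal(deterministic_risk(p2, 0.003, 10),
               2 * deterministic_risk(p, 0.003, 10))
  p3 <- risk_params(exposure_duration_years = 30)
  expect_equal(deterministic_risk(p3, 0.003, 10),
               2 * deterministic_risk(p, 0.003, 10))
  expect_equal(deterministic_risk(p, 0.006, 10),
               2 * deterministic_risk(p, 0.003, 10))
  expect_error(deterministic_risk(p, -1, 10), class = "pumprisk_data_error")
})

test_that("degenerate input distributions collapse the MC onto the closed form", {
  dists <- fitted_distributions(lognormal_params(log(0.00324), 0),
                                truncnorm_params(3.08, 0, 0.5, 6),
                                positive_poisson_params(1e-9))
  p <- risk_params()
  sim <- simulate_consumer_risk(dists, p, n_iter = 500, seed = 1)
  want <- deterministic_risk(p, 0.00324, 3.08 / 60 * 12 * 1)
  expect_equal(unique(sim$draws), want)

  occ <- occupational_params(hours_sd = 1e-12, days_sd = 1e-12)
  p4 <- risk_params(scale = 1e4)
  sim_o <- simulate_occupational_risk(occ, lognormal_params(log(0.00324), 0),
                                      p4, n_iter = 500, seed = 2)
  want_o <- deterministic_risk(p4, 0.00324, 7 * 260)
  expect_equal(sim_o$draws, rep(want_o, 500), tolerance = 1e-9)
})

test_that("simulations are seed-reproducible and scale-checked", {
  dists <- default_consumer_distributions()
  a <- simulate_consumer_risk(dists, n_iter = 200, seed = 42)
  b <- simulate_consumer_risk(dists, n_iter = 200, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_true(all(a$draws > 0))
  expect_equal(a$n_iter, 200)

  expect_error(simulate_consumer_risk(dists, risk_params(scale = 1e4),
                                      n_iter = 10, seed = 1),
               class = "pumprisk_validation_error")
  expect_error(simulate_occupational_risk(occupational_params(),
                                          dists$concentration,
                                          risk_params(scale = 1e6),
                                          n_iter = 10, seed = 1),
               class = "pumprisk_validation_error")
})

test_that("log10 percentile summaries interpolate linearly", {
  const <- risk_distribution(rep(0.02, 10))
  s <- summarize_risk(const, c(5, 50, 95))
  expect_equal(s$log10_risk, rep(log10(0.02), 3))

  three <- risk_distribution(c(1, 10, 100))
  expect_equal(summarize_risk(three, 50)$log10_risk, 1)

  expect_equal(summarize_risk(three, c(50), digits = 1)$log10_risk, 1)
})

test_that("exceedance is strict and monotone in the threshold", {
  d <- risk_distribution(c(0.5, 1, 2))
  expect_equal(exceedance_fraction(d, 1), 1 / 3) # the draw at 1 is not above
  expect_equal(exceedance_fraction(d, 10), 0)
  thresholds <- c(0.1, 0.5, 1, 2, 5)
  fr <- vapply(thresholds, function(t) exceedance_fraction(d, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("rescaling between per-10K and per-1M multiplies draws by 100", {
  d <- risk_distribution(c(0.01, 0.02), scale = 1e4)
  r <- rescale_risk(d, 1e6)
  expect_equal(r$draws, c(1, 2))
  expect_equal(r$scale, 1e6)
})

test_that("consumer median log10 risk decomposes into factor medians", {
  dists <- default_consumer_distributions()
  p <- risk_params(convention = "calibrated")
  sim <- simulate_consumer_risk(dists, p, n_iter = 1e5, seed = 11)

  set.seed(11) # regenerate the same factor draws
  ca <- sample_lognormal(dists$concentration, 1e5)
  minutes <- sample_truncnorm(dists$fill_time, 1e5)
  fills <- sample_positive_poisson(dists$fill_frequency, 1e5)
  const <- 1e6 * 2.2e-6 * (78.11 / 24.45 * 1000) * (12 / 60) / 8760 * 0.5
  additive <- log10(const) + stats::median(log10(ca)) +
    stats::median(log10(minutes)) + stats::median(log10(fills))
  # additivity is approximate: the discrete, right-skewed fill-frequency
  # factor shifts the median of the sum ~0.04 below the sum of medians
  expect_lt(abs(stats::median(log10(sim$draws)) - additive), 0.05)
})

test_that("log10 spread between 95th and 50th percentiles is stable", {
  dists <- default_consumer_distributions()
  p_c <- risk_params(convention = "calibrated")
  sim_c <- simulate_consumer_risk(dists, p_c, n_iter = 1e5, seed = 21)
  s_c <- summarize_risk(sim_c, c(50, 95))
  # published percentiles are rounded to 0.1, so their difference carries
  # up to 0.1 of print slack
  expect_lt(abs(diff(s_c$log10_risk) - 0.8), 0.1)

  p_o <- risk_params(convention = "calibrated", scale = 1e4)
  sim_o <- simulate_occupational_risk(occupational_params(),
                                      dists$concentration, p_o,
                                      n_iter = 1e5, seed = 22)
  s_o <- summarize_risk(sim_o, c(50, 95))
  expect_lt(abs(diff(s_o$log10_risk) - 0.7), 0.05)
})

test_that("risk distributions persist to CSV + JSON and restore", {
  d <- simulate_consumer_risk(default_consumer_distributions(),
                              n_iter = 50, seed = 3)
  stem <- file.path(withr::local_tempdir(), "consumer_risk")
  write_risk_distribution(d, stem)
  back <- read_risk_distribution(stem)
  expect_equal(back$draws, d$draws)
  expect_equal(back$scale, d$scale)
  expect_equal(back$scenario, "consumer")
})
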