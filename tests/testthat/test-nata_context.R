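test_that("tract table reading validates content", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "tracts.csv")
  utils::write.csv(make_tracts(), path, row.names = FALSE)
  tab <- read_tracts(path)
  expect_s3_class(tab, "tract_table")
  expect_equal(nrow(tab), 2)

  utils::write.csv(make_tracts(risk = c(4.4, -1)), path, row.names = FALSE)
  expect_error(read_tracts(path), class = "pumprisk_data_error")

  utils::write.csv(make_tracts(population = c(-5, 1)), path,
                   row.names = FALSE)
  expect_error(read_tracts(path), class = "pumprisk_data_error")

  bad <- make_tracts()
  bad$tract_id <- c("dup", "dup")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_warning(tab2 <- read_tracts(path), "duplicated")
  expect_equal(nrow(tab2), 2)

  utils::write.csv(make_tracts()[0, ], path, row.names = FALSE)
  expect_error(read_tracts(path), class = "pumprisk_data_error")
})

test_that("weighted ambient draws follow the two-tract enumeration oracle", {
  # single tract: 0.8 r + 0.2 r = r exactly
  one <- make_tracts(risk = 7.7, population = 10, region = "city")
  set.seed(1)
  expect_equal(draw_ambient(one, 5), rep(7.7, 5))

  # populations {1, 0}: home always tract a; work uniform over both,
  # so E[draw] = 0.8 a + 0.2 (a + b) / 2 by enumerating the two outcomes
  two <- make_tracts(risk = c(4, 2), population = c(1, 0))
  set.seed(2)
  d <- draw_ambient(two, 2e4)
  expect_setequal(unique(d), c(0.8 * 4 + 0.2 * 4, 0.8 * 4 + 0.2 * 2))
  expect_lt(abs(mean(d) - (0.8 * 4 + 0.2 * 3)), 0.01)

  # equal populations reduce the home draw to uniform sampling
  eq <- make_tracts(risk = c(4, 2), population = c(3, 3))
  set.seed(3)
  expect_lt(abs(mean(draw_ambient(eq, 2e4)) - 3), 0.02)

  none <- make_tracts(population = c(0, 0))
  expect_error(draw_ambient(none, 1), class = "pumprisk_data_error")
})

test_that("generated city tracts reproduce the configured ambient mean", {
  tab <- generate_tracts(generator_config(n_city = 200, n_county = 0),
                         seed = 4)$tracts
  set.seed(5)
  d <- draw_ambient(tab, 1e5)
  expect_lt(abs(mean(d) - 4.4), 0.06)
})

test_that("ratio draws follow the closed form for degenerate inputs", {
  tracts <- make_tracts(risk = 4.4, population = 1, region = "city")
  pump <- risk_distribution(rep(10^0.4, 100), scale = 1e6)
  rd <- ratio_simulation(tracts, pump, n_iter = 200, seed = 6)
  expect_equal(unique(rd$draws), 0.4 - log10(4.4))

  # pumping identical to ambient: all ratios zero
  same <- risk_distribution(rep(4.4, 100), scale = 1e6)
  rd0 <- ratio_simulation(tracts, same, n_iter = 50, seed = 7)
  expect_equal(unique(rd0$draws), 0)

  # orientation flag negates the draws
  rd_inv <- ratio_simulation(tracts, pump, n_iter = 200, seed = 6,
                             orientation = "ambient_over_pumping")
  expect_equal(rd_inv$draws, -rd$draws)

  per10k <- risk_distribution(rep(0.1, 10), scale = 1e4)
  expect_error(ratio_simulation(tracts, per10k, n_iter = 5, seed = 1),
               class = "pumprisk_validation_error")
})

test_that("ratio summaries report percentiles and strict exceedance", {
  tracts <- make_tracts(risk = 2, population = 1, region = "city")
  pump <- risk_distribution(c(rep(1, 50), rep(4, 50)), scale = 1e6)
  rd <- ratio_simulation(tracts, pump, n_iter = 1e4, seed = 8)
  rs <- ratio_summary(rd, c(50, 95), threshold = 0)
  expect_equal(nrow(rs$percentiles), 2)
  expect_lt(abs(rs$exceedance - 0.5), 0.02) # half the draws are log10(2) > 0

  # exceedance monotone nonincreasing in the threshold
  fr <- vapply(c(-1, -0.5, 0, 0.5),
               function(t) ratio_summary(rd, 50, t)$exceedance, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("ratio median decomposes into risk median minus log ambient", {
  dists <- default_consumer_distributions()
  sim <- simulate_consumer_risk(dists, risk_params(convention = "calibrated"),
                                n_iter = 5e4, seed = 9)
  tracts <- generate_tracts(generator_config(), seed = 10)$tracts
  rd <- ratio_simulation(tracts, sim, n_iter = 5e4, seed = 11)
  set.seed(12)
  ambient_mean <- mean(draw_ambient(tracts, 5e4))
  lhs <- stats::median(rd$draws)
  rhs <- stats::median(log10(sim$draws)) - log10(ambient_mean)
  expect_lt(abs(lhs - rhs), 0.03)
})

test_that("ratio simulation is seed-reproducible", {
  tracts <- make_tracts()
  pump <- risk_distribution(exp(stats::rnorm(100)), scale = 1e6)
  a <- ratio_simulation(tracts, pump, n_iter = 100, seed = 13)
  b <- ratio_simulation(tracts, pump, n_iter = 100, seed = 13)
  expect_identical(a$draws, b$draws)
})
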