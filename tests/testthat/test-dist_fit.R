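test_that("lognormal fit works on the ln(ppm) scale", {
  p <- fit_lognormal(rep(3.24, 4))
  expect_equal(p$mu, log(0.00324))
  expect_equal(p$sigma, 0)

  # brute-force oracle for {1, 1000} ppb: mean of ln(0.001) and ln(1)
  p2 <- fit_lognormal(c(1, 1000))
  expect_equal(p2$mu, (log(0.001) + log(1)) / 2)

  # scaling inputs x10 shifts mu by ln(10), sigma unchanged
  x <- c(0.8, 3.1, 12)
  expect_equal(fit_lognormal(10 * x)$mu, fit_lognormal(x)$mu + log(10))
  expect_equal(fit_lognormal(10 * x)$sigma, fit_lognormal(x)$sigma)

  expect_error(fit_lognormal(c(1, 0)), class = "pumprisk_data_error")
})

test_that("truncated-normal fit uses raw sample moments, bounds affect sampling only", {
  p <- fit_truncnorm(c(3.08, 3.08))
  expect_equal(p$mean, 3.08)
  expect_equal(p$sd, 0)
  p2 <- fit_truncnorm(c(2, 4))
  expect_equal(p2$mean, 3)
  expect_equal(p2$sd, sqrt(2)) # |4-2|/sqrt(2) with the n-1 denominator
  # out-of-bounds observations still contribute to the moments
  p3 <- fit_truncnorm(c(0.1, 8))
  expect_equal(p3$mean, 4.05)
  expect_error(fit_truncnorm(3), class = "pumprisk_data_error")
})

test_that("positive-Poisson fit takes the raw mean of counts", {
  expect_equal(fit_positive_poisson(c(1, 2, 3))$lambda, 2)
  expect_equal(fit_positive_poisson(c(2, 2, 2))$lambda, 2)
  expect_equal(fit_positive_poisson(5)$lambda, 5)
  expect_error(fit_positive_poisson(c(0, 2)), class = "pumprisk_data_error")
  expect_error(fit_positive_poisson(c(1.5, 2)), class = "pumprisk_data_error")
})

test_that("samplers respect support, degenerate cases and seeding", {
  set.seed(1)
  expect_equal(sample_lognormal(lognormal_params(-5.73, 0), 10),
               rep(exp(-5.73), 10))

  tn <- truncnorm_params(3.08, 1.56, 0.5, 6)
  set.seed(2)
  draws <- sample_truncnorm(tn, 1e5)
  expect_gte(min(draws), 0.5)
  expect_lte(max(draws), 6)

  set.seed(3)
  k <- sample_positive_poisson(positive_poisson_params(2), 1e5)
  expect_gte(min(k), 1)
  expect_true(all(k == floor(k)))

  set.seed(99); a <- sample_truncnorm(tn, 100)
  set.seed(99); b <- sample_truncnorm(tn, 100)
  expect_identical(a, b)
})

test_that("zero-truncated Poisson matches its closed-form mean and pmf", {
  lam <- 2
  set.seed(4)
  k <- sample_positive_poisson(positive_poisson_params(lam), 1e5)
  # closed-form mean oracle: lambda / (1 - exp(-lambda)) ~ 2.313
  expect_lt(abs(mean(k) - lam / (1 - exp(-lam))), 0.02)

  # chi-square GOF against p(j) = e^-lam lam^j / (j! (1 - e^-lam)),
  # pooling j >= 8 so every expected count is comfortably large
  j <- 1:7
  p <- exp(-lam) * lam^j / (factorial(j) * (1 - exp(-lam)))
  obs <- tabulate(pmin(k, 8), nbins = 8)
  gof <- stats::chisq.test(obs, p = c(p, 1 - sum(p)))
  expect_gt(gof$p.value, 0.001)
})

test_that("truncated-normal sampler converges to numeric-integration moments", {
  tn <- truncnorm_params(3.08, 1.56, 0.5, 6)
  z <- stats::pnorm(6, 3.08, 1.56) - stats::pnorm(0.5, 3.08, 1.56)
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, 3.08, 1.56) / z,
                         0.5, 6)$value
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, 3.08, 1.56) / z,
                         0.5, 6)$value
  set.seed(5)
  draws <- sample_truncnorm(tn, 2e5)
  expect_lt(abs(mean(draws) - m1), 0.01)
  expect_lt(abs(stats::sd(draws) - sqrt(m2 - m1^2)), 0.01)
})

test_that("fits recover generating parameters from large samples", {
  set.seed(6)
  ppm_draws <- sample_lognormal(lognormal_params(-5.73, 0.98), 1e4)
  p <- fit_lognormal(ppm_draws * 1000) # back to ppb for the fitting surface
  expect_lt(abs(p$mu - (-5.73)), 0.03)
  expect_lt(abs(p$sigma - 0.98), 0.03)

  set.seed(7)
  k <- sample_positive_poisson(positive_poisson_params(2), 1e4)
  # the raw-mean parameterization targets the truncated mean, not lambda;
  # the MLE inverts the truncation and recovers the parent lambda
  expect_lt(abs(fit_positive_poisson(k)$lambda - 2 / (1 - exp(-2))), 0.05)
  expect_lt(abs(fit_positive_poisson(k, method = "mle")$lambda - 2), 0.05)

  set.seed(8)
  minutes <- sample_truncnorm(truncnorm_params(3.08, 1.56, 0.5, 6), 1e4)
  ft <- fit_truncnorm(minutes)
  # raw moments of truncated draws, not the parent parameters
  expect_lt(abs(ft$mean - mean(minutes)), 1e-12)
})

test_that("fitted parameters round-trip through JSON", {
  dists <- default_consumer_distributions()
  path <- withr::local_tempfile(fileext = ".json")
  write_fitted_params(dists, path, occupational = occupational_params())
  back <- read_fitted_params(path)
  expect_equal(back$dists, dists)
  expect_equal(back$occupational, occupational_params())
})
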