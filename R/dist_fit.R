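# Parameterization and sampling of the exposure-factor distributions.
#
# Consumer scenario: lognormal benzene concentration (natural log of ppm),
# truncated-normal fill time (minutes, bounded by the canister's operating
# window), zero-truncated Poisson fill frequency (fills per month).
# Occupational scenario: normal work hours/day and workdays/year.

#' Lognormal concentration parameters
#'
#' `mu` and `sigma` are the mean and standard deviation of the natural log
#' of the concentration in ppm.
#'
#' @param mu Log-scale location, `ln(ppm)`.
#' @param sigma Log-scale spread (unitless), `>= 0`.
#' @export
lognormal_params <- function(mu, sigma) {
  if (sigma < 0) stop_validation("sigma must be nonnegative")
  structure(list(mu = mu, sigma = sigma), class = "lognormal_params")
}

#' Truncated-normal fill-time parameters
#'
#' `mean` and `sd` are the moments of the untruncated parent normal (set
#' from the raw sample moments of the calculated fill times, not a
#' truncated-likelihood fit); `lower`/`upper` bound the sampled support.
#'
#' @param mean,sd Minutes; `sd >= 0`.
#' @param lower,upper Support bounds in minutes, `lower < upper`. Defaults
#'   0.5 and 6, the shortest plausible fill and the canister's six-minute
#'   operational limit.
#' @export
truncnorm_params <- function(mean, sd, lower = 0.5, upper = 6) {
  if (sd < 0) stop_validation("sd must be nonnegative")
  if (!(lower < upper)) stop_validation("lower bound must be below upper bound")
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper),
            class = "truncnorm_params")
}

#' Zero-truncated ("positive") Poisson parameters
#'
#' @param lambda Mean of the parent Poisson (here, the raw mean of the
#'   reported fill-up counts), `> 0`. Draws are conditioned on being
#'   `>= 1`: everyone in the study fills up at least once a month.
#' @export
positive_poisson_params <- function(lambda) {
  if (lambda <= 0) stop_validation("lambda must be positive")
  structure(list(lambda = lambda), class = "positive_poisson_params")
}

#' Occupational exposure-factor parameters
#'
#' Work hours per day and workdays per year, each normally distributed.
#' Defaults describe a full-time station attendant: 7 +/- 0.5 h of
#' near-pump time per day and 260 +/- 10 workdays per year.
#'
#' @param hours_mean,hours_sd Hours/day.
#' @param days_mean,days_sd Days/year.
#' @export
occupational_params <- function(hours_mean = 7, hours_sd = 0.5,
                                days_mean = 260, days_sd = 10) {
  if (any(c(hours_mean, hours_sd, days_mean, days_sd) <= 0)) {
    stop_validation("occupational parameters must be positive")
  }
  structure(list(hours_mean = hours_mean, hours_sd = hours_sd,
                 days_mean = days_mean, days_sd = days_sd),
            class = "occupational_params")
}

#' Bundle of fitted consumer exposure-factor distributions
#'
#' @param concentration [lognormal_params()] for the benzene air
#'   concentration.
#' @param fill_time [truncnorm_params()] for minutes per fill.
#' @param fill_frequency [positive_poisson_params()] for fills per month.
#' @export
fitted_distributions <- function(concentration, fill_time, fill_frequency) {
  stopifnot(inherits(concentration, "lognormal_params"),
            inherits(fill_time, "truncnorm_params"),
            inherits(fill_frequency, "positive_poisson_params"))
  structure(list(concentration = concentration, fill_time = fill_time,
                 fill_frequency = fill_frequency),
            class = "fitted_distributions")
}

#' @export
print.fitted_distributions <- function(x, ...) {
  cat(sprintf("concentration : lnN(mu = %.3f, sigma = %.3f)  [ln ppm]\n",
              x$concentration$mu, x$concentration$sigma))
  cat(sprintf("fill time     : Ntrunc(%.3f, %.3f, [%.2g, %.2g]) min\n",
              x$fill_time$mean, x$fill_time$sd, x$fill_time$lower,
              x$fill_time$upper))
  cat(sprintf("fill frequency: zero-truncated Pois(lambda = %.3f) /month\n",
              x$fill_frequency$lambda))
  invisible(x)
}

#' Reference consumer parameterization
#'
#' The published Baltimore consumer-fueling parameterization: benzene
#' concentration lnN(-5.73, 0.98) in ln(ppm) (geometric mean 3.24 ppb),
#' fill time Ntrunc(3.08, 1.56) minutes on \[0.5, 6\], and zero-truncated
#' Pois(2) fills per month. Useful for reproduction runs without the raw
#' samples; [fit_exposure_factors()] produces the same object from data.
#'
#' @return A [fitted_distributions()] object.
#' @export
default_consumer_distributions <- function() {
  fitted_distributions(
    concentration = lognormal_params(-5.73, 0.98),
    fill_time = truncnorm_params(3.08, 1.56, 0.5, 6),
    fill_frequency = positive_poisson_params(2)
  )
}

#' Fit the lognormal concentration distribution
#'
#' Log-transforms concentrations to natural log of ppm (`ppb/1000`) and
#' takes the sample mean and standard deviation on that scale.
#'
#' @param ppb Positive concentrations in ppb.
#' @return A [lognormal_params()] object (sigma is 0 for a single value).
#' @examples
#' fit_lognormal(rep(3.24, 5)) # mu = ln(0.00324) ~ -5.732
#' @export
fit_lognormal <- function(ppb) {
  if (length(ppb) < 1 || anyNA(ppb) || any(ppb <= 0)) {
    stop_data("lognormal fit requires strictly positive concentrations")
  }
  lx <- log(ppb / 1000)
  lognormal_params(mean(lx), if (length(lx) > 1) stats::sd(lx) else 0)
}

#' Fit the truncated-normal fill-time distribution
#'
#' Sets the parent normal's mean and sd to the raw sample moments of the
#' calculated fill times. The bounds affect sampling only; observed values
#' outside them still contribute to the moments.
#'
#' @param minutes Fill times in minutes (at least 2).
#' @param lower,upper Truncation bounds passed to [truncnorm_params()].
#' @export
fit_truncnorm <- function(minutes, lower = 0.5, upper = 6) {
  if (length(minutes) < 2 || anyNA(minutes)) {
    stop_data("truncated-normal fit requires at least 2 fill times")
  }
  truncnorm_params(mean(minutes), stats::sd(minutes), lower, upper)
}

#' Fit the zero-truncated Poisson fill-frequency distribution
#'
#' The default (`method = "mean"`) sets lambda to the arithmetic mean of
#' the reported counts — the parameterization used for the study's
#' fill-frequency factor. `method = "mle"` instead solves the
#' zero-truncated likelihood equation `lambda / (1 - exp(-lambda)) =
#' mean(counts)`, which recovers the parent lambda when the counts really
#' are zero-truncated Poisson draws.
#'
#' @param counts Positive integer fills-per-month counts.
#' @param method `"mean"` (raw sample mean, default) or `"mle"`.
#' @export
fit_positive_poisson <- function(counts, method = c("mean", "mle")) {
  method <- match.arg(method)
  if (length(counts) < 1 || anyNA(counts) ||
      any(counts < 1 | counts %% 1 != 0)) {
    stop_data("fill counts must be integers >= 1")
  }
  m <- mean(counts)
  lam <- if (method == "mean" || m <= 1) {
    m
  } else {
    stats::uniroot(function(l) ztp_mean(l) - m, c(1e-9, m),
                   tol = 1e-10)$root
  }
  positive_poisson_params(lam)
}

#' Fit all consumer exposure factors from QC'd samples
#'
#' Convenience wrapper: benzene concentration from `benzene_ppb`, fill
#' times from the canister vacuum pair via [estimate_fill_time()], fill
#' frequency from `fills_per_month`.
#'
#' @param samples An `exposure_samples` data frame with resolved
#'   concentrations (post-QC).
#' @param lower,upper Fill-time truncation bounds (minutes).
#' @param decay_rate Canister vacuum decay rate (mmHg/min).
#' @return A [fitted_distributions()] object.
#' @export
fit_exposure_factors <- function(samples, lower = 0.5, upper = 6,
                                 decay_rate = 5) {
  minutes <- estimate_fill_time(samples$initial_vacuum_mmHg,
                                samples$final_vacuum_mmHg, decay_rate)
  fitted_distributions(
    concentration = fit_lognormal(samples$benzene_ppb),
    fill_time = fit_truncnorm(minutes, lower, upper),
    fill_frequency = fit_positive_poisson(samples$fills_per_month)
  )
}

#' Samplers for the exposure-factor distributions
#'
#' Draws use R's global RNG stream so that a single `set.seed()` upstream
#' makes whole simulations reproducible.
#'
#' `sample_lognormal()` returns concentrations in ppm
#' (`exp(N(mu, sigma))`). `sample_truncnorm()` uses the inverse-CDF method
#' (a uniform draw mapped through the normal quantile function restricted
#' to the truncation interval), so every draw lies in `[lower, upper]`.
#' `sample_positive_poisson()` uses the inverse CDF of the parent Poisson
#' restricted to outcomes `>= 1` (exact, never emits 0).
#'
#' @param params The matching parameter object.
#' @param n Number of draws.
#' @return Numeric (or integer-valued) vector of length `n`.
#' @name samplers
NULL

#' @rdname samplers
#' @export
sample_lognormal <- function(params, n) {
  stopifnot(inherits(params, "lognormal_params"), n >= 1)
  exp(stats::rnorm(n, params$mu, params$sigma))
}

#' @rdname samplers
#' @export
sample_truncnorm <- function(params, n) {
  stopifnot(inherits(params, "truncnorm_params"), n >= 1)
  with(params, {
    if (sd == 0) {
      if (mean < lower || mean > upper) {
        stop_data("degenerate truncated normal: mean outside [lower, upper]")
      }
      return(rep(mean, n))
    }
    plo <- stats::pnorm((lower - mean) / sd)
    phi <- stats::pnorm((upper - mean) / sd)
    mean + sd * stats::qnorm(plo + stats::runif(n) * (phi - plo))
  })
}

#' @rdname samplers
#' @export
sample_positive_poisson <- function(params, n) {
  stopifnot(inherits(params, "positive_poisson_params"), n >= 1)
  p0 <- stats::ppois(0, params$lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), params$lambda)
}

# Normal draws constrained positive by resampling; at the occupational
# defaults a nonpositive draw has probability ~ pnorm(-14), so the loop is
# a guard, not a distortion.
sample_positive_normal <- function(mean, sd, n) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Mean of the zero-truncated Poisson: lambda / (1 - exp(-lambda)).
ztp_mean <- function(lambda) lambda / (1 - exp(-lambda))

#' Serialize fitted distributions to JSON
#'
#' Round-trippable, versioned schema covering the consumer bundle and,
#' optionally, occupational parameters.
#'
#' @param dists A [fitted_distributions()] object.
#' @param path Output JSON path.
#' @param occupational Optional [occupational_params()] to embed.
#' @export
write_fitted_params <- function(dists, path, occupational = NULL) {
  obj <- list(schema = "pumprisk/fitted-params/1",
              concentration = unclass(dists$concentration),
              fill_time = unclass(dists$fill_time),
              fill_frequency = unclass(dists$fill_frequency))
  if (!is.null(occupational)) obj$occupational <- unclass(occupational)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fitted_params
#' @return `read_fitted_params()` returns a list with `dists` and
#'   (possibly NULL) `occupational`.
#' @export
read_fitted_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "pumprisk/fitted-params/1")) {
    stop_validation("unrecognized fitted-params schema in %s", path)
  }
  dists <- fitted_distributions(
    concentration = lognormal_params(obj$concentration$mu,
                                     obj$concentration$sigma),
    fill_time = truncnorm_params(obj$fill_time$mean, obj$fill_time$sd,
                                 obj$fill_time$lower, obj$fill_time$upper),
    fill_frequency = positive_poisson_params(obj$fill_frequency$lambda)
  )
  occ <- NULL
  if (!is.null(obj$occupational)) {
    occ <- do.call(occupational_params, as.list(obj$occupational))
  }
  list(dists = dists, occupational = occ)
}
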