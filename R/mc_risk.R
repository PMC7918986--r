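# Excess lifetime cancer risk: deterministic chain and Monte Carlo.

#' Risk-equation parameters
#'
#' Scalar constants of the excess-risk chain
#' `scale * UR * CA * (ET/8760) * ED/AT`, plus the unit convention used to
#' apply the inhalation unit risk to concentration draws.
#'
#' The benzene inhalation unit risk is expressed per ug/m3 of lifetime
#' continuous exposure (the most conservative published value, 2.2e-6), so
#' concentration draws in ppm are converted to ug/m3 at the chosen
#' reference temperature by default. `ur_basis` can instead be `"ppb"` or
#' `"ppm"` for unit-risk values quoted on those bases.
#'
#' `convention = "calibrated"` sets `ed_at_override = 0.5`, a documented
#' calibration of the duration/averaging ratio that reproduces the
#' published percentile set; `"as_printed"` uses
#' `exposure_duration_years / averaging_time_years` (15/70). An explicit
#' `ed_at_override` always wins.
#'
#' @param unit_risk Inhalation unit risk (excess lifetime cancer risk per
#'   unit concentration on `ur_basis`).
#' @param exposure_duration_years Exposure duration ED (years); default 15,
#'   reflecting the 10-20 year latency window over which benzene exposure
#'   drives leukemia risk.
#' @param averaging_time_years Averaging time AT (years); default a
#'   70-year lifetime.
#' @param ed_at_override Optional dimensionless ratio replacing ED/AT.
#' @param convention `"as_printed"` or `"calibrated"` (see Details).
#' @param ur_basis Concentration basis of `unit_risk`: `"ug_m3"`, `"ppb"`
#'   or `"ppm"`.
#' @param temperature Reference temperature for ppm -> ug/m3 conversion:
#'   `"25C"` (molar volume 24.45 L/mol) or `"0C"` (22.414 L/mol).
#' @param scale Risk reporting scale: 1e6 (per million, general
#'   population) or 1e4 (per ten thousand, occupational).
#' @return A `risk_params` object.
#' @export
risk_params <- function(unit_risk = 2.2e-6, exposure_duration_years = 15,
                        averaging_time_years = 70, ed_at_override = NULL,
                        convention = c("as_printed", "calibrated"),
                        ur_basis = c("ug_m3", "ppb", "ppm"),
                        temperature = c("25C", "0C"), scale = 1e6) {
  convention <- match.arg(convention)
  ur_basis <- match.arg(ur_basis)
  temperature <- match.arg(temperature)
  if (unit_risk <= 0) stop_validation("unit_risk must be positive")
  if (exposure_duration_years <= 0 ||
      exposure_duration_years > averaging_time_years) {
    stop_validation("need 0 < ED <= AT")
  }
  if (!scale %in% c(1e6, 1e4)) {
    stop_validation("scale must be 1e6 (per 1M) or 1e4 (per 10K)")
  }
  if (is.null(ed_at_override) && convention == "calibrated") {
    ed_at_override <- 0.5
  }
  structure(list(unit_risk = unit_risk,
                 exposure_duration_years = exposure_duration_years,
                 averaging_time_years = averaging_time_years,
                 ed_at_override = ed_at_override,
                 convention = convention, ur_basis = ur_basis,
                 temperature = temperature, scale = scale),
            class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  cat(sprintf("UR %.3g per %s, ED/AT %s, scale per %s (%s convention)\n",
              x$unit_risk, x$ur_basis,
              if (is.null(x$ed_at_override)) {
                sprintf("%g/%g", x$exposure_duration_years,
                        x$averaging_time_years)
              } else sprintf("override %g", x$ed_at_override),
              format(x$scale, big.mark = ","), x$convention))
  invisible(x)
}

ed_at_ratio <- function(params) {
  params$ed_at_override %||%
    (params$exposure_duration_years / params$averaging_time_years)
}

#' Convert benzene air concentrations between units
#'
#' ppm, ppb and ug/m3, using the ideal-gas molar volume at the reference
#' temperature (1 ppm = 78.11 / 24.45 mg/m3 ~ 3194.7 ug/m3 at 25 C).
#' Conversions are exact inverses of one another.
#'
#' @param x Concentration value(s).
#' @param from,to Units: `"ppm"`, `"ppb"`, `"ug_m3"`.
#' @param temperature `"25C"` (default) or `"0C"`.
#' @export
convert_concentration <- function(x, from, to, temperature = "25C") {
  units <- c("ppm", "ppb", "ug_m3")
  if (!from %in% units || !to %in% units) {
    stop_validation("unknown concentration unit (use ppm, ppb or ug_m3)")
  }
  if (!temperature %in% names(MOLAR_VOLUME)) {
    stop_validation("temperature convention must be one of: %s",
                    paste(names(MOLAR_VOLUME), collapse = ", "))
  }
  ug_per_ppm <- BENZENE_MOLAR_MASS / MOLAR_VOLUME[[temperature]] * 1000
  ppm <- switch(from, ppm = x, ppb = x / 1000, ug_m3 = x / ug_per_ppm)
  switch(to, ppm = ppm, ppb = ppm * 1000, ug_m3 = ppm * ug_per_ppm)
}

# Express a ppm concentration on the unit-risk basis of `params`.
ca_on_ur_basis <- function(ca_ppm, params) {
  convert_concentration(ca_ppm, "ppm", params$ur_basis, params$temperature)
}

#' Deterministic excess lifetime cancer risk
#'
#' The point-estimate risk chain:
#' `scale * UR * CA * (ET/8760) * ED/AT`, where CA is the benzene
#' concentration (given in ppm, converted internally to the unit-risk
#' basis) and ET is aggregated to hours of exposure per year.
#'
#' @param params A [risk_params()] object.
#' @param ca_ppm Benzene concentration(s) in ppm.
#' @param et_hours_per_year Exposure hours per year.
#' @return Excess risk on `params$scale` (vectorized).
#' @examples
#' p <- risk_params()
#' # a 3.08-minute fill twice a month at the geometric-mean concentration
#' deterministic_risk(p, 3.24 / 1000, 3.08 / 60 * 24)
#' @export
deterministic_risk <- function(params, ca_ppm, et_hours_per_year) {
  stopifnot(inherits(params, "risk_params"))
  if (any(ca_ppm < 0) || any(et_hours_per_year < 0)) {
    stop_data("concentration and exposure time must be nonnegative")
  }
  params$scale * params$unit_risk * ca_on_ur_basis(ca_ppm, params) *
    (et_hours_per_year / HOURS_PER_YEAR) * ed_at_ratio(params)
}

#' Construct a risk distribution from existing draws
#'
#' Wraps a vector of excess-risk draws (e.g. from an external simulation
#' or a closed-form construction) in the container used throughout the
#' package.
#'
#' @param draws Positive excess-risk values on `scale`.
#' @param scale 1e6 (per million) or 1e4 (per ten thousand).
#' @param seed Seed that produced the draws (NA if not applicable).
#' @param scenario Label, e.g. `"consumer"`.
#' @export
risk_distribution <- function(draws, scale = 1e6, seed = NA_integer_,
                              scenario = "custom") {
  if (length(draws) == 0 || any(draws <= 0)) {
    stop_data("risk draws must be a nonempty positive vector")
  }
  if (!scale %in% c(1e6, 1e4)) stop_validation("scale must be 1e6 or 1e4")
  new_risk_distribution(draws, scale, seed, scenario, list())
}

new_risk_distribution <- function(draws, scale, seed, scenario, params) {
  structure(list(draws = draws, scale = scale, n_iter = length(draws),
                 seed = seed, scenario = scenario,
                 provenance = list(scenario = scenario, seed = seed,
                                   n_iter = length(draws),
                                   params = unclass(params))),
            class = "risk_distribution")
}

#' @export
print.risk_distribution <- function(x, ...) {
  q <- stats::quantile(log10(x$draws), c(0.5, 0.75, 0.95), names = FALSE)
  cat(sprintf("%s excess risk: %s draws per %s (seed %s)\n",
              x$scenario, format(x$n_iter, big.mark = ","),
              format(x$scale, big.mark = ","), format(x$seed)))
  cat(sprintf("  log10 percentiles 50/75/95: %.2f / %.2f / %.2f\n",
              q[1], q[2], q[3]))
  invisible(x)
}

#' Monte Carlo consumer excess-risk simulation
#'
#' Per iteration, draws a benzene concentration (ppm), a fill time
#' (minutes) and a fill frequency (fills/month), aggregates exposure to
#' hours/year as `(minutes / 60) * 12 * fills_per_month`, and applies the
#' deterministic risk chain. Consumer risk is reported per 1,000,000.
#'
#' @param dists A [fitted_distributions()] bundle.
#' @param params A [risk_params()] with `scale = 1e6`.
#' @param n_iter Number of Monte Carlo iterations (default 100,000).
#' @param seed RNG seed (required: reproduction runs must be seeded).
#' @return A `risk_distribution` object (all draws positive).
#' @export
simulate_consumer_risk <- function(dists, params = risk_params(),
                                   n_iter = 1e5, seed) {
  stopifnot(inherits(dists, "fitted_distributions"), n_iter >= 1)
  if (params$scale != 1e6) {
    stop_validation("consumer risk is reported per 1,000,000: set scale = 1e6")
  }
  set.seed(seed)
  ca <- sample_lognormal(dists$concentration, n_iter)
  minutes <- sample_truncnorm(dists$fill_time, n_iter)
  fills <- sample_positive_poisson(dists$fill_frequency, n_iter)
  hours_per_year <- minutes / 60 * 12 * fills
  draws <- deterministic_risk(params, ca, hours_per_year)
  new_risk_distribution(draws, params$scale, seed, "consumer", params)
}

#' Monte Carlo occupational excess-risk simulation
#'
#' Reuses the near-pump concentration distribution with occupational
#' exposure factors: hours/year = (hours/day) * (days/year), both normal
#' draws constrained positive. Occupational risk is reported per 10,000.
#'
#' @param occ An [occupational_params()] object.
#' @param conc [lognormal_params()] for the benzene concentration.
#' @param params A [risk_params()] with `scale = 1e4`.
#' @inheritParams simulate_consumer_risk
#' @return A `risk_distribution` object.
#' @export
simulate_occupational_risk <- function(occ, conc,
                                       params = risk_params(scale = 1e4),
                                       n_iter = 1e5, seed) {
  stopifnot(inherits(occ, "occupational_params"),
            inherits(conc, "lognormal_params"), n_iter >= 1)
  if (params$scale != 1e4) {
    stop_validation("occupational risk is reported per 10,000: set scale = 1e4")
  }
  set.seed(seed)
  ca <- sample_lognormal(conc, n_iter)
  hours <- sample_positive_normal(occ$hours_mean, occ$hours_sd, n_iter)
  days <- sample_positive_normal(occ$days_mean, occ$days_sd, n_iter)
  draws <- deterministic_risk(params, ca, hours * days)
  new_risk_distribution(draws, params$scale, seed, "occupational", params)
}

#' Rescale a risk distribution
#'
#' e.g. occupational per-10K draws times 100 onto the per-1M scale for
#' direct comparison with ambient risk.
#'
#' @param dist A `risk_distribution`.
#' @param scale Target scale (1e6 or 1e4).
#' @export
rescale_risk <- function(dist, scale = 1e6) {
  stopifnot(inherits(dist, "risk_distribution"))
  if (!scale %in% c(1e6, 1e4)) {
    stop_validation("scale must be 1e6 or 1e4")
  }
  dist$draws <- dist$draws * (scale / dist$scale)
  dist$scale <- scale
  dist
}

#' Percentiles of a risk distribution on the log10 scale
#'
#' Linear-interpolation percentiles (type 7) of `log10(draws)`.
#'
#' @param dist A `risk_distribution`.
#' @param percentiles Percentile levels in 0-100.
#' @param digits Optional rounding of the reported values.
#' @return Data frame with columns `percentile` and `log10_risk`.
#' @export
summarize_risk <- function(dist, percentiles = c(50, 75, 95), digits = NULL) {
  stopifnot(inherits(dist, "risk_distribution"))
  if (length(dist$draws) == 0) stop_data("empty risk distribution")
  q <- stats::quantile(log10(dist$draws), percentiles / 100, names = FALSE,
                       type = 7)
  if (!is.null(digits)) q <- round(q, digits)
  data.frame(percentile = percentiles, log10_risk = q)
}

#' Fraction of draws exceeding a risk-management threshold
#'
#' Strict exceedance: `mean(draws > threshold)`. On the per-1M scale a
#' threshold of 1.0 is the 1:1,000,000 general-population risk-management
#' level; on the per-10K scale, 1.0 is the 1:10,000 occupational level.
#'
#' @param dist A `risk_distribution`.
#' @param threshold Threshold on the same scale as the draws.
#' @export
exceedance_fraction <- function(dist, threshold = 1) {
  stopifnot(inherits(dist, "risk_distribution"))
  mean(dist$draws > threshold)
}

#' Persist / restore a risk distribution
#'
#' Draws go to `<stem>.csv` (single `risk` column) and metadata (scenario,
#' scale, seed, parameters) to `<stem>.json`.
#'
#' @param dist A `risk_distribution`.
#' @param stem Path stem without extension.
#' @export
write_risk_distribution <- function(dist, stem) {
  utils::write.csv(data.frame(risk = dist$draws), paste0(stem, ".csv"),
                   row.names = FALSE)
  meta <- list(schema = "pumprisk/risk-distribution/1",
               scenario = dist$scenario, scale = dist$scale,
               n_iter = dist$n_iter, seed = dist$seed,
               provenance = dist$provenance)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_risk_distribution
#' @export
read_risk_distribution <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, "pumprisk/risk-distribution/1")) {
    stop_validation("unrecognized risk-distribution schema at %s", stem)
  }
  draws <- utils::read.csv(paste0(stem, ".csv"))$risk
  out <- new_risk_distribution(draws, meta$scale, meta$seed, meta$scenario,
                               meta$provenance$params)
  out$provenance <- meta$provenance
  out
}
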