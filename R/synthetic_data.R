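# Synthetic exposure-sample and census-tract generators. The defaults
# emulate the statistical structure of the Baltimore consumer-fueling
# study data: lognormal BTEX/TVOC concentrations at the published
# geometric means, truncated-normal fill times encoded as a canister
# vacuum pair, zero-truncated Poisson fill frequency, and City/County
# ambient-risk tract tables.

#' Configuration for the synthetic data generator
#'
#' @param n_consumers Number of sample rows (default 32, the study's valid
#'   sample count). Anomaly injections transform existing rows, so the row
#'   count is always `n_consumers`.
#' @param gm,gsd Named per-compound geometric means (ppb) and geometric
#'   standard deviations for benzene, toluene, ethylbenzene, xylene, tvoc.
#' @param fill_mean,fill_sd Fill-time parent-normal moments (minutes).
#' @param fill_bounds Fill-time truncation bounds (minutes).
#' @param fills_lambda Zero-truncated Poisson mean for fills/month.
#' @param lod Named per-compound limits of detection (ppb); defaults sit
#'   below the observed concentration minima so censoring is rare unless
#'   raised.
#' @param initial_vacuum Canister evacuation magnitude (mmHg).
#' @param decay_rate Vacuum decay per sampled minute (mmHg/min), the
#'   encoding inverse of [estimate_fill_time()].
#' @param n_leak,n_outlier Number of rows to corrupt as a transport leak
#'   (flagged, vacuum fully lost) or a contamination outlier (all
#'   concentrations multiplied by `outlier_magnitude`).
#' @param outlier_magnitude Multiplicative contamination factor (default
#'   1000, i.e. three orders of magnitude).
#' @param n_city,n_county Tract counts for the two regions (defaults: the
#'   200 Baltimore City and 214 Baltimore County census tracts).
#' @param city_mean,city_sd,county_mean,county_sd Ambient excess cancer
#'   risk per 1,000,000 in each region (normal, truncated positive).
#' @param base_population Population assigned to every tract.
#' @param population_skew Multiplier on city-tract populations (1 = equal
#'   populations everywhere; >1 skews the population-weighted home draw
#'   toward city values).
#' @param temperature_mean,temperature_sd Sampling-day temperature model
#'   (deg C), descriptive only.
#' @param seed Default seed used by the generators when none is passed.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_consumers = 32,
                             gm = c(benzene = 3.24, toluene = 9.50,
                                    ethylbenzene = 1.99, xylene = 7.32,
                                    tvoc = 487),
                             gsd = c(benzene = 2.72, toluene = 3.50,
                                     ethylbenzene = 2.80, xylene = 3.01,
                                     tvoc = 3.06),
                             fill_mean = 3.08, fill_sd = 1.56,
                             fill_bounds = c(0.5, 6), fills_lambda = 2,
                             lod = c(benzene = 0.25, toluene = 0.75,
                                     ethylbenzene = 0.15, xylene = 0.75,
                                     tvoc = 30),
                             initial_vacuum = 30, decay_rate = 5,
                             n_leak = 0, n_outlier = 0,
                             outlier_magnitude = 1000,
                             n_city = 200, n_county = 214,
                             city_mean = 4.4, city_sd = 0.31,
                             county_mean = 3.76, county_sd = 0.39,
                             base_population = 4000, population_skew = 1,
                             temperature_mean = 19.7, temperature_sd = 8,
                             seed = NULL) {
  cfg <- list(n_consumers = n_consumers, gm = gm, gsd = gsd,
              fill_mean = fill_mean, fill_sd = fill_sd,
              fill_bounds = fill_bounds, fills_lambda = fills_lambda,
              lod = lod, initial_vacuum = initial_vacuum,
              decay_rate = decay_rate, n_leak = n_leak,
              n_outlier = n_outlier, outlier_magnitude = outlier_magnitude,
              n_city = n_city, n_county = n_county, city_mean = city_mean,
              city_sd = city_sd, county_mean = county_mean,
              county_sd = county_sd, base_population = base_population,
              population_skew = population_skew,
              temperature_mean = temperature_mean,
              temperature_sd = temperature_sd, seed = seed)
  if (n_consumers < 2) stop_validation("n_consumers must be at least 2")
  if (n_leak + n_outlier >= n_consumers) {
    stop_validation("anomaly injections must leave at least one clean sample")
  }
  if (any(gm <= 0) || any(gsd < 1) || any(lod <= 0) ||
      fill_sd < 0 || fills_lambda <= 0 || initial_vacuum <= 0 ||
      decay_rate <= 0 || city_sd < 0 || county_sd < 0 ||
      city_mean <= 0 || county_mean <= 0 || base_population <= 0 ||
      population_skew <= 0) {
    stop_validation("generator scale parameters must be positive (gsd >= 1)")
  }
  if (!setequal(names(gm), COMPOUNDS) || !setequal(names(gsd), COMPOUNDS) ||
      !setequal(names(lod), COMPOUNDS)) {
    stop_validation("gm, gsd and lod must be named for: %s",
                    paste(COMPOUNDS, collapse = ", "))
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic exposure-sample dataset
#'
#' Draws per-compound concentrations lognormally at the configured
#' GM/GSD, fill times from the truncated normal (encoded as a canister
#' vacuum pair: `final = initial - decay_rate * minutes`, the exact
#' inverse of [estimate_fill_time()]), and fills/month from the
#' zero-truncated Poisson. Values below the LOD are censored (`"<LOD"` in
#' the CSV). Injected anomalies (leaks, contamination outliers) are
#' recorded in a truth sidecar so QC behaviour can be checked against
#' known ground truth.
#'
#' @param cfg A [generator_config()].
#' @param dir Optional output directory; if given, writes `samples.csv`
#'   and `samples_truth.json` there.
#' @param seed RNG seed (falls back to `cfg$seed`).
#' @return Invisibly, a list with `samples` (an `exposure_samples` data
#'   frame, censored values unresolved), `truth` (injection record and
#'   drawn latent values) and `paths` (if written).
#' @export
generate_samples <- function(cfg = generator_config(), dir = NULL,
                             seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(seed)) stop_validation("generate_samples requires a seed")
  set.seed(seed)
  n <- cfg$n_consumers
  ids <- sprintf("consumer_%03d", seq_len(n))

  conc <- sapply(COMPOUNDS, function(cmp) {
    stats::rlnorm(n, log(cfg$gm[[cmp]]), log(cfg$gsd[[cmp]]))
  })
  minutes <- sample_truncnorm(
    truncnorm_params(cfg$fill_mean, cfg$fill_sd,
                     cfg$fill_bounds[1], cfg$fill_bounds[2]), n)
  fills <- sample_positive_poisson(positive_poisson_params(cfg$fills_lambda), n)
  temperature <- round(stats::rnorm(n, cfg$temperature_mean,
                                    cfg$temperature_sd), 1)

  anomaly_rows <- sample.int(n, cfg$n_leak + cfg$n_outlier)
  leak_rows <- anomaly_rows[seq_len(cfg$n_leak)]
  outlier_rows <- setdiff(anomaly_rows, leak_rows)
  if (length(outlier_rows) > 0) {
    conc[outlier_rows, ] <- conc[outlier_rows, ] * cfg$outlier_magnitude
  }

  final_vacuum <- cfg$initial_vacuum - cfg$decay_rate * minutes
  leaked <- rep(FALSE, n)
  if (length(leak_rows) > 0) {
    leaked[leak_rows] <- TRUE
    final_vacuum[leak_rows] <- 0 # transport leak: vacuum fully lost
  }

  samples <- data.frame(consumer_id = ids, stringsAsFactors = FALSE)
  for (cmp in COMPOUNDS) {
    value <- conc[, cmp]
    censored <- value < cfg$lod[[cmp]]
    value[censored] <- NA_real_
    samples[[conc_col(cmp)]] <- value
    samples[[cens_col(cmp)]] <- censored
    samples[[lod_col(cmp)]] <- rep(cfg$lod[[cmp]], n)
  }
  samples$initial_vacuum_mmHg <- rep(cfg$initial_vacuum, n)
  samples$final_vacuum_mmHg <- final_vacuum
  samples$fills_per_month <- fills
  samples$temperature_c <- temperature
  samples$leaked <- leaked
  class(samples) <- c("exposure_samples", "data.frame")

  truth <- list(schema = "pumprisk/samples-truth/1", seed = seed,
                n_consumers = n,
                leak_ids = ids[leak_rows], outlier_ids = ids[outlier_rows],
                fill_minutes = stats::setNames(minutes, ids),
                fills_per_month = stats::setNames(fills, ids),
                censored_counts = vapply(COMPOUNDS, function(cmp) {
                  sum(samples[[cens_col(cmp)]])
                }, integer(1)))

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(samples = file.path(dir, "samples.csv"),
                  truth = file.path(dir, "samples_truth.json"))
    write_samples_csv(samples, paths$samples)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(samples = samples, truth = truth, paths = paths))
}

# Write an exposure_samples frame in the documented CSV dialect:
# censored cells as "<LOD", numerics at full precision.
write_samples_csv <- function(samples, path) {
  out <- data.frame(consumer_id = samples$consumer_id,
                    stringsAsFactors = FALSE)
  num <- function(x) formatC(x, digits = 15, format = "g")
  for (cmp in COMPOUNDS) {
    cell <- num(samples[[conc_col(cmp)]])
    cell[samples[[cens_col(cmp)]]] <- "<LOD"
    out[[conc_col(cmp)]] <- cell
    out[[lod_col(cmp)]] <- num(samples[[lod_col(cmp)]])
  }
  out$initial_vacuum_mmHg <- num(samples$initial_vacuum_mmHg)
  out$final_vacuum_mmHg <- num(samples$final_vacuum_mmHg)
  out$fills_per_month <- samples$fills_per_month
  if (!is.null(samples$temperature_c)) {
    out$temperature_c <- num(samples$temperature_c)
  }
  out$leaked <- samples$leaked %||% FALSE
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic census-tract ambient-risk table
#'
#' City and county tract risks are drawn from the configured normals
#' (truncated to positive values by resampling); populations follow the
#' configured model (equal by default, with an optional city skew).
#'
#' @inheritParams generate_samples
#' @return Invisibly, a list with `tracts` (a `tract_table`) and `paths`
#'   (if written to `dir` as `tracts.csv`).
#' @export
generate_tracts <- function(cfg = generator_config(), dir = NULL,
                            seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(seed)) stop_validation("generate_tracts requires a seed")
  set.seed(seed)
  rpos <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    sample_positive_normal(mean, sd, n)
  }
  tab <- data.frame(
    tract_id = c(sprintf("24510-%04d", seq_len(cfg$n_city)),
                 sprintf("24005-%04d", seq_len(cfg$n_county))),
    region = rep(c("city", "county"), c(cfg$n_city, cfg$n_county)),
    population = c(rep(round(cfg$base_population * cfg$population_skew),
                       cfg$n_city),
                   rep(cfg$base_population, cfg$n_county)),
    ambient_risk_per_1M = c(rpos(cfg$n_city, cfg$city_mean, cfg$city_sd),
                            rpos(cfg$n_county, cfg$county_mean,
                                 cfg$county_sd)),
    stringsAsFactors = FALSE)
  tab <- validate_tracts(tab)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(tracts = file.path(dir, "tracts.csv"))
    utils::write.csv(tab, paths$tracts, row.names = FALSE)
  }
  invisible(list(tracts = tab, paths = paths))
}
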