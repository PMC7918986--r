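# Contextualization of pumping risk against ambient (census-tract) benzene
# cancer risk via the home/work weighted two-tract Monte Carlo.

#' Read a census-tract ambient-risk table
#'
#' Expects columns `tract_id`, `region` (`"city"` / `"county"`),
#' `population`, and `ambient_risk_per_1M` (ambient-benzene excess cancer
#' risk per 1,000,000, e.g. a NATA extract).
#'
#' @param path CSV path.
#' @return A validated `tract_table` data frame.
#' @export
read_tracts <- function(path) {
  if (!file.exists(path)) stop_validation("tracts file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("tract_id", "region", "population",
                       "ambient_risk_per_1M"), names(tab))
  if (length(missing) > 0) {
    stop_validation("tracts CSV is missing required column(s): %s",
                    paste(missing, collapse = ", "))
  }
  validate_tracts(tab)
}

validate_tracts <- function(tab) {
  if (nrow(tab) == 0) stop_data("tract table is empty")
  if (any(!is.finite(tab$ambient_risk_per_1M) | tab$ambient_risk_per_1M <= 0)) {
    stop_data("ambient risk must be positive for every tract")
  }
  if (any(!is.finite(tab$population) | tab$population < 0)) {
    stop_data("tract populations must be nonnegative")
  }
  if (anyDuplicated(tab$tract_id)) {
    warning("duplicated tract_id values in tract table; keeping all rows")
  }
  class(tab) <- c("tract_table", "data.frame")
  tab
}

#' Draw home/work weighted ambient risk values
#'
#' Each draw picks a home tract with probability proportional to
#' population and a work tract uniformly, both from the full table, and
#' returns the weighted ambient risk
#' `home_weight * home + (1 - home_weight) * work`. The default weights
#' (0.8 / 0.2) reflect an approximate 40-hour work week spent away from
#' the home tract.
#'
#' @param tracts A `tract_table` (see [read_tracts()]).
#' @param n Number of draws.
#' @param home_weight Weight on the home tract's ambient risk.
#' @return Numeric vector of `n` ambient risks per 1,000,000.
#' @export
draw_ambient <- function(tracts, n = 1, home_weight = 0.8) {
  stopifnot(inherits(tracts, "tract_table") || is.data.frame(tracts), n >= 1)
  if (sum(tracts$population) <= 0) {
    stop_data("cannot population-weight home tract: all populations are zero")
  }
  risk <- tracts$ambient_risk_per_1M
  home <- sample.int(nrow(tracts), n, replace = TRUE,
                     prob = tracts$population)
  work <- sample.int(nrow(tracts), n, replace = TRUE)
  home_weight * risk[home] + (1 - home_weight) * risk[work]
}

#' Monte Carlo ratio of pumping risk to ambient risk
#'
#' Per iteration, draws a weighted ambient risk ([draw_ambient()]) and a
#' pumping-risk value (bootstrap-resampled with replacement from the
#' stored Monte Carlo distribution, which is equivalent in distribution to
#' re-simulating) and records the base-10 log of their ratio. Values above
#' zero mean the pumping risk exceeds the ambient risk.
#'
#' The pumping distribution must be on the per-1M scale; rescale
#' occupational draws first (`rescale_risk(dist, 1e6)`).
#'
#' @param tracts A `tract_table`.
#' @param risk A `risk_distribution` on the per-1M scale.
#' @param n_iter Number of paired draws (default: the risk distribution's
#'   own iteration count).
#' @param seed RNG seed.
#' @param orientation `"pumping_over_ambient"` (default) or its inverse.
#' @param home_weight Passed to [draw_ambient()].
#' @return A `ratio_distribution`: log10 ratio draws plus provenance.
#' @export
ratio_simulation <- function(tracts, risk, n_iter = risk$n_iter, seed,
                             orientation = c("pumping_over_ambient",
                                             "ambient_over_pumping"),
                             home_weight = 0.8) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(risk, "risk_distribution"), n_iter >= 1)
  if (risk$scale != 1e6) {
    stop_validation(paste0("ratio simulation needs pumping risk per 1,000,000;",
                           " use rescale_risk(dist, 1e6) first"))
  }
  set.seed(seed)
  ambient <- draw_ambient(tracts, n_iter, home_weight)
  pumping <- sample(risk$draws, n_iter, replace = TRUE)
  draws <- log10(pumping / ambient)
  if (orientation == "ambient_over_pumping") draws <- -draws
  structure(list(draws = draws, n_iter = n_iter, seed = seed,
                 scenario = risk$scenario, orientation = orientation,
                 provenance = list(scenario = risk$scenario, seed = seed,
                                   n_iter = n_iter,
                                   orientation = orientation,
                                   home_weight = home_weight,
                                   n_tracts = nrow(tracts))),
            class = "ratio_distribution")
}

#' @export
print.ratio_distribution <- function(x, ...) {
  cat(sprintf("%s pumping/ambient log10 ratio: %s draws (seed %s)\n",
              x$scenario, format(x$n_iter, big.mark = ","), format(x$seed)))
  cat(sprintf("  median %.2f, fraction > 0: %.3f\n",
              stats::median(x$draws), mean(x$draws > 0)))
  invisible(x)
}

#' Summarize a ratio distribution
#'
#' @param rd A `ratio_distribution`.
#' @param percentiles Percentile levels in 0-100 (log10-ratio scale,
#'   linear interpolation).
#' @param threshold Exceedance threshold on the log10-ratio scale
#'   (default 0: pumping risk exceeds ambient risk).
#' @return A `ratio_summary` list: `percentiles` data frame, `exceedance`
#'   fraction of draws strictly above `threshold`, and the threshold.
#' @export
ratio_summary <- function(rd, percentiles = c(50, 75, 95), threshold = 0) {
  stopifnot(inherits(rd, "ratio_distribution"))
  if (length(rd$draws) == 0) stop_data("empty ratio distribution")
  q <- stats::quantile(rd$draws, percentiles / 100, names = FALSE, type = 7)
  structure(list(percentiles = data.frame(percentile = percentiles,
                                          log10_ratio = q),
                 exceedance = mean(rd$draws > threshold),
                 threshold = threshold, scenario = rd$scenario),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("%s log10(pumping/ambient) percentiles:\n", x$scenario))
  print(x$percentiles, row.names = FALSE)
  cat(sprintf("fraction of draws > %g: %.4f\n", x$threshold, x$exceedance))
  invisible(x)
}
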