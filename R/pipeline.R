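# Config-driven orchestration: generate -> assess -> contextualize, with
# one root seed split deterministically across stages and provenance
# embedded in every artifact.

#' Run configuration for the full pipeline
#'
#' @param samples,tracts Paths to the input CSVs (either may be NULL when
#'   [cmd_generate()] is used first; [run_pipeline()] fills them in).
#' @param output_dir Directory for all written artifacts.
#' @param scenario `"consumer"`, `"occupational"` or `"both"`.
#' @param n_iter Monte Carlo iterations per simulation.
#' @param seed Root seed; every stage seed is derived from it. Required.
#' @param convention Unit convention passed to [risk_params()]
#'   (`"as_printed"` or `"calibrated"`).
#' @param percentiles Percentile levels for the summary reports.
#' @param consumer_threshold,occupational_threshold Risk-management
#'   exceedance thresholds on the per-1M / per-10K scales.
#' @param ratio_threshold Exceedance threshold on the log10-ratio scale.
#' @param generator A [generator_config()] for `cmd_generate`.
#' @param risk Extra arguments for [risk_params()] (e.g. `ed_at_override`).
#' @param qc Extra arguments for [qc_filter()] (e.g. `outlier_factor`).
#' @return A `run_config` object.
#' @export
run_config <- function(samples = NULL, tracts = NULL, output_dir = ".",
                       scenario = c("both", "consumer", "occupational"),
                       n_iter = 1e5, seed = NULL,
                       convention = c("as_printed", "calibrated"),
                       percentiles = c(50, 75, 95),
                       consumer_threshold = 1, occupational_threshold = 1,
                       ratio_threshold = 0,
                       generator = generator_config(), risk = list(),
                       qc = list()) {
  scenario <- match.arg(scenario)
  convention <- match.arg(convention)
  if (is.null(seed)) stop_validation("run configuration requires a seed")
  structure(list(samples = samples, tracts = tracts,
                 output_dir = output_dir, scenario = scenario,
                 n_iter = n_iter, seed = as.integer(seed),
                 convention = convention, percentiles = percentiles,
                 consumer_threshold = consumer_threshold,
                 occupational_threshold = occupational_threshold,
                 ratio_threshold = ratio_threshold, generator = generator,
                 risk = risk, qc = qc),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [run_config()]; a `generator` mapping is
#' forwarded to [generator_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(obj$generator)) {
    gen <- obj$generator
    for (f in c("gm", "gsd", "lod")) {
      if (!is.null(gen[[f]])) gen[[f]] <- unlist(gen[[f]])
    }
    obj$generator <- do.call(generator_config, gen)
  }
  do.call(run_config, obj)
}

# Deterministic per-stage seeds from the root seed.
derive_seeds <- function(seed, stages = c("generate_samples",
                                          "generate_tracts", "consumer",
                                          "occupational", "ratio_consumer",
                                          "ratio_occupational")) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max, length(stages)), stages)
}

config_fingerprint <- function(cfg) {
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  sprintf("%08x", sum(utf8ToInt(json) * seq_along(utf8ToInt(json))) %%
            .Machine$integer.max)
}

write_provenance <- function(cfg, stage, path, extra = list()) {
  obj <- c(list(schema = "pumprisk/provenance/1", stage = stage,
                fingerprint = config_fingerprint(cfg),
                seeds = as.list(derive_seeds(cfg$seed)),
                config = unclass(cfg)), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Generate the synthetic input datasets
#'
#' Writes `samples.csv`, `samples_truth.json` and `tracts.csv` under the
#' configured output directory using seeds derived from the root seed.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the list of written paths.
#' @export
cmd_generate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- derive_seeds(cfg$seed)
  s <- generate_samples(cfg$generator, dir = cfg$output_dir,
                        seed = seeds[["generate_samples"]])
  t <- generate_tracts(cfg$generator, dir = cfg$output_dir,
                       seed = seeds[["generate_tracts"]])
  paths <- c(s$paths, t$paths)
  write_provenance(cfg, "generate",
                   file.path(cfg$output_dir, "generate_provenance.json"))
  invisible(paths)
}

#' Run the exposure-to-risk assessment
#'
#' Reads samples, resolves censoring, applies QC, fits the exposure
#' factors, simulates the requested scenario(s) and writes percentile
#' summaries, draw files and provenance to the output directory.
#'
#' @param cfg A [run_config()] whose `samples` path exists.
#' @return Invisibly, a list with the QC result, fitted distributions,
#'   per-scenario `risk_distribution`s and summary data frames.
#' @export
cmd_assess <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$samples)) stop_validation("config has no samples path")
  seeds <- derive_seeds(cfg$seed)
  out_dir <- cfg$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  samples <- substitute_lod(read_exposure_samples(cfg$samples))
  qc <- do.call(qc_filter, c(list(samples), cfg$qc))
  if (nrow(qc$kept) < 2) {
    stop_data("fewer than 2 samples survive QC; cannot fit distributions")
  }
  write_qc_report(qc, file.path(out_dir, "qc_report.csv"))
  dists <- fit_exposure_factors(qc$kept)
  write_fitted_params(dists, file.path(out_dir, "fitted_params.json"),
                      occupational = occupational_params())

  results <- list(qc = qc, dists = dists)
  scenarios <- if (cfg$scenario == "both") {
    c("consumer", "occupational")
  } else {
    cfg$scenario
  }
  for (sc in scenarios) {
    if (sc == "consumer") {
      params <- do.call(risk_params, c(list(convention = cfg$convention,
                                            scale = 1e6), cfg$risk))
      dist <- simulate_consumer_risk(dists, params, cfg$n_iter,
                                     seed = seeds[["consumer"]])
      threshold <- cfg$consumer_threshold
    } else {
      params <- do.call(risk_params, c(list(convention = cfg$convention,
                                            scale = 1e4), cfg$risk))
      dist <- simulate_occupational_risk(occupational_params(),
                                         dists$concentration, params,
                                         cfg$n_iter, seed = seeds[[sc]])
      threshold <- cfg$occupational_threshold
    }
    summary <- summarize_risk(dist, cfg$percentiles)
    summary$exceedance <- exceedance_fraction(dist, threshold)
    summary$threshold <- threshold
    utils::write.csv(summary,
                     file.path(out_dir, paste0(sc, "_risk_summary.csv")),
                     row.names = FALSE)
    write_risk_distribution(dist, file.path(out_dir, paste0(sc, "_risk")))
    results[[sc]] <- list(dist = dist, summary = summary)
  }
  write_provenance(cfg, "assess",
                   file.path(out_dir, "assess_provenance.json"),
                   extra = list(n_kept = nrow(qc$kept)))
  invisible(results)
}

#' Contextualize pumping risk against ambient tract risk
#'
#' Loads the stored risk draws for each assessed scenario, rescales
#' occupational draws to the per-1M scale, runs the home/work weighted
#' ratio Monte Carlo against the tract table and writes ratio summaries.
#'
#' @param cfg A [run_config()] whose `tracts` path exists and whose
#'   output directory holds draws written by [cmd_assess()].
#' @return Invisibly, per-scenario lists with the `ratio_distribution`
#'   and its `ratio_summary`.
#' @export
cmd_contextualize <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$tracts)) stop_validation("config has no tracts path")
  seeds <- derive_seeds(cfg$seed)
  tracts <- read_tracts(cfg$tracts)
  out_dir <- cfg$output_dir

  scenarios <- if (cfg$scenario == "both") {
    c("consumer", "occupational")
  } else {
    cfg$scenario
  }
  results <- list()
  for (sc in scenarios) {
    stem <- file.path(out_dir, paste0(sc, "_risk"))
    if (!file.exists(paste0(stem, ".csv"))) {
      stop_validation("no stored %s risk draws at %s; run cmd_assess first",
                      sc, stem)
    }
    dist <- read_risk_distribution(stem)
    if (dist$scale != 1e6) dist <- rescale_risk(dist, 1e6)
    rd <- ratio_simulation(tracts, dist, n_iter = cfg$n_iter,
                           seed = seeds[[paste0("ratio_", sc)]])
    rs <- ratio_summary(rd, cfg$percentiles, cfg$ratio_threshold)
    tab <- rs$percentiles
    tab$exceedance <- rs$exceedance
    tab$threshold <- rs$threshold
    utils::write.csv(tab,
                     file.path(out_dir, paste0(sc, "_ratio_summary.csv")),
                     row.names = FALSE)
    results[[sc]] <- list(ratio = rd, summary = rs)
  }
  write_provenance(cfg, "contextualize",
                   file.path(out_dir, "contextualize_provenance.json"))
  invisible(results)
}

#' Run the whole pipeline
#'
#' [cmd_generate()] (when no samples path is configured), then
#' [cmd_assess()], then [cmd_contextualize()]. Identical configuration and
#' seed give byte-identical reports.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the combined results of the assess and
#'   contextualize stages.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$samples)) {
    paths <- cmd_generate(cfg)
    cfg$samples <- paths$samples
    cfg$tracts <- paths$tracts
  }
  assessed <- cmd_assess(cfg)
  contextualized <- if (!is.null(cfg$tracts)) cmd_contextualize(cfg) else NULL
  invisible(list(assess = assessed, contextualize = contextualized))
}
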