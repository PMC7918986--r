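# Reading, quality control and summarization of personal exposure samples.

COMPOUNDS <- c("benzene", "toluene", "ethylbenzene", "xylene", "tvoc")
BTEX <- COMPOUNDS[1:4]

conc_col <- function(compound) paste0(compound, "_ppb")
lod_col <- function(compound) paste0("lod_", compound, "_ppb")
cens_col <- function(compound) paste0(compound, "_censored")

required_sample_cols <- function() {
  c("consumer_id", conc_col(COMPOUNDS), lod_col(COMPOUNDS),
    "initial_vacuum_mmHg", "final_vacuum_mmHg", "fills_per_month")
}

#' Read personal exposure samples from CSV
#'
#' Reads one fueling event per row. Concentration cells may carry the
#' sentinel `"<LOD"` for measurements below the limit of detection; these
#' are parsed as missing with the matching `<compound>_censored` flag set,
#' and are resolved later by [substitute_lod()].
#'
#' The required columns are `consumer_id`, `<compound>_ppb` and
#' `lod_<compound>_ppb` for benzene, toluene, ethylbenzene, xylene and
#' tvoc, `initial_vacuum_mmHg`, `final_vacuum_mmHg` and
#' `fills_per_month`. Optional columns: `temperature_c` (numeric) and
#' `leaked` (logical field note that a canister leaked in handling).
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @return A data frame of class `exposure_samples` with numeric
#'   concentration columns (NA where censored) and one logical
#'   `<compound>_censored` column per compound.
#' @seealso [substitute_lod()], [qc_filter()], [generate_samples()]
#' @export
read_exposure_samples <- function(path) {
  if (!file.exists(path)) stop_validation("samples file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing <- setdiff(required_sample_cols(), names(raw))
  if (length(missing) > 0) {
    stop_validation("samples CSV is missing required column(s): %s",
                    paste(missing, collapse = ", "))
  }

  out <- data.frame(consumer_id = raw$consumer_id, stringsAsFactors = FALSE)
  for (cmp in COMPOUNDS) {
    cell <- raw[[conc_col(cmp)]]
    censored <- grepl("^<\\s*LOD$", cell, ignore.case = TRUE)
    value <- rep(NA_real_, length(cell))
    value[!censored] <- parse_numeric(cell[!censored], conc_col(cmp),
                                      which(!censored))
    out[[conc_col(cmp)]] <- value
    out[[cens_col(cmp)]] <- censored
    out[[lod_col(cmp)]] <- parse_numeric(raw[[lod_col(cmp)]], lod_col(cmp))
  }
  out$initial_vacuum_mmHg <- parse_numeric(raw$initial_vacuum_mmHg,
                                           "initial_vacuum_mmHg")
  out$final_vacuum_mmHg <- parse_numeric(raw$final_vacuum_mmHg,
                                         "final_vacuum_mmHg")
  out$fills_per_month <- parse_numeric(raw$fills_per_month, "fills_per_month")
  if ("temperature_c" %in% names(raw)) {
    out$temperature_c <- parse_numeric(raw$temperature_c, "temperature_c")
  }
  out$leaked <- if ("leaked" %in% names(raw)) {
    tolower(raw$leaked) %in% c("true", "t", "1", "yes")
  } else {
    FALSE
  }

  validate_samples(out)
  class(out) <- c("exposure_samples", "data.frame")
  out
}

# Parse a character column to numeric with a row-indexed error on failure.
parse_numeric <- function(x, column, rows = seq_along(x)) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(is.na(x) | x == "" | toupper(x) == "NA")
  if (any(bad)) {
    i <- which(bad)[1]
    stop_data("row %d: non-numeric value '%s' in column %s",
              rows[i], x[i], column)
  }
  out
}

validate_samples <- function(s) {
  neg <- vapply(COMPOUNDS,
                function(cmp) any(s[[conc_col(cmp)]] < 0, na.rm = TRUE),
                logical(1))
  if (any(neg)) {
    stop_data("negative concentration in column %s",
              conc_col(COMPOUNDS[neg][1]))
  }
  if (any(s$final_vacuum_mmHg < 0, na.rm = TRUE)) {
    stop_data("negative final canister vacuum")
  }
  if (any(s$fills_per_month < 1 | s$fills_per_month %% 1 != 0, na.rm = TRUE)) {
    stop_data("fills_per_month must be a positive integer count")
  }
  invisible(s)
}

#' Substitute censored concentrations by LOD/sqrt(2)
#'
#' Replaces every below-detection concentration by its limit of detection
#' divided by the square root of two, the conventional substitution for
#' left-censored exposure data. Uncensored values are untouched and the
#' operation is idempotent.
#'
#' @param samples An `exposure_samples` data frame (see
#'   [read_exposure_samples()]).
#' @return The samples with all censored concentrations resolved;
#'   censoring flags are retained for provenance.
#' @export
substitute_lod <- function(samples) {
  for (cmp in COMPOUNDS) {
    cens <- samples[[cens_col(cmp)]]
    if (!any(cens)) next
    lod <- samples[[lod_col(cmp)]][cens]
    if (any(is.na(lod) | lod <= 0)) {
      stop_data("censored %s value with missing or nonpositive LOD (row %d)",
                cmp, which(cens)[which(is.na(lod) | lod <= 0)[1]])
    }
    samples[[conc_col(cmp)]][cens] <- lod / sqrt(2)
  }
  samples
}

#' Estimate fill time from canister vacuum decay
#'
#' The sampling canisters draw air at a constant flow, losing vacuum at a
#' fixed rate while open (5 mmHg per minute up to a six-minute operational
#' limit), so the fueling duration is the vacuum drop divided by the decay
#' rate. A zero drop means the canister was never opened.
#'
#' @param initial_vacuum,final_vacuum Canister vacuum magnitudes (mmHg)
#'   before deployment and on return. Vectorized.
#' @param decay_rate Vacuum loss per minute of active sampling (mmHg/min).
#' @return Fill time(s) in minutes.
#' @examples
#' estimate_fill_time(30, 14.6) # 3.08 minutes
#' @export
estimate_fill_time <- function(initial_vacuum, final_vacuum, decay_rate = 5) {
  if (any(final_vacuum > initial_vacuum)) {
    stop_data("final vacuum exceeds initial vacuum: canister vacuum cannot increase")
  }
  if (any(final_vacuum < 0) || any(initial_vacuum < 0)) {
    stop_data("canister vacuum magnitudes must be nonnegative")
  }
  (initial_vacuum - final_vacuum) / decay_rate
}

#' Quality-control filter for exposure samples
#'
#' Partitions samples into kept and excluded with a reason code:
#' \describe{
#'   \item{LEAK}{the `leaked` field note is set, the final vacuum exceeds
#'     the initial, or the vacuum drop exceeds what the operational window
#'     allows (`decay_rate * max_minutes`).}
#'   \item{CONTAMINATION_OUTLIER}{any BTEX concentration exceeds that
#'     compound's geometric mean across the candidate samples by more than
#'     `outlier_factor` (default 100, i.e. two orders of magnitude).}
#'   \item{UNUSED}{zero vacuum change — the canister was never opened.}
#' }
#' Censored concentrations must be resolved first ([substitute_lod()]).
#'
#' @param samples An `exposure_samples` data frame with resolved
#'   concentrations.
#' @param outlier_factor Multiplicative threshold over the compound
#'   geometric mean beyond which a sample is treated as contaminated.
#' @param decay_rate,max_minutes Canister operating constants defining the
#'   plausible vacuum-drop window.
#' @return A `qc_result`: list with `kept` (exposure_samples) and
#'   `excluded` (samples plus a `reason` column). Kept and excluded always
#'   partition the input.
#' @export
qc_filter <- function(samples, outlier_factor = 100, decay_rate = 5,
                      max_minutes = 6) {
  conc <- as.matrix(as.data.frame(samples)[, conc_col(BTEX)])
  if (anyNA(conc)) {
    stop_data("unresolved censored concentrations: apply substitute_lod() first")
  }
  drop <- samples$initial_vacuum_mmHg - samples$final_vacuum_mmHg
  leaked <- samples$leaked %||% rep(FALSE, nrow(samples))
  leak <- leaked |
    samples$final_vacuum_mmHg > samples$initial_vacuum_mmHg |
    drop > decay_rate * max_minutes + 1e-9
  unused <- !leak & drop == 0

  candidate <- !leak & !unused
  outlier <- rep(FALSE, nrow(samples))
  if (any(candidate)) {
    for (j in seq_along(BTEX)) {
      gm <- exp(mean(log(conc[candidate, j])))
      outlier <- outlier | (candidate & conc[, j] > outlier_factor * gm)
    }
  }

  reason <- rep(NA_character_, nrow(samples))
  reason[unused] <- "UNUSED"
  reason[outlier] <- "CONTAMINATION_OUTLIER"
  reason[leak] <- "LEAK"

  keep <- is.na(reason)
  kept <- samples[keep, , drop = FALSE]
  class(kept) <- class(samples)
  excluded <- as.data.frame(samples)[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]

  structure(list(kept = kept, excluded = excluded, n_input = nrow(samples)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("Exposure sample QC: %d of %d samples kept\n",
              nrow(x$kept), x$n_input))
  if (nrow(x$excluded) > 0) {
    tab <- table(x$excluded$reason)
    for (r in names(tab)) cat(sprintf("  excluded %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Write a QC exclusion report
#'
#' @param qc A `qc_result` from [qc_filter()].
#' @param path Output CSV path (`consumer_id`, `reason`).
#' @export
write_qc_report <- function(qc, path) {
  utils::write.csv(qc$excluded[, c("consumer_id", "reason")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Geometric summary statistics
#'
#' Geometric mean `exp(mean(log x))` and geometric standard deviation
#' `exp(sd(log x))` (sample standard deviation, n-1 denominator), the
#' natural summaries for lognormally distributed exposure data.
#'
#' @param x Positive concentrations.
#' @return A `geo_stats` list: `geometric_mean`, `geometric_sd`, `min`,
#'   `max`, `n`.
#' @export
geo_stats <- function(x) {
  if (length(x) < 2) stop_data("need at least 2 values for geometric summaries")
  if (anyNA(x) || any(x <= 0)) {
    stop_data("geometric statistics require strictly positive values")
  }
  lx <- log(x)
  structure(list(geometric_mean = exp(mean(lx)),
                 geometric_sd = exp(stats::sd(lx)),
                 min = min(x), max = max(x), n = length(x)),
            class = "geo_stats")
}

#' @export
print.geo_stats <- function(x, ...) {
  cat(sprintf("GM %.3g (GSD %.3g), range [%.3g, %.3g], n = %d\n",
              x$geometric_mean, x$geometric_sd, x$min, x$max, x$n))
  invisible(x)
}

#' Descriptive statistics for one compound
#'
#' @param samples An `exposure_samples` data frame with resolved
#'   concentrations.
#' @param compound One of `"benzene"`, `"toluene"`, `"ethylbenzene"`,
#'   `"xylene"`, `"tvoc"`.
#' @return A `geo_stats` summary of that compound's concentrations (ppb).
#' @export
descriptive_stats <- function(samples, compound = "benzene") {
  compound <- match.arg(compound, COMPOUNDS)
  geo_stats(samples[[conc_col(compound)]])
}

#' Descriptive statistics for all compounds
#'
#' @inheritParams descriptive_stats
#' @return A data frame with one row per compound: geometric mean and GSD,
#'   range and n.
#' @export
descriptive_stats_table <- function(samples) {
  rows <- lapply(COMPOUNDS, function(cmp) {
    g <- descriptive_stats(samples, cmp)
    data.frame(compound = cmp, geometric_mean_ppb = g$geometric_mean,
               geometric_sd = g$geometric_sd, min_ppb = g$min,
               max_ppb = g$max, n = g$n)
  })
  do.call(rbind, rows)
}

#' Count samples below occupational exposure limits
#'
#' Counts samples whose concentration is strictly below each limit, e.g.
#' the benzene NIOSH REL (100 ppb) and OSHA PEL (1000 ppb), both 8-h
#' time-weighted averages. A sample exactly at a limit is not "below" it.
#'
#' @param samples An `exposure_samples` data frame with resolved
#'   concentrations.
#' @param limits Named numeric vector of limits in ppb.
#' @param compound Compound to compare.
#' @return Named integer vector of counts below each limit.
#' @export
compare_to_limits <- function(samples, limits = c(REL = 100, PEL = 1000),
                              compound = "benzene") {
  compound <- match.arg(compound, COMPOUNDS)
  x <- samples[[conc_col(compound)]]
  if (anyNA(x)) {
    stop_data("unresolved censored concentrations: apply substitute_lod() first")
  }
  vapply(limits, function(lim) sum(x < lim), integer(1))
}
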