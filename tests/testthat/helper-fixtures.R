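# Fixtures are built in code: a small hand-specified sample frame plus a
# CSV writer matching the documented dialect.

compound_names <- c("benzene", "toluene", "ethylbenzene", "xylene", "tvoc")

# A clean exposure_samples frame with controllable benzene values.
make_samples <- function(benzene = c(2, 3, 4, 5),
                         fill_minutes = rep(3, length(benzene)),
                         fills = rep(2, length(benzene)),
                         leaked = rep(FALSE, length(benzene)),
                         censored = rep(FALSE, length(benzene)),
                         lod_benzene = 1) {
  n <- length(benzene)
  s <- data.frame(consumer_id = sprintf("c%02d", seq_len(n)),
                  stringsAsFactors = FALSE)
  values <- list(benzene = benzene, toluene = benzene * 3,
                 ethylbenzene = benzene * 0.6, xylene = benzene * 2,
                 tvoc = benzene * 150)
  for (cmp in compound_names) {
    v <- values[[cmp]]
    cens <- if (cmp == "benzene") censored else rep(FALSE, n)
    v[cens] <- NA_real_
    s[[paste0(cmp, "_ppb")]] <- v
    s[[paste0(cmp, "_censored")]] <- cens
    s[[paste0("lod_", cmp, "_ppb")]] <- if (cmp == "benzene") {
      rep(lod_benzene, n)
    } else {
      rep(0.1, n)
    }
  }
  s$initial_vacuum_mmHg <- rep(30, n)
  s$final_vacuum_mmHg <- 30 - 5 * fill_minutes
  s$fills_per_month <- fills
  s$temperature_c <- rep(20, n)
  s$leaked <- leaked
  class(s) <- c("exposure_samples", "data.frame")
  s
}

# Minimal valid samples CSV text (3 rows, one censored benzene cell).
write_sample_csv <- function(path, drop_column = NULL, bad_cell = FALSE) {
  header <- c("consumer_id",
              paste0(compound_names, "_ppb"),
              paste0("lod_", compound_names, "_ppb"),
              "initial_vacuum_mmHg", "final_vacuum_mmHg", "fills_per_month",
              "temperature_c")
  row <- function(id, benzene, final) {
    c(id, benzene, "9.5", "2.0", "7.3", "487",
      "1.0", "0.75", "0.15", "0.75", "30",
      "30", final, "2", "21.5")
  }
  rows <- list(row("c01", "3.24", "14.6"),
               row("c02", "<LOD", "20.0"),
               row("c03", if (bad_cell) "oops" else "6.1", "10.0"))
  keep <- if (is.null(drop_column)) {
    seq_along(header)
  } else {
    which(header != drop_column)
  }
  lines <- c(paste(header[keep], collapse = ","),
             vapply(rows, function(r) paste(r[keep], collapse = ","),
                    character(1)))
  writeLines(lines, path)
  path
}

make_tracts <- function(risk = c(4.4, 3.76), population = c(1, 1),
                        region = NULL) {
  n <- length(risk)
  region <- region %||% rep(c("city", "county"), length.out = n)
  tab <- data.frame(tract_id = sprintf("t%03d", seq_len(n)),
                    region = region, population = population,
                    ambient_risk_per_1M = risk, stringsAsFactors = FALSE)
  class(tab) <- c("tract_table", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
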