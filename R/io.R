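.fmt_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
.parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S",
                                    tz = "UTC")

# write a data frame with timestamps in ISO-8601 and coordinates at full
# double precision
.write_table <- function(d, path, full = character()) {
  for (nm in names(d)) {
    if (inherits(d[[nm]], "POSIXct")) d[[nm]] <- .fmt_ts(d[[nm]])
    if (inherits(d[[nm]], "Date")) d[[nm]] <- format(d[[nm]])
    if (nm %in% full) d[[nm]] <- sprintf("%.17g", d[[nm]])
  }
  write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Serializes the output of [simulate_pups()] as plain-text CSV tables
#' (`fixes.csv`, `weather.csv`, `metadata.csv`, `biometrics.csv`,
#' `attendance.csv`) plus a `truth.json` holding the generating parameters
#' and the per-step true states. Timestamps are ISO-8601 UTC; coordinates
#' are written at full double precision so a round trip reproduces them
#' exactly.
#'
#' @param sim Output of [simulate_pups()].
#' @param out_dir Directory to create/write into.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", out_dir)
  .write_table(sim$fixes, file.path(out_dir, "fixes.csv"),
               full = c("lat", "lon"))
  .write_table(sim$weather, file.path(out_dir, "weather.csv"),
               full = c("temp_c", "wind_speed"))
  .write_table(sim$metadata, file.path(out_dir, "metadata.csv"))
  .write_table(sim$biometrics, file.path(out_dir, "biometrics.csv"),
               full = c("mass_kg", "length_cm"))
  .write_table(sim$attendance, file.path(out_dir, "attendance.csv"))
  tr <- sim$truth
  truth <- list(
    beta = tr$beta, emission = tr$emission,
    scaling = tr$scaling, homes = tr$homes,
    states = lapply(split(tr$states, tr$states$id), function(d)
      list(timestamp = .fmt_ts(d$timestamp), state = d$state,
           step_m = d$step_m)),
    missing = list(id = tr$missing$id,
                   timestamp = .fmt_ts(tr$missing$timestamp)),
    outliers = list(id = tr$outliers$id,
                    timestamp = .fmt_ts(tr$outliers$timestamp)),
    seed = tr$config$seed)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(out_dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the CSV tables (and optionally
#'   `truth.json`).
#' @return List with elements `fixes`, `weather`, `metadata`,
#'   `biometrics`, `attendance` and (if present) `truth`.
#' @export
read_dataset <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  fixes <- rd("fixes.csv")
  fixes$timestamp <- .parse_ts(fixes$timestamp)
  weather <- rd("weather.csv")
  weather$timestamp <- .parse_ts(weather$timestamp)
  metadata <- rd("metadata.csv")
  metadata$birth_date <- as.Date(metadata$birth_date)
  metadata$death_date <- as.Date(metadata$death_date)
  metadata$year <- as.character(metadata$year)
  biometrics <- rd("biometrics.csv")
  biometrics$date <- as.Date(biometrics$date)
  attendance <- rd("attendance.csv")
  attendance$date <- as.Date(attendance$date)
  out <- list(fixes = fixes, weather = weather, metadata = metadata,
              biometrics = biometrics, attendance = attendance)
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) out$truth <- jsonlite::read_json(tf,
                                                        simplifyVector = TRUE)
  out
}
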