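#' Regularize raw GPS fixes onto the nominal sampling grid
#'
#' Snaps each fix to the nearest instant of a regular grid (default hourly)
#' spanning the first to last fix of each individual, and inserts explicit
#' missing rows for grid instants with no fix. If two fixes snap to the
#' same instant the nearer one wins and a warning is issued.
#'
#' @param fixes Data frame with columns `id`, `timestamp` (POSIXct),
#'   `lat`, `lon` (decimal degrees).
#' @param interval Nominal sampling interval in minutes.
#' @return Data frame `id`, `timestamp`, `lat`, `lon` with one row per grid
#'   instant per individual; unmatched instants have `NA` coordinates.
#'   Attribute `n_duplicates` counts fixes dropped in snapping conflicts.
#' @export
regularize <- function(fixes, interval = 60) {
  cols <- c("id", "timestamp", "lat", "lon")
  stopifnot(all(cols %in% names(fixes)))
  if (!nrow(fixes)) {
    out <- fixes[, cols]
    attr(out, "n_duplicates") <- 0L
    return(out)
  }
  sec <- interval * 60
  ndup <- 0L
  out <- lapply(split(fixes, fixes$id), function(d) {
    d <- d[order(d$timestamp), ]
    t <- as.numeric(d$timestamp)
    t0 <- round(t[1] / sec) * sec
    t1 <- round(t[length(t)] / sec) * sec
    grid <- seq(t0, t1, by = sec)
    idx <- round((t - t0) / sec) + 1
    off <- abs(t - grid[pmin(pmax(idx, 1), length(grid))])
    keep <- idx >= 1 & idx <= length(grid)
    lat <- lon <- rep(NA_real_, length(grid))
    best <- rep(Inf, length(grid))
    for (k in which(keep)) {
      if (off[k] < best[idx[k]]) {
        if (is.finite(best[idx[k]])) ndup <<- ndup + 1L
        best[idx[k]] <- off[k]
        lat[idx[k]] <- d$lat[k]
        lon[idx[k]] <- d$lon[k]
      } else ndup <<- ndup + 1L
    }
    data.frame(id = d$id[1],
               timestamp = as.POSIXct(grid, origin = "1970-01-01",
                                      tz = "UTC"),
               lat = lat, lon = lon)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (ndup > 0)
    warning(ndup, " fix(es) discarded: multiple fixes snapped to one grid instant")
  attr(out, "n_duplicates") <- ndup
  out
}

#' Step lengths between consecutive regularized fixes
#'
#' Great-circle (haversine, Earth radius 6,371,000 m) distance between each
#' grid instant and the next, in metres. A step is missing if either fix is
#' missing; the last instant of each individual has no step.
#'
#' @param gridded Output of [regularize()].
#' @return `gridded` with an added `step_m` column.
#' @export
compute_steps <- function(gridded) {
  n <- nrow(gridded)
  step <- rep(NA_real_, n)
  if (n > 1) {
    same <- gridded$id[-n] == gridded$id[-1]
    ok <- same & !is.na(gridded$lat[-n]) & !is.na(gridded$lat[-1])
    if (any(ok)) {
      i <- which(ok)
      step[i] <- geosphere::distHaversine(
        cbind(gridded$lon[i], gridded$lat[i]),
        cbind(gridded$lon[i + 1], gridded$lat[i + 1]), r = 6371000)
    }
  }
  gridded$step_m <- step
  gridded
}

#' Censor implausibly fast steps
#'
#' Sets steps strictly greater than the speed threshold to missing. The
#' default 400 m/h reflects the fastest plausible hourly pup movement; for
#' other sampling intervals the threshold is scaled proportionally.
#'
#' @param steps Numeric vector of step lengths in metres per interval.
#' @param threshold Speed threshold in metres per hour.
#' @param interval Sampling interval in minutes.
#' @return List with `step` (censored vector), `n_censored`, and
#'   `censored_idx` (indices replaced).
#' @export
censor_steps <- function(steps, threshold = 400, interval = 60) {
  stopifnot(threshold > 0)
  thr <- threshold * interval / 60
  idx <- which(!is.na(steps) & steps > thr)
  steps[idx] <- NA_real_
  list(step = steps, n_censored = length(idx), censored_idx = idx)
}

#' Split tracks at long observation gaps and drop short bursts
#'
#' Cuts each individual's regularized track wherever the gap between
#' consecutive observed fixes exceeds `max_gap` hours, trims each resulting
#' burst to its first and last observed fix, and drops bursts spanning less
#' than `min_span` hours (first-to-last instant). Burst indices are
#' consecutive from 1 within each individual.
#'
#' @param gridded Output of [regularize()] (optionally with `step_m`).
#' @param max_gap Maximum tolerated observation gap, hours.
#' @param min_span Minimum burst span, hours.
#' @return Rows of `gridded` belonging to kept bursts, with a `burst`
#'   column. Attribute `report`: counts of bursts kept/dropped and grid
#'   rows dropped.
#' @export
split_and_filter_bursts <- function(gridded, max_gap = 4, min_span = 48) {
  kept <- 0L; dropped <- 0L; rows_dropped <- 0L
  out <- lapply(split(gridded, gridded$id), function(d) {
    d <- d[order(d$timestamp), ]
    pres <- which(!is.na(d$lat))
    if (!length(pres)) {
      rows_dropped <<- rows_dropped + nrow(d)
      return(NULL)
    }
    t <- as.numeric(d$timestamp) / 3600
    gap_after <- diff(t[pres])
    seg_start <- pres[c(1L, which(gap_after > max_gap) + 1L)]
    seg_end <- pres[c(which(gap_after > max_gap), length(pres))]
    res <- NULL
    b <- 0L
    for (s in seq_along(seg_start)) {
      span <- t[seg_end[s]] - t[seg_start[s]]
      if (span >= min_span) {
        b <- b + 1L
        kept <<- kept + 1L
        piece <- d[seg_start[s]:seg_end[s], , drop = FALSE]
        piece$burst <- b
        res <- rbind(res, piece)
      } else dropped <<- dropped + 1L
    }
    rows_dropped <<- rows_dropped + nrow(d) - NROW(res)
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- cbind(gridded[0, , drop = FALSE], burst = integer(0))
  }
  rownames(out) <- NULL
  attr(out, "report") <- list(n_bursts_kept = kept,
                              n_bursts_dropped = dropped,
                              n_rows_dropped = rows_dropped)
  out
}

#' Fill gaps in an hourly weather series
#'
#' Linearly interpolates interior missing values in time; leading and
#' trailing missing values are filled with the nearest observed value
#' (linear interpolation is undefined there).
#'
#' @param weather Data frame with `timestamp` and numeric series columns
#'   (e.g. `temp_c`, `wind_speed`).
#' @return `weather` with all series gap-free.
#' @export
interpolate_weather <- function(weather) {
  t <- as.numeric(weather$timestamp)
  for (nm in setdiff(names(weather), "timestamp")) {
    y <- weather[[nm]]
    if (!is.numeric(y)) next
    if (all(is.na(y))) stop("series '", nm, "' is entirely missing")
    if (sum(!is.na(y)) == 1) {
      weather[[nm]] <- rep(y[!is.na(y)], length(y))
      next
    }
    if (anyNA(y))
      weather[[nm]] <- approx(t[!is.na(y)], y[!is.na(y)], xout = t,
                              rule = 2)$y
  }
  weather
}

#' Scaled mass index body condition
#'
#' Computes the scaled mass index `SMI_i = M_i * (L0 / L_i)^b_SMA`, where
#' `L0` is the arithmetic mean length of the population, and `b_SMA` is the
#' standardized major axis slope of `ln M` on `ln L`: the OLS slope divided
#' by the Pearson correlation of the log variables.
#'
#' @param population Data frame with columns `mass_kg` and `length_cm`
#'   (at least 3 rows) defining the scaling relationship.
#' @param individual Data frame of records to score (defaults to the
#'   population itself).
#' @return Numeric vector of SMI values (kg) with attributes `b_sma` and
#'   `L0`.
#' @export
scaled_mass_index <- function(population, individual = population) {
  stopifnot(nrow(population) >= 3,
            all(population$mass_kg > 0), all(population$length_cm > 0))
  lL <- log(population$length_cm)
  lM <- log(population$mass_kg)
  if (var(lL) == 0) stop("zero variance in length; SMA slope undefined")
  b_ols <- cov(lL, lM) / var(lL)
  r <- cor(lL, lM)
  if (!is.finite(r) || r == 0) stop("length and mass are uncorrelated; SMA slope undefined")
  b_sma <- b_ols / r
  L0 <- mean(population$length_cm)
  smi <- individual$mass_kg * (L0 / individual$length_cm)^b_sma
  attr(smi, "b_sma") <- b_sma
  attr(smi, "L0") <- L0
  smi
}

#' Attach aligned, standardized covariates to step rows
#'
#' Joins hourly weather by timestamp, derives age (whole days since the
#' individual's first grid instant, i.e. first capture), body condition
#' (most recent scaled mass index), sex/year/colony indicators (reference
#' categories female, earliest season, and `reference_colony`), and the raw
#' hour of day for trigonometric expansion. Metric covariates (age,
#' condition, temperature, wind) are standardized with pooled
#' all-individuals mean and standard deviation; the constants are attached
#' (and can be supplied for reuse, e.g. when scoring new data).
#'
#' @param steps Step table: `id`, `burst`, `timestamp`, `step_m`.
#' @param weather Gap-free hourly weather (see [interpolate_weather()])
#'   with `temp_c` and `wind_speed`.
#' @param metadata Data frame `id`, `sex` (`"F"`/`"M"`), `colony`, `year`.
#' @param biometrics Data frame `id`, `date`, `mass_kg`, `length_cm`.
#' @param reference_colony Colony coded 0 (default `"FWB"`).
#' @param reference_year Season coded 0 (default the earliest).
#' @param scaling Optional standardization constants (data frame `var`,
#'   `mean`, `sd`) to reuse instead of recomputing.
#' @return `steps` with columns `hour`, `sex`, `year`, `colony`, `age_z`,
#'   `cond_z`, `temp_z`, `wind_z` added; attribute `scaling` holds the
#'   constants.
#' @export
build_covariates <- function(steps, weather, metadata, biometrics,
                             reference_colony = "FWB",
                             reference_year = NULL, scaling = NULL) {
  missing_ids <- setdiff(unique(steps$id), metadata$id)
  if (length(missing_ids))
    stop("individual(s) missing from metadata: ",
         paste(missing_ids, collapse = ", "))
  wi <- match(as.numeric(steps$timestamp), as.numeric(weather$timestamp))
  if (anyNA(wi))
    stop("weather series does not cover all step timestamps")
  if (anyNA(weather$temp_c) || anyNA(weather$wind_speed))
    stop("weather has missing values; run interpolate_weather() first")
  temp <- weather$temp_c[wi]
  wind <- weather$wind_speed[wi]

  ts <- as.numeric(steps$timestamp)
  steps$hour <- (ts %% 86400) / 3600
  first <- tapply(ts, steps$id, min)
  age <- floor((ts - first[match(steps$id, names(first))]) / 86400)

  smi <- scaled_mass_index(biometrics)
  cond <- rep(NA_real_, nrow(steps))
  day <- as.Date(steps$timestamp, tz = "UTC")
  for (i in unique(steps$id)) {
    bi <- which(biometrics$id == i)
    if (!length(bi))
      stop("individual missing from biometrics: ", i)
    bd <- as.Date(biometrics$date[bi])
    o <- order(bd)
    bi <- bi[o]; bd <- bd[o]
    rows <- which(steps$id == i)
    k <- findInterval(as.numeric(day[rows]), as.numeric(bd))
    k[k == 0] <- 1  # steps before the first record use the first record
    cond[rows] <- smi[bi][k]
  }

  mi <- match(steps$id, metadata$id)
  sex <- as.numeric(metadata$sex[mi] != "F")
  yr <- as.character(metadata$year[mi])
  if (is.null(reference_year)) reference_year <- min(as.character(metadata$year))
  year <- as.numeric(yr != as.character(reference_year))
  colony <- as.numeric(metadata$colony[mi] != reference_colony)

  metric <- list(age = age, cond = cond, temp = temp, wind = wind)
  if (is.null(scaling)) {
    scaling <- data.frame(var = names(metric),
                          mean = vapply(metric, mean, 0),
                          sd = vapply(metric, sd, 0))
    rownames(scaling) <- NULL
  }
  z <- lapply(names(metric), function(nm) {
    s <- scaling[scaling$var == nm, ]
    (metric[[nm]] - s$mean) / s$sd
  })
  steps$sex <- sex
  steps$year <- year
  steps$colony <- colony
  steps$age_z <- z[[1]]
  steps$cond_z <- z[[2]]
  steps$temp_z <- z[[3]]
  steps$wind_z <- z[[4]]
  attr(steps, "scaling") <- scaling
  steps
}

#' Hourly travel and natal-colony displacement summaries
#'
#' Mean non-missing step length per individual and pooled over all steps,
#' and haversine distance of every observed fix from the individual's
#' natal-colony reference point, averaged per individual and per colony.
#'
#' @param track Regularized track with `id`, `lat`, `lon`, `step_m`.
#' @param metadata Data frame `id`, `colony`.
#' @param reference_points Named list of `c(lat, lon)` per colony.
#' @return List with `per_pup` (id, colony, mean_step_m,
#'   mean_displacement_m), `overall_mean_step_m` (pooled over steps), and
#'   `per_colony` (colony means of the per-pup displacement and step
#'   means).
#' @export
displacement_summaries <- function(track, metadata, reference_points) {
  col <- metadata$colony[match(track$id, metadata$id)]
  unknown <- setdiff(unique(as.character(col)), names(reference_points))
  if (length(unknown))
    stop("no reference point for colony: ", paste(unknown, collapse = ", "))
  pres <- !is.na(track$lat)
  disp <- rep(NA_real_, nrow(track))
  for (cl in names(reference_points)) {
    i <- which(pres & col == cl)
    if (!length(i)) next
    ref <- reference_points[[cl]]
    disp[i] <- geosphere::distHaversine(
      cbind(track$lon[i], track$lat[i]),
      cbind(ref[["lon"]], ref[["lat"]]), r = 6371000)
  }
  ids <- unique(track$id)
  per <- do.call(rbind, lapply(ids, function(i) {
    ri <- track$id == i
    data.frame(id = i,
               colony = as.character(col[ri][1]),
               mean_step_m = mean(track$step_m[ri], na.rm = TRUE),
               mean_displacement_m = mean(disp[ri], na.rm = TRUE))
  }))
  per_colony <- do.call(rbind, lapply(split(per, per$colony), function(d)
    data.frame(colony = d$colony[1], n = nrow(d),
               mean_step_m = mean(d$mean_step_m),
               mean_displacement_m = mean(d$mean_displacement_m))))
  rownames(per_colony) <- NULL
  list(per_pup = per,
       overall_mean_step_m = mean(track$step_m, na.rm = TRUE),
       per_colony = per_colony)
}

#' Full preprocessing pipeline: raw fixes to analysis-ready bursts
#'
#' Runs, in order: [regularize()], [compute_steps()], [censor_steps()],
#' [split_and_filter_bursts()], and [build_covariates()], and assembles a
#' reconciliation report accounting for every raw sampling interval.
#'
#' @param fixes,weather,metadata,biometrics Input tables (see the
#'   individual steps).
#' @param interval Sampling interval, minutes.
#' @param threshold Speed censoring threshold, m/h.
#' @param max_gap Burst-splitting gap, hours.
#' @param min_span Minimum burst span, hours.
#' @param reference_colony,reference_year Reference categories for the
#'   covariate coding.
#' @return List with `bursts` (one row per step with covariates), `fixes`
#'   (regularized grid with censored steps), `burst_fixes` (grid rows of
#'   kept bursts), `scaling` (standardization constants), and `report`
#'   (counts; `report$balanced` confirms that kept step rows plus dropped
#'   intervals exactly account for all grid intervals).
#' @export
preprocess_tracks <- function(fixes, weather, metadata, biometrics,
                              interval = 60, threshold = 400, max_gap = 4,
                              min_span = 48, reference_colony = "FWB",
                              reference_year = NULL) {
  reg <- regularize(fixes, interval)
  reg <- compute_steps(reg)
  cs <- censor_steps(reg$step_m, threshold, interval)
  reg$step_m <- cs$step
  bf <- split_and_filter_bursts(reg, max_gap = max_gap, min_span = min_span)
  srep <- attr(bf, "report")

  # one row per step interval: every burst row except its last
  key <- paste(bf$id, bf$burst, sep = "\r")
  last <- !duplicated(key, fromLast = TRUE)
  steps <- bf[!last, c("id", "burst", "timestamp", "step_m")]
  rownames(steps) <- NULL

  wt <- interpolate_weather(weather)
  bursts <- build_covariates(steps, wt, metadata, biometrics,
                             reference_colony = reference_colony,
                             reference_year = reference_year)

  # reconciliation: classify every grid interval independently
  n <- nrow(reg)
  same_id <- reg$id[-n] == reg$id[-1]
  n_intervals <- sum(same_id)
  burst_of <- rep(NA_integer_, n)
  idx <- match(paste(reg$id, as.numeric(reg$timestamp)),
               paste(bf$id, as.numeric(bf$timestamp)))
  burst_of[!is.na(idx)] <- bf$burst[idx[!is.na(idx)]]
  kept_int <- same_id & !is.na(burst_of[-n]) & !is.na(burst_of[-1]) &
    burst_of[-n] == burst_of[-1] &
    reg$id[-n] == reg$id[-1]
  report <- list(
    n_raw_fixes = nrow(fixes),
    n_duplicates_dropped = attr(reg, "n_duplicates") %||% 0L,
    n_grid_rows = n,
    n_missing_fixes = sum(is.na(reg$lat)),
    n_intervals = n_intervals,
    n_censored = cs$n_censored,
    n_bursts_kept = srep$n_bursts_kept,
    n_bursts_dropped = srep$n_bursts_dropped,
    n_step_rows = nrow(steps),
    n_intervals_dropped = n_intervals - sum(kept_int),
    balanced = nrow(steps) == sum(kept_int) &&
      nrow(steps) + (n_intervals - sum(kept_int)) == n_intervals)
  list(bursts = bursts, fixes = reg, burst_fixes = bf,
       scaling = attr(bursts, "scaling"), report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
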