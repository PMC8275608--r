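#' Configuration for the synthetic pup-track generator
#'
#' Bundles every knob of the synthetic "central place explorer"
#' generator with defaults emulating the study system: two breeding
#' colonies of contrasting density (FWB, the reference, and SSB) sampled
#' over two seasons, hourly fixes, deployment durations of 20-80 days,
#' gamma step-length states with means 22.5 m (inactive) and 75.8 m
#' (active), diurnal/age/season effects on the transition logits that
#' differ by colony, star-shaped excursions around a per-pup home patch,
#' missing fixes, implausible-speed outliers, staggered births, early
#' mortality, and alternating maternal attendance bouts.
#'
#' The transition intercepts correspond to mean bout durations of about
#' 8 h (inactive) and 4.3 h (active), which give a long-run activity
#' budget of roughly 35% active / 65% inactive.
#'
#' @param counts Data frame `colony`, `year`, `n`: pups per colony and
#'   season.
#' @param colony_labels Two colony labels, reference first.
#' @param season_labels Two season labels, reference first.
#' @param sampling_interval Minutes between fixes (must divide 24 h).
#' @param duration_range Deployment duration range in days (uniform draw).
#' @param home_patch Named list of colony reference coordinates
#'   `c(lat, lon)`.
#' @param home_jitter_sigma Rayleigh scale (m) of each pup's home-patch
#'   offset from its colony reference, per colony.
#' @param emission List `mu`, `sigma`: per-state gamma mean/sd in metres
#'   (state 1 mean < state 2 mean).
#' @param covariates,interact,harmonics Transition model structure (see
#'   [hmm_spec()]) used as ground truth.
#' @param beta 2 x p ground-truth transition coefficients matching the
#'   spec's design; `NULL` uses the built-in defaults.
#' @param attendance_effect Length-2 additive shift of the (1->2, 2->1)
#'   logits when the mother is absent at sea.
#' @param mortality_effect Length-2 additive logit shift for pups fated to
#'   die (a behavioural frailty: doomed pups are less active).
#' @param missing_rate Probability a fix is absent (independent signal
#'   lapses).
#' @param gap_rate Probability per fix that a multi-hour signal outage
#'   starts (these create the observation gaps that split tracks into
#'   bursts).
#' @param gap_hours Integer range of outage durations, hours.
#' @param outlier_rate Probability a fix is displaced so the implied step
#'   exceeds the 400 m/h screen.
#' @param mortality_rate Probability a pup dies before the end of tracking.
#' @param mortality_day Lognormal parameters (`meanlog`, `sdlog`) and
#'   clipping range (`min`, `max`) of the death day.
#' @param attendance List `perinatal_days`, `ashore_mean`, `atsea_mean`
#'   (days) for the alternating maternal attendance bouts.
#' @param temperature,wind AR(1) weather-series parameters (per-season
#'   mean/sd for temperature, plus diurnal amplitude).
#' @param weather_missing_rate Probability a weather record is missing.
#' @param growth Biometric growth parameters (mass/length at first capture
#'   and daily gains; records every `biometric_interval` days).
#' @param heading List `persistence_sd` (rad) and `attraction_scale` (m)
#'   of the active-state heading dynamics.
#' @param seed Integer master seed.
#' @return Validated object of class `sim_config`.
#' @export
sim_config <- function(
    counts = data.frame(colony = c("FWB", "SSB", "FWB", "SSB"),
                        year = c("2019", "2019", "2020", "2020"),
                        n = c(19L, 21L, 13L, 13L)),
    colony_labels = c("FWB", "SSB"),
    season_labels = c("2019", "2020"),
    sampling_interval = 60,
    duration_range = c(20L, 80L),
    home_patch = list(FWB = c(lat = -54.0105, lon = -38.0560),
                      SSB = c(lat = -54.0125, lon = -38.0490)),
    home_jitter_sigma = c(FWB = 40, SSB = 140),
    emission = list(mu = c(22.5, 75.8), sigma = c(22.5, 75.8)),
    covariates = c("age_z", "hour", "year"),
    interact = c("age_z", "hour", "year"),
    harmonics = 1L,
    beta = NULL,
    attendance_effect = c(0.12, -0.08),
    mortality_effect = c(-0.55, 0.25),
    missing_rate = 0.02,
    gap_rate = 0.002,
    gap_hours = c(2L, 12L),
    outlier_rate = 0.002,
    mortality_rate = 13 / 66,
    mortality_day = list(meanlog = log(15), sdlog = 0.6, min = 4, max = 41),
    attendance = list(perinatal_days = 7, ashore_mean = 2, atsea_mean = 5),
    temperature = list(mean = c("2019" = 3.7, "2020" = 3.9),
                       sd = c("2019" = 1.3, "2020" = 1.4),
                       phi = 0.98, diurnal_amp = 0.7, noise_sd = 0.3),
    wind = list(mean = 7, sd = 3, phi = 0.95),
    weather_missing_rate = 0.002,
    growth = list(mass0_mean = 5.6, mass0_sd = 0.9, mass_gain = 0.09,
                  length0_mean = 63, length0_sd = 3, length_gain = 0.3,
                  biometric_interval = 10),
    heading = list(persistence_sd = 0.4, attraction_scale = 150),
    seed = 1L) {
  spec <- hmm_spec(covariates, interact, harmonics)
  if (is.null(beta)) beta <- .default_beta(spec)
  cols <- .spec_colnames(spec)
  beta <- rbind(beta)
  if (ncol(beta) != length(cols))
    stop("beta has ", ncol(beta), " columns but the spec design has ",
         length(cols), " (", paste(cols, collapse = ", "), ")")
  colnames(beta) <- cols
  rownames(beta) <- c("1->2", "2->1")
  stopifnot(
    all(emission$mu > 0), all(emission$sigma > 0),
    emission$mu[2] > emission$mu[1],
    missing_rate >= 0, missing_rate <= 1,
    outlier_rate >= 0, outlier_rate <= 1,
    mortality_rate >= 0, mortality_rate <= 1,
    (24 * 60) %% sampling_interval == 0,
    length(colony_labels) == 2, length(season_labels) == 2,
    all(counts$colony %in% colony_labels),
    all(as.character(counts$year) %in% season_labels),
    all(is.finite(beta)))
  structure(list(counts = counts, colony_labels = colony_labels,
                 season_labels = season_labels,
                 sampling_interval = sampling_interval,
                 duration_range = duration_range, home_patch = home_patch,
                 home_jitter_sigma = home_jitter_sigma,
                 emission = emission, spec = spec, beta = beta,
                 attendance_effect = attendance_effect,
                 mortality_effect = mortality_effect,
                 missing_rate = missing_rate, gap_rate = gap_rate,
                 gap_hours = gap_hours, outlier_rate = outlier_rate,
                 mortality_rate = mortality_rate,
                 mortality_day = mortality_day, attendance = attendance,
                 temperature = temperature, wind = wind,
                 weather_missing_rate = weather_missing_rate,
                 growth = growth, heading = heading,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# ground-truth coefficients on the standardized design: diurnal activity
# peak at midday, an age effect confined to the reference colony, and a
# season effect strongest at the reference colony
.default_beta <- function(spec) {
  cols <- .spec_colnames(spec)
  b <- matrix(0, 2, length(cols), dimnames = list(c("1->2", "2->1"), cols))
  set <- function(row, nm, val) if (nm %in% cols) b[row, nm] <<- val
  b[1, "(Intercept)"] <- qlogis(1 / 8)      # mean inactive bout ~8 h
  b[2, "(Intercept)"] <- qlogis(1 / 4.3)    # mean active bout ~4.3 h
  set(1, "age_z", 0.25);          set(2, "age_z", -0.10)
  set(1, "sin1", -0.20);          set(2, "sin1", 0.15)
  set(1, "cos1", -0.45);          set(2, "cos1", 0.40)
  set(1, "year", -0.30);          set(2, "year", 0.15)
  set(1, "colony", 0.10)
  set(1, "age_z:colony", -0.25);  set(2, "age_z:colony", 0.10)
  set(1, "cos1:colony", 0.10);    set(2, "cos1:colony", -0.10)
  set(1, "year:colony", 0.20);    set(2, "year:colony", -0.10)
  b
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic pup-track generator configuration\n")
  cat("  pups:", sum(x$counts$n), "(",
      paste(sprintf("%s/%s: %d", x$counts$colony, x$counts$year,
                    x$counts$n), collapse = ", "), ")\n")
  cat("  interval:", x$sampling_interval, "min; durations",
      x$duration_range[1], "-", x$duration_range[2], "days\n")
  cat("  emission means:", paste(x$emission$mu, collapse = " / "), "m\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

.season_start <- function(year) as.Date(paste0(as.integer(year) - 1, "-12-01"))

# deterministic per-season weather stream over the whole season window
.weather_series <- function(config, year) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed((config$seed * 1009 + match(year, config$season_labels) * 7919) %%
             .Machine$integer.max)
  from <- .season_start(year)
  to <- as.Date(paste0(year, "-03-31"))
  ts <- seq(as.POSIXct(paste(from, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(to, "23:00:00"), tz = "UTC"), by = 3600)
  n <- length(ts)
  h <- (as.numeric(ts) %% 86400) / 3600
  tp <- config$temperature
  m <- tp$mean[[year]]; s <- tp$sd[[year]]
  ar_var <- max(s^2 - tp$diurnal_amp^2 / 2 - tp$noise_sd^2, 0.1)
  ar <- as.numeric(stats::arima.sim(list(ar = tp$phi), n,
                                    sd = sqrt(ar_var * (1 - tp$phi^2))))
  temp <- m + ar - tp$diurnal_amp * cos(2 * pi * h / 24) +
    rnorm(n, 0, tp$noise_sd)
  wp <- config$wind
  arw <- as.numeric(stats::arima.sim(list(ar = wp$phi), n,
                                     sd = wp$sd * sqrt(1 - wp$phi^2)))
  wind <- pmax(wp$mean + arw, 0)
  data.frame(timestamp = ts, temp_c = temp, wind_speed = wind)
}

.sim_roster <- function(config) {
  counts <- config$counts
  rows <- NULL
  k <- 0L
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(counts$n[i])) {
      k <- k + 1L
      rows <- rbind(rows, data.frame(
        id = sprintf("P%03d", k), colony = counts$colony[i],
        year = as.character(counts$year[i]), stringsAsFactors = FALSE))
    }
  }
  n <- nrow(rows)
  rows$sex <- sample(c("F", "M"), n, replace = TRUE)
  birth_offset <- sample(0:15, n, replace = TRUE)
  rows$birth_date <- .season_start(rows$year) + 4 + birth_offset
  rows$capture_date <- rows$birth_date + sample(2:3, n, replace = TRUE)
  dur <- seq(config$duration_range[1], config$duration_range[2])
  rows$duration <- dur[sample.int(length(dur), n, replace = TRUE)]
  died <- runif(n) < config$mortality_rate
  md <- config$mortality_day
  dday <- pmin(pmax(round(rlnorm(n, md$meanlog, md$sdlog)), md$min), md$max)
  rows$fate <- ifelse(died, "died", "survived")
  rows$death_day <- ifelse(died, dday, NA)
  rows$track_days <- ifelse(died, pmin(rows$duration, dday), rows$duration)
  rows$death_date <- rows$capture_date + rows$death_day
  rows
}

.sim_biometrics <- function(config, pup) {
  g <- config$growth
  days <- seq(0, pup$track_days, by = g$biometric_interval)
  l0 <- rnorm(1, g$length0_mean, g$length0_sd)
  m0 <- rnorm(1, g$mass0_mean, g$mass0_sd)
  data.frame(id = pup$id, date = pup$capture_date + days,
             mass_kg = pmax(m0 + g$mass_gain * days + rnorm(length(days), 0, 0.15), 1),
             length_cm = pmax(l0 + g$length_gain * days +
                                cumsum(abs(rnorm(length(days), 0, 0.2))), 30))
}

.sim_attendance <- function(config, pup) {
  at <- config$attendance
  pres <- rep(1L, min(at$perinatal_days, pup$track_days + 1))
  while (length(pres) <= pup$track_days) {
    absent <- rgeom(1, 1 / at$atsea_mean) + 1
    ashore <- rgeom(1, 1 / at$ashore_mean) + 1
    pres <- c(pres, rep(0L, absent), rep(1L, ashore))
  }
  data.frame(id = pup$id, date = pup$capture_date + 0:pup$track_days,
             mother_present = pres[1:(pup$track_days + 1)])
}

#' Per-pup covariate series on the sampling grid
#'
#' Builds the hourly (or finer) covariate grid covering one pup's tracked
#' life span: raw hour of day, age in whole days since first capture,
#' temperature and wind sliced from the shared per-season weather stream,
#' body condition (piecewise constant between 10-day biometric records),
#' and the pup's sex/colony/season labels.
#'
#' @param config A [sim_config()].
#' @param pup One roster row (as produced inside [simulate_pups()]) or a
#'   pup index into the deterministic roster implied by `config`.
#' @param weather Optional pre-generated season weather (gap-free); by
#'   default the deterministic per-season stream is used.
#' @param condition Optional vector of per-record condition values aligned
#'   to `biometrics` rows; by default the record's mass is used.
#' @param biometrics Optional pre-generated biometric records for the pup.
#' @return Data frame with one row per sampling interval (step): columns
#'   `id`, `timestamp`, `hour`, `age`, `temp`, `wind`, `condition`, `sex`,
#'   `colony`, `year`.
#' @export
simulate_covariates <- function(config, pup, weather = NULL,
                                condition = NULL, biometrics = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.numeric(pup)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(config$seed)
    roster <- .sim_roster(config)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    stopifnot(pup >= 1, pup <= nrow(roster))
    pup <- roster[pup, ]
  }
  if (is.null(weather)) weather <- .weather_series(config, pup$year)
  if (is.null(biometrics)) biometrics <- .sim_biometrics(config, pup)
  if (is.null(condition)) condition <- biometrics$mass_kg
  step_sec <- config$sampling_interval * 60
  n <- pup$track_days * 86400 / step_sec
  start <- as.POSIXct(paste(pup$capture_date, "00:00:00"), tz = "UTC")
  ts <- start + (seq_len(n) - 1) * step_sec
  wi <- match(trunc(as.numeric(ts) / 3600) * 3600,
              as.numeric(weather$timestamp))
  if (anyNA(wi)) stop("weather stream does not cover the pup's life span")
  day <- as.numeric(as.Date(ts, tz = "UTC"))
  k <- findInterval(day, as.numeric(as.Date(biometrics$date)))
  k[k == 0] <- 1
  data.frame(id = pup$id, timestamp = ts,
             hour = (as.numeric(ts) %% 86400) / 3600,
             age = floor(as.numeric(ts - start, units = "days")),
             temp = weather$temp_c[wi], wind = weather$wind_speed[wi],
             condition = condition[k],
             sex = pup$sex, colony = pup$colony, year = pup$year,
             stringsAsFactors = FALSE)
}

#' Simulate a behavioural state sequence from transition coefficients
#'
#' Runs the covariate-dependent two-state Markov chain generatively: the
#' transition matrix at each step is the logistic function of the design
#' row (see [transition_matrix()]), and each burst's initial state is drawn
#' from the stationary distribution at its first row.
#'
#' @param beta 2 x p transition coefficient matrix.
#' @param design n x p design matrix (see [hmm_design()]).
#' @param bkey Optional integer burst key (new burst where the value
#'   changes); a single burst by default.
#' @param seed Optional seed.
#' @return Integer vector of states (1 = inactive, 2 = active).
#' @export
simulate_state_sequence <- function(beta, design, bkey = NULL, seed = NULL) {
  beta <- rbind(beta)
  if (ncol(beta) != ncol(design))
    stop("beta columns (", ncol(beta), ") do not match design columns (",
         ncol(design), ")")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bkey)) bkey <- rep(1L, nrow(design))
  tp <- .trans_probs(beta, design)
  .sim_states(tp$g12, tp$g21, bkey)
}

#' Simulate GPS positions for a given state sequence
#'
#' Draws step lengths from the per-state gamma distributions and headings
#' following the central-place-explorer mechanics: inactive headings are
#' isotropic; active headings persist (previous heading plus small wrapped
#' noise) with a home-attraction component proportional to the distance
#' from the home patch, so excursions return. Displacements in metres are
#' mapped to coordinates by local-scale equirectangular inversion.
#'
#' @param states Integer state sequence (1/2).
#' @param emission List `mu`, `sigma` (per-state gamma mean/sd, metres).
#' @param home `c(lat, lon)` of the pup's home patch.
#' @param heading List `persistence_sd` (rad), `attraction_scale` (m).
#' @param seed Optional seed.
#' @return Data frame `lat`, `lon` with `length(states) + 1` fixes (the
#'   first at the home patch); the drawn step lengths are attached as
#'   attribute `step_m`.
#' @export
simulate_positions <- function(states, emission, home,
                               heading = list(persistence_sd = 0.4,
                                              attraction_scale = 400),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(states)
  L <- rgamma_meansd(n, emission$mu[states], emission$sigma[states])
  x <- y <- numeric(n + 1)
  h <- runif(1, 0, 2 * pi)
  for (t in seq_len(n)) {
    if (states[t] == 1L) {
      dir <- runif(1, 0, 2 * pi)
    } else {
      d <- sqrt(x[t]^2 + y[t]^2)
      w <- min(d / heading$attraction_scale, 2)
      bh <- atan2(-y[t], -x[t])
      dir <- atan2(sin(h) + w * sin(bh), cos(h) + w * cos(bh)) +
        rnorm(1, 0, heading$persistence_sd)
    }
    x[t + 1] <- x[t] + L[t] * cos(dir)
    y[t + 1] <- y[t] + L[t] * sin(dir)
    h <- dir
  }
  R <- 6371000
  lat <- home[["lat"]] + (y / R) * 180 / pi
  lon <- home[["lon"]] + (x / (R * cos(home[["lat"]] * pi / 180))) * 180 / pi
  out <- data.frame(lat = lat, lon = lon)
  attr(out, "step_m") <- L
  out
}

#' Degrade a clean track with missing fixes and speed outliers
#'
#' Deletes fixes independently with probability `missing_rate` and
#' displaces a fraction `outlier_rate` of the surviving fixes far enough
#' (1.2-2.5 km, random bearing) that every implied step exceeds the
#' 400 m/h screen; displaced fixes are kept at least two grid instants
#' apart so their implied steps cannot cancel.
#'
#' @param fixes Data frame `id`, `timestamp`, `lat`, `lon`.
#' @param missing_rate,outlier_rate Degradation probabilities in `[0, 1]`.
#' @param gap_rate,gap_hours Optional clustered outages: with probability
#'   `gap_rate` per fix a run of `gap_hours[1]` to `gap_hours[2]`
#'   consecutive fixes is deleted (default off).
#' @param seed Optional seed.
#' @return List with `fixes` (degraded), `missing` (deleted rows' id and
#'   timestamp) and `outliers` (displaced rows' id and timestamp).
#' @export
inject_missing_and_outliers <- function(fixes, missing_rate, outlier_rate,
                                        gap_rate = 0, gap_hours = c(2L, 12L),
                                        seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1, gap_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  drop <- runif(nrow(fixes)) < missing_rate
  if (gap_rate > 0) {
    starts <- which(runif(nrow(fixes)) < gap_rate)
    for (s in starts) {
      len <- sample(seq(gap_hours[1], gap_hours[2]), 1)
      run <- s:min(s + len - 1, nrow(fixes))
      drop[run[fixes$id[run] == fixes$id[s]]] <- TRUE
    }
  }
  missing <- fixes[drop, c("id", "timestamp")]
  fx <- fixes[!drop, , drop = FALSE]
  cand <- which(runif(nrow(fx)) < outlier_rate)
  # enforce spacing >= 2 rows within id
  keep <- cand[c(TRUE, diff(cand) > 2)[seq_along(cand)]]
  out_rows <- fx[keep, c("id", "timestamp")]
  if (length(keep)) {
    d <- runif(length(keep), 1200, 2500)
    brg <- runif(length(keep), 0, 2 * pi)
    R <- 6371000
    fx$lat[keep] <- fx$lat[keep] + (d * sin(brg) / R) * 180 / pi
    fx$lon[keep] <- fx$lon[keep] +
      (d * cos(brg) / (R * cos(fx$lat[keep] * pi / 180))) * 180 / pi
  }
  rownames(fx) <- NULL
  list(fixes = fx, missing = missing, outliers = out_rows)
}

# pooled standardization of the generator's metric covariates; returns the
# augmented table and the constants
.standardize_covariates <- function(cov) {
  metric <- c(age = "age", cond = "condition", temp = "temp", wind = "wind")
  scaling <- data.frame(var = names(metric),
                        mean = vapply(metric, function(v) mean(cov[[v]]), 0),
                        sd = vapply(metric, function(v) sd(cov[[v]]), 0))
  rownames(scaling) <- NULL
  cov$age_z <- (cov$age - scaling$mean[1]) / scaling$sd[1]
  cov$cond_z <- (cov$condition - scaling$mean[2]) / scaling$sd[2]
  cov$temp_z <- (cov$temp - scaling$mean[3]) / scaling$sd[3]
  cov$wind_z <- (cov$wind - scaling$mean[4]) / scaling$sd[4]
  attr(cov, "scaling") <- scaling
  cov
}

#' Simulate a complete multi-pup tracking study
#'
#' Generates the full synthetic dataset with known ground truth: a pup
#' roster (colonies, seasons, sexes, staggered births, deployment
#' durations, early mortality), shared per-season weather, 10-day
#' biometrics with scaled-mass-index condition, daily maternal attendance,
#' covariate-dependent behavioural state sequences, gamma step lengths,
#' star-shaped GPS tracks around per-pup home patches, and degradation by
#' missing fixes and speed outliers. Mortality truncates each track before
#' anything is written.
#'
#' Sex/colony/year indicators use the reference coding of
#' [build_covariates()] and metric covariates are standardized with pooled
#' constants before the ground-truth coefficients are applied, so the
#' generating `beta` lives on the same scale that a refit on the
#' preprocessed data estimates.
#'
#' @param config A [sim_config()].
#' @return List with the degraded observation tables (`fixes`, `weather`,
#'   `metadata`, `biometrics`, `attendance`), the clean `fixes_clean` and
#'   `weather_clean`, and `truth` (generating parameters, per-step state
#'   and step-length table, per-pup home patches, degradation records, and
#'   the standardization constants).
#' @export
simulate_pups <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  weather <- lapply(setNames(config$season_labels, config$season_labels),
                    function(y) .weather_series(config, y))
  set.seed(config$seed)
  roster <- .sim_roster(config)
  n <- nrow(roster)

  biometrics <- do.call(rbind, lapply(seq_len(n), function(i)
    .sim_biometrics(config, roster[i, ])))
  smi <- scaled_mass_index(biometrics)
  attendance <- do.call(rbind, lapply(seq_len(n), function(i)
    .sim_attendance(config, roster[i, ])))

  cov <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- roster[i, ]
    simulate_covariates(config, p, weather = weather[[p$year]],
                        condition = smi[biometrics$id == p$id],
                        biometrics = biometrics[biometrics$id == p$id, ])
  }))
  cov$sex <- as.numeric(cov$sex != "F")
  cov$year <- as.numeric(cov$year != config$season_labels[1])
  cov$colony <- as.numeric(cov$colony != config$colony_labels[1])
  cov <- .standardize_covariates(cov)

  # ground-truth transitions, with attendance and mortality-frailty shifts
  X <- hmm_design(config$spec, cov)
  att_day <- paste(attendance$id, attendance$date)
  ai <- match(paste(cov$id, as.Date(cov$timestamp, tz = "UTC")), att_day)
  absent <- 1 - attendance$mother_present[ai]
  absent[is.na(absent)] <- 0
  doomed <- as.numeric(roster$fate[match(cov$id, roster$id)] == "died")
  eta12 <- drop(X %*% config$beta[1, ]) +
    config$attendance_effect[1] * absent + config$mortality_effect[1] * doomed
  eta21 <- drop(X %*% config$beta[2, ]) +
    config$attendance_effect[2] * absent + config$mortality_effect[2] * doomed
  bkey <- cumsum(c(TRUE, cov$id[-1] != cov$id[-nrow(cov)]))
  states <- .sim_states(plogis(eta12), plogis(eta21), bkey)

  # geometry per pup
  fixes <- NULL
  steps_true <- numeric(nrow(cov))
  homes <- NULL
  for (i in seq_len(n)) {
    p <- roster[i, ]
    rows <- which(cov$id == p$id)
    ref <- config$home_patch[[p$colony]]
    rad <- config$home_jitter_sigma[[p$colony]] * sqrt(-2 * log(runif(1)))
    brg <- runif(1, 0, 2 * pi)
    R <- 6371000
    home <- c(lat = ref[["lat"]] + (rad * sin(brg) / R) * 180 / pi,
              lon = ref[["lon"]] + (rad * cos(brg) /
                                      (R * cos(ref[["lat"]] * pi / 180))) * 180 / pi)
    homes <- rbind(homes, data.frame(id = p$id, lat = home[["lat"]],
                                     lon = home[["lon"]]))
    pos <- simulate_positions(states[rows], config$emission, home,
                              heading = config$heading)
    steps_true[rows] <- attr(pos, "step_m")
    ts <- c(cov$timestamp[rows],
            cov$timestamp[rows[length(rows)]] + config$sampling_interval * 60)
    fixes <- rbind(fixes, data.frame(id = p$id, timestamp = ts,
                                     lat = pos$lat, lon = pos$lon))
  }

  deg <- inject_missing_and_outliers(fixes, config$missing_rate,
                                     config$outlier_rate,
                                     gap_rate = config$gap_rate,
                                     gap_hours = config$gap_hours)
  weather_out <- do.call(rbind, weather)
  rownames(weather_out) <- NULL
  if (config$weather_missing_rate > 0) {
    interior <- seq(2, nrow(weather_out) - 1)
    miss <- interior[runif(length(interior)) < config$weather_missing_rate]
    weather_out$temp_c[miss] <- NA
    weather_out$wind_speed[miss] <- NA
  }

  metadata <- data.frame(id = roster$id, sex = roster$sex,
                         colony = roster$colony, year = roster$year,
                         birth_date = roster$birth_date,
                         fate = roster$fate,
                         death_date = roster$death_date)
  truth <- list(config = config, roster = roster, beta = config$beta,
                emission = config$emission,
                states = data.frame(id = cov$id, timestamp = cov$timestamp,
                                    state = states, step_m = steps_true),
                homes = homes,
                missing = deg$missing, outliers = deg$outliers,
                scaling = attr(cov, "scaling"))
  list(fixes = deg$fixes, fixes_clean = fixes, weather = weather_out,
       weather_clean = weather, metadata = metadata,
       biometrics = biometrics, attendance = attendance, truth = truth)
}

#' Simulate analysis-ready bursts with known truth (no geometry)
#'
#' A lighter companion to [simulate_pups()] for estimation studies: the
#' covariate grids, state sequences and gamma step lengths are generated
#' exactly as in the full generator, but positions are never formed, no
#' degradation is applied, and the attendance/mortality logit shifts are
#' omitted, so the transition structure is exactly `config$beta` on the
#' standardized design.
#'
#' @param config A [sim_config()].
#' @return List with `bursts` (ready for [fit_hmm()]: `id`, `burst`,
#'   `timestamp`, `step_m` plus covariate columns) and `truth` (`beta`,
#'   `emission`, `states`, `spec`, `scaling`).
#' @export
simulate_bursts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  weather <- lapply(setNames(config$season_labels, config$season_labels),
                    function(y) .weather_series(config, y))
  set.seed(config$seed)
  roster <- .sim_roster(config)
  n <- nrow(roster)
  biometrics <- do.call(rbind, lapply(seq_len(n), function(i)
    .sim_biometrics(config, roster[i, ])))
  smi <- scaled_mass_index(biometrics)
  cov <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- roster[i, ]
    simulate_covariates(config, p, weather = weather[[p$year]],
                        condition = smi[biometrics$id == p$id],
                        biometrics = biometrics[biometrics$id == p$id, ])
  }))
  cov$sex <- as.numeric(cov$sex != "F")
  cov$year <- as.numeric(cov$year != config$season_labels[1])
  cov$colony <- as.numeric(cov$colony != config$colony_labels[1])
  cov <- .standardize_covariates(cov)
  X <- hmm_design(config$spec, cov)
  bkey <- cumsum(c(TRUE, cov$id[-1] != cov$id[-nrow(cov)]))
  tp <- .trans_probs(config$beta, X)
  states <- .sim_states(tp$g12, tp$g21, bkey)
  cov$burst <- 1L
  cov$step_m <- rgamma_meansd(nrow(cov), config$emission$mu[states],
                              config$emission$sigma[states])
  list(bursts = cov,
       truth = list(beta = config$beta, emission = config$emission,
                    states = states, spec = config$spec,
                    scaling = attr(cov, "scaling")))
}
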