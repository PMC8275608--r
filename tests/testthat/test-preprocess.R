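ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

test_that("regularize marks gaps, snaps jittered fixes, handles empty input", {
  f <- data.frame(id = "a",
                  timestamp = ts_utc("2019-01-01 00:00") +
                    c(0, 3600, 3 * 3600),
                  lat = c(-54, -54.001, -54.003), lon = -38)
  g <- regularize(f)
  expect_equal(nrow(g), 4)
  expect_true(is.na(g$lat[3]))  # the absent hour
  # fixes at :02 and :58 snap to the adjacent hours
  f2 <- data.frame(id = "a",
                   timestamp = ts_utc("2019-01-01 00:02") + c(0, 56 * 60),
                   lat = c(-54, -54.01), lon = -38)
  g2 <- regularize(f2)
  expect_equal(format(g2$timestamp, "%H:%M"), c("00:00", "01:00"))
  expect_equal(g2$lat, f2$lat)
  # empty input
  g0 <- regularize(f[0, ])
  expect_equal(nrow(g0), 0)
  # two fixes snapping to one instant: nearer wins, with a warning
  f3 <- data.frame(id = "a",
                   timestamp = ts_utc("2019-01-01 00:10") + c(0, 10 * 60),
                   lat = c(-54.5, -54.6), lon = -38)
  expect_warning(g3 <- regularize(f3), "discarded")
  expect_equal(nrow(g3), 1)
  expect_equal(g3$lat, -54.5)  # the :10 fix is nearer to the 00:00 instant
})

test_that("steps are haversine distances with missing propagation", {
  f <- data.frame(id = "a",
                  timestamp = ts_utc("2019-01-01 00:00") + (0:2) * 3600,
                  lat = c(-54, -54, -54.001), lon = c(-38, -38, -38))
  g <- compute_steps(f)
  expect_equal(g$step_m[1], 0)
  # 0.001 degrees of latitude = R * dphi
  expect_equal(g$step_m[2], 6371000 * 0.001 * pi / 180, tolerance = 1e-6)
  expect_true(is.na(g$step_m[3]))
  # a missing middle fix kills both adjacent steps
  f$lat[2] <- NA
  g2 <- compute_steps(f)
  expect_true(all(is.na(g2$step_m[1:2])))
  # steps never cross individuals
  f2 <- rbind(f, transform(f, id = "b"))
  g3 <- compute_steps(f2)
  expect_true(is.na(g3$step_m[3]))
})

test_that("censoring replaces fast steps and counts them", {
  cs <- censor_steps(c(100, 450, 399))
  expect_equal(cs$step, c(100, NA, 399))
  expect_equal(cs$n_censored, 1)
  cs0 <- censor_steps(c(1, 400, 399.99))
  expect_equal(cs0$n_censored, 0)  # strictly greater than
  # threshold scales with the interval
  cs5 <- censor_steps(c(40, 20), threshold = 400, interval = 5)
  expect_equal(cs5$step, c(NA, 20))
  expect_error(censor_steps(1, threshold = -1))
})

test_that("burst splitting cuts at >4 h gaps and drops short fragments", {
  h <- 3600
  mk <- function(hours) {
    data.frame(id = "a", timestamp = ts_utc("2019-01-01 00:00") + hours * h,
               lat = -54 + hours * 1e-5, lon = -38)
  }
  # 5-day track with a 6-hour hole after hour 49
  hours <- setdiff(0:119, 50:55)
  b <- split_and_filter_bursts(regularize(mk(hours)))
  expect_equal(attr(b, "report")$n_bursts_kept, 2)
  expect_equal(sort(unique(b$burst)), c(1, 2))
  # a 3-hour hole is retained as missing rows inside one burst
  hours2 <- setdiff(0:119, 50:52)
  b2 <- split_and_filter_bursts(regularize(mk(hours2)))
  expect_equal(attr(b2, "report")$n_bursts_kept, 1)
  expect_equal(sum(is.na(b2$lat)), 3)
  # an isolated 40-hour fragment is dropped
  b3 <- split_and_filter_bursts(regularize(mk(0:40)))
  expect_equal(nrow(b3), 0)
  expect_equal(attr(b3, "report")$n_bursts_dropped, 1)
  # a 48-hour span is exactly at the threshold and kept
  b4 <- split_and_filter_bursts(regularize(mk(0:48)))
  expect_equal(attr(b4, "report")$n_bursts_kept, 1)
})

test_that("weather interpolation fills interior and edge gaps", {
  w <- data.frame(timestamp = ts_utc("2019-01-01 00:00") + (0:2) * 3600,
                  temp_c = c(1, NA, 3), wind_speed = c(5, 5, 5))
  wi <- interpolate_weather(w)
  expect_equal(wi$temp_c, c(1, 2, 3))
  expect_equal(wi$wind_speed, c(5, 5, 5))  # identity when complete
  w2 <- data.frame(timestamp = w$timestamp, temp_c = c(NA, 5, NA))
  expect_equal(interpolate_weather(w2)$temp_c, c(5, 5, 5))
  w3 <- data.frame(timestamp = w$timestamp, temp_c = rep(NA_real_, 3))
  expect_error(interpolate_weather(w3), "entirely missing")
})

test_that("scaled mass index matches a step-by-step hand computation", {
  # individual at the reference length: SMI equals its mass
  pop <- data.frame(mass_kg = c(5, 6, 7, 8), length_cm = c(60, 62, 64, 66))
  ind <- data.frame(mass_kg = 6.5, length_cm = mean(pop$length_cm))
  expect_equal(unclass(scaled_mass_index(pop, ind))[1], 6.5)
  # perfectly collinear ln M = 2 ln L + c: r = 1 so SMA = OLS = 2
  pop2 <- data.frame(length_cm = c(50, 60, 70),
                     mass_kg = exp(2 * log(c(50, 60, 70)) - 7))
  expect_equal(attr(scaled_mass_index(pop2), "b_sma"), 2, tolerance = 1e-12)
  # 5-row toy table against explicit arithmetic
  pop5 <- data.frame(mass_kg = c(5.1, 5.9, 6.4, 7.2, 8.3),
                     length_cm = c(61, 63, 64, 67, 70))
  lL <- log(pop5$length_cm); lM <- log(pop5$mass_kg)
  b_ols <- sum((lL - mean(lL)) * (lM - mean(lM))) / sum((lL - mean(lL))^2)
  r <- sum((lL - mean(lL)) * (lM - mean(lM))) /
    sqrt(sum((lL - mean(lL))^2) * sum((lM - mean(lM))^2))
  b_sma <- b_ols / r
  L0 <- mean(pop5$length_cm)
  expected <- pop5$mass_kg * (L0 / pop5$length_cm)^b_sma
  got <- scaled_mass_index(pop5)
  expect_equal(as.numeric(got), expected, tolerance = 1e-12)
  expect_equal(attr(got, "b_sma"), b_sma, tolerance = 1e-12)
  # degenerate inputs
  expect_error(scaled_mass_index(data.frame(mass_kg = 1:3,
                                            length_cm = c(60, 60, 60))),
               "zero variance")
})

test_that("covariates are joined, standardized, and reference-coded", {
  sim <- simulate_pups(sim_config(
    counts = data.frame(colony = c("FWB", "SSB"), year = c("2019", "2020"),
                        n = c(2L, 2L)),
    duration_range = c(10L, 14L), mortality_rate = 0, seed = 5))
  pp <- preprocess_tracks(sim$fixes, sim$weather, sim$metadata,
                          sim$biometrics)
  b <- pp$bursts
  for (v in c("age_z", "cond_z", "temp_z", "wind_z")) {
    expect_lt(abs(mean(b[[v]])), 1e-10)
    expect_equal(sd(b[[v]]), 1, tolerance = 1e-10)
  }
  expect_true(all(b$sex %in% 0:1))
  # reference categories: female, first season, FWB
  f_id <- sim$metadata$id[sim$metadata$sex == "F"][1]
  expect_true(all(b$sex[b$id == f_id] == 0))
  expect_true(all(b$colony[b$id %in%
    sim$metadata$id[sim$metadata$colony == "FWB"]] == 0))
  expect_true(all(b$year[b$id %in%
    sim$metadata$id[sim$metadata$year == "2019"]] == 0))
  # condition is piecewise constant and uses the most recent record
  one <- b[b$id == b$id[1], ]
  expect_lte(length(unique(one$cond_z)), 3)
  # an individual absent from metadata raises an error naming it
  md_bad <- sim$metadata[-1, ]
  expect_error(preprocess_tracks(sim$fixes, sim$weather, md_bad,
                                 sim$biometrics), sim$metadata$id[1])
})

test_that("condition look-up takes the most recent biometric record", {
  steps <- data.frame(id = "a", burst = 1L,
                      timestamp = ts_utc("2019-01-01 00:00") + (0:2) * 86400 * 6,
                      step_m = 1)
  weather <- data.frame(timestamp = steps$timestamp,
                        temp_c = c(3, 4, 5), wind_speed = c(6, 7, 8))
  metadata <- data.frame(id = "a", sex = "F", colony = "FWB", year = "2019")
  biometrics <- data.frame(id = "a",
                           date = as.Date("2019-01-01") + c(0, 10),
                           mass_kg = c(5, 6), length_cm = c(60, 61))
  # need >= 3 rows for the SMA population; add a second animal
  biometrics <- rbind(biometrics,
                      data.frame(id = "b", date = as.Date("2019-01-01"),
                                 mass_kg = 7, length_cm = 63))
  cv <- build_covariates(steps, weather, metadata, biometrics)
  smi <- scaled_mass_index(biometrics)
  # day 0 and day 6 use the day-0 record; day 12 uses the day-10 record
  raw <- cv$cond_z * attr(cv, "scaling")$sd[2] + attr(cv, "scaling")$mean[2]
  expect_equal(raw, smi[c(1, 1, 2)], ignore_attr = TRUE)
})

test_that("displacement summaries aggregate per pup and per colony", {
  track <- data.frame(id = rep(c("a", "b"), each = 3),
                      lat = c(-54, -54, -54, -54.001, -54.001, -54.001),
                      lon = -38, step_m = c(0, 0, NA, 10, 20, NA))
  metadata <- data.frame(id = c("a", "b"), colony = c("FWB", "SSB"))
  refs <- list(FWB = c(lat = -54, lon = -38),
               SSB = c(lat = -54.001, lon = -38))
  ds <- displacement_summaries(track, metadata, refs)
  expect_equal(ds$per_pup$mean_step_m, c(0, 15))
  expect_equal(ds$per_pup$mean_displacement_m, c(0, 0))
  expect_equal(ds$overall_mean_step_m, mean(c(0, 0, 10, 20)))
  expect_error(displacement_summaries(track, metadata, refs["FWB"]),
               "no reference point")
})

test_that("the pipeline is idempotent and its report balances", {
  sim <- simulate_pups(sim_config(
    counts = data.frame(colony = c("FWB", "SSB"), year = c("2019", "2019"),
                        n = c(3L, 3L)),
    duration_range = c(8L, 20L), seed = 9))
  pp <- preprocess_tracks(sim$fixes, sim$weather, sim$metadata,
                          sim$biometrics)
  expect_true(pp$report$balanced)
  expect_equal(pp$report$n_step_rows, nrow(pp$bursts))
  # re-regularizing already regular fixes changes nothing
  obs <- pp$fixes[!is.na(pp$fixes$lat), c("id", "timestamp", "lat", "lon")]
  g2 <- compute_steps(regularize(obs))
  expect_equal(g2[, c("id", "timestamp", "lat", "lon")],
               pp$fixes[, c("id", "timestamp", "lat", "lon")],
               ignore_attr = TRUE)
  # censoring is idempotent
  cs1 <- censor_steps(pp$fixes$step_m)
  expect_identical(censor_steps(cs1$step)$n_censored, 0L)
  expect_identical(censor_steps(cs1$step)$step, cs1$step)
})
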