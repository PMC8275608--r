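small_cfg <- function(...) {
  sim_config(counts = data.frame(colony = c("FWB", "SSB"),
                                 year = c("2019", "2019"), n = c(2L, 2L)),
             duration_range = c(6L, 10L), mortality_rate = 0, seed = 3, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(emission = list(mu = c(75, 22), sigma = c(20, 20))))
  expect_error(sim_config(emission = list(mu = c(-1, 20), sigma = c(5, 5))))
  expect_error(sim_config(missing_rate = 1.5))
  expect_error(sim_config(sampling_interval = 7))
  expect_error(sim_config(beta = matrix(0, 2, 3)), "columns")
})

test_that("covariate grids have the right span, age and condition steps", {
  cfg <- small_cfg()
  set.seed(1)
  pup <- data.frame(id = "P1", colony = "FWB", year = "2019", sex = "F",
                    capture_date = as.Date("2018-12-20"), track_days = 2)
  cv <- simulate_covariates(cfg, pup)
  expect_equal(nrow(cv), 48)
  expect_setequal(unique(cv$age), c(0, 1))
  # condition changes exactly at the 10-day record boundaries
  pup$track_days <- 25
  cv25 <- simulate_covariates(cfg, pup)
  expect_equal(length(unique(cv25$condition)), 3)
  expect_equal(unique(cv25$condition[cv25$age < 10]),
               unique(cv25$condition)[1])
})

test_that("temperature stream matches the configured seasonal mean", {
  cfg <- small_cfg()
  w <- pupmove:::.weather_series(cfg, "2019")
  # AR(1)-adjusted Monte Carlo s.e. for the mean of a correlated series
  phi <- cfg$temperature$phi
  se <- sd(w$temp_c) * sqrt((1 + phi) / (1 - phi) / nrow(w))
  expect_lt(abs(mean(w$temp_c) - 3.7), 3 * se)
  expect_lt(abs(sd(w$temp_c) - 1.3), 0.5)
  # the two pups of a season share one environment
  sim <- simulate_pups(cfg)
  ids <- unique(sim$fixes$id)[1:2]
  expect_equal(nrow(unique(sim$weather[c("timestamp", "temp_c")])),
               nrow(sim$weather))
})

test_that("state sequences follow the transition logits", {
  n <- 40000
  X <- matrix(1, n, 1)
  # symmetric chain: half the time active
  s <- simulate_state_sequence(matrix(c(0, 0), 2, 1), X, seed = 2)
  expect_lt(abs(mean(s == 2) - 0.5), 3 / sqrt(n) * 3)
  # logits (-1.5, -0.5): empirical transition frequencies match plogis
  s2 <- simulate_state_sequence(matrix(c(-1.5, -0.5), 2, 1), X, seed = 4)
  from1 <- s2[-n] == 1
  f12 <- mean(s2[-1][from1] == 2)
  f21 <- mean(s2[-1][!from1] == 1)
  expect_lt(abs(f12 - plogis(-1.5)),
            3 * sqrt(plogis(-1.5) * (1 - plogis(-1.5)) / sum(from1)))
  expect_lt(abs(f21 - plogis(-0.5)),
            3 * sqrt(plogis(-0.5) * (1 - plogis(-0.5)) / sum(!from1)))
  # a positive age coefficient makes late life more active
  age <- seq(-1.5, 1.5, length.out = n)
  Xa <- cbind(1, age)
  sa <- simulate_state_sequence(matrix(c(-1.5, 0.8, -0.5, 0), 2, 2,
                                       byrow = TRUE), Xa, seed = 5)
  q <- n %/% 4
  expect_gt(mean(sa[(3 * q):n] == 2), mean(sa[1:q] == 2))
  expect_error(simulate_state_sequence(matrix(0, 2, 3), X), "do not match")
})

test_that("positions reproduce the emission marginals and stay near home", {
  em <- list(mu = c(22.5, 75.8), sigma = c(22.5, 75.8))
  home <- c(lat = -54.01, lon = -38.05)
  n <- 4000
  pos <- simulate_positions(rep(1L, n), em, home, seed = 6)
  st <- attr(pos, "step_m")
  expect_lt(abs(mean(st) - 22.5), 3 * 22.5 / sqrt(n))
  # recomputed haversine steps agree with the drawn gamma steps
  g <- compute_steps(data.frame(id = "a",
                                timestamp = as.POSIXct(Sys.time()) +
                                  3600 * (0:n),
                                lat = pos$lat, lon = pos$lon))
  expect_equal(g$step_m[1:n], st, tolerance = 1e-4)
  pos2 <- simulate_positions(rep(2L, n), em, home, seed = 7)
  expect_lt(abs(mean(attr(pos2, "step_m")) - 75.8), 3 * 75.8 / sqrt(n))
  # mixed sequence with attraction on: no drift away from home
  set.seed(8)
  s <- sample(1:2, 1000, replace = TRUE, prob = c(0.65, 0.35))
  pos3 <- simulate_positions(s, em, home, seed = 9)
  dist <- geosphere::distHaversine(cbind(pos3$lon, pos3$lat),
                                   cbind(home[["lon"]], home[["lat"]]),
                                   r = 6371000)
  expect_lt(max(dist), 10 * qgamma(0.95, 1, 1 / 75.8))
})

test_that("degradation is faithful to its rates and recomputable", {
  cfg <- small_cfg()
  sim <- simulate_pups(cfg)
  fixes <- sim$fixes_clean
  # identity at zero rates
  d0 <- inject_missing_and_outliers(fixes, 0, 0, seed = 1)
  expect_identical(d0$fixes$lat, fixes$lat)
  expect_equal(nrow(d0$missing), 0)
  # deletion count within 3 binomial s.e.
  big <- fixes[rep(seq_len(nrow(fixes)), 10), ]
  n <- nrow(big)
  d1 <- inject_missing_and_outliers(big, 0.05, 0, seed = 2)
  expect_lt(abs(nrow(d1$missing) - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95))
  # every injected outlier produces steps over the 400 m/h screen
  d2 <- inject_missing_and_outliers(fixes, 0, 0.01, seed = 3)
  g <- compute_steps(regularize(d2$fixes))
  bad <- paste(d2$outliers$id, d2$outliers$timestamp)
  key <- paste(g$id, g$timestamp)
  touched <- which(key %in% bad)
  adj <- unique(c(touched, touched - 1))
  adj <- adj[adj > 0 & !is.na(g$step_m[pmax(adj, 1)])]
  expect_true(all(g$step_m[adj] > 400, na.rm = TRUE))
})

test_that("truth records refer to pre-degradation states and align", {
  cfg <- small_cfg()
  sim <- simulate_pups(cfg)
  # one true state per simulated step, for every pup
  for (i in unique(sim$metadata$id)) {
    n_steps <- sum(sim$truth$states$id == i)
    n_fixes_clean <- sum(sim$fixes_clean$id == i)
    expect_equal(n_fixes_clean, n_steps + 1)
  }
  # deleted fixes are still present in the truth table
  expect_true(all(paste(sim$truth$missing$id, sim$truth$missing$timestamp)
                  %in% paste(sim$fixes_clean$id,
                             sim$fixes_clean$timestamp)))
  # mortality truncates the track at the recorded day
  cfg2 <- small_cfg()
  cfg2$mortality_rate <- 1
  sim2 <- simulate_pups(cfg2)
  died <- sim2$metadata$id[sim2$metadata$fate == "died"]
  expect_true(length(died) == nrow(sim2$metadata))
  for (i in died) {
    md <- sim2$metadata[sim2$metadata$id == i, ]
    last_fix <- max(sim2$fixes_clean$timestamp[sim2$fixes_clean$id == i])
    expect_lte(as.Date(last_fix, tz = "UTC"), md$death_date)
  }
})

test_that("datasets round-trip through disk byte-faithfully", {
  cfg <- small_cfg()
  sim <- simulate_pups(cfg)
  dir1 <- file.path(tempdir(), "simds1")
  write_dataset(sim, dir1)
  back <- read_dataset(dir1)
  expect_identical(back$fixes$id, sim$fixes$id)
  expect_identical(.subset2(back$fixes, "timestamp"), sim$fixes$timestamp)
  expect_identical(back$fixes$lat, sim$fixes$lat)
  expect_identical(back$fixes$lon, sim$fixes$lon)
  expect_equal(back$metadata, sim$metadata, ignore_attr = TRUE)
  expect_equal(back$attendance$mother_present, sim$attendance$mother_present)
  # truth lists one state per retained step
  expect_equal(sum(lengths(lapply(back$truth$states, `[[`, "state"))),
               nrow(sim$truth$states))
  # same seed, same bytes
  dir2 <- file.path(tempdir(), "simds2")
  write_dataset(simulate_pups(cfg), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("long-run activity matches the stationary covariate average", {
  cfg <- sim_config(counts = data.frame(colony = c("FWB", "SSB"),
                                        year = c("2019", "2019"),
                                        n = c(4L, 4L)),
                    duration_range = c(40L, 40L), mortality_rate = 0,
                    missing_rate = 0, outlier_rate = 0, seed = 13)
  sb <- simulate_bursts(cfg)
  X <- hmm_design(cfg$spec, sb$bursts)
  tp <- pupmove:::.trans_probs(cfg$beta, X)
  pi2 <- mean(tp$g12 / (tp$g12 + tp$g21))
  frac <- mean(sb$truth$states == 2)
  # generous Monte Carlo margin: the chain is serially correlated
  expect_lt(abs(frac - pi2), 5 * sqrt(pi2 * (1 - pi2) / nrow(X)) * 8)
})
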