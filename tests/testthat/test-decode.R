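test_that("Viterbi equals exhaustive argmax on short bursts", {
  mu <- c(22.5, 75.8)
  sigma <- c(20, 55)
  fit <- logit_fit(mu, sigma)
  for (seed in 11:16) {
    set.seed(200 + seed)
    T <- sample(4:10, 1)
    b <- make_logit_burst(T, seed)
    df <- logit_burst_df(b$step, b$g12, b$g21)
    v <- viterbi(fit, df)
    expect_equal(v$state, unname(oracle_viterbi(b$step, b$g12, b$g21,
                                                mu, sigma)))
  }
})

test_that("Viterbi returns the dominant state under overwhelming emissions", {
  fit <- logit_fit(c(10, 500), c(5, 50))
  df <- logit_burst_df(rgamma(20, 100, 10), rep(0.3, 20), rep(0.3, 20))
  expect_true(all(viterbi(fit, df)$state == 1))
})

test_that("Viterbi path log-probability dominates the true path", {
  mu <- c(20, 70); sigma <- c(18, 50)
  fit <- logit_fit(mu, sigma)
  for (seed in 31:35) {
    set.seed(seed)
    T <- 50
    g12 <- runif(T, 0.1, 0.4); g21 <- runif(T, 0.1, 0.4)
    s <- integer(T); s[1] <- 1 + (runif(1) < g12[1] / (g12[1] + g21[1]))
    for (t in 2:T)
      s[t] <- if (s[t - 1] == 1) 1 + (runif(1) < g12[t]) else
        2 - (runif(1) < g21[t])
    step <- rgamma_meansd(T, mu[s], sigma[s])
    df <- logit_burst_df(step, g12, g21)
    v <- viterbi(fit, df)
    expect_gte(oracle_path_logprob(v$state, step, g12, g21, mu, sigma),
               oracle_path_logprob(s, step, g12, g21, mu, sigma))
  }
})

test_that("decoding is accurate when the state distributions are well separated", {
  cfg <- sim_config(counts = data.frame(colony = c("FWB", "SSB"),
                                        year = c("2019", "2019"),
                                        n = c(3L, 3L)),
                    duration_range = c(15L, 15L),
                    emission = list(mu = c(22.5, 75.8),
                                    sigma = c(11.25, 37.9)),
                    covariates = c("age_z", "hour"),
                    interact = c("age_z", "hour"),
                    missing_rate = 0, outlier_rate = 0, mortality_rate = 0,
                    seed = 31)
  sb <- simulate_bursts(cfg)
  fit <- hmm_fit(cfg$emission$mu, cfg$emission$sigma, cfg$beta, cfg$spec)
  v <- viterbi(fit, sb$bursts)
  expect_gt(mean(v$state == sb$truth$states), 0.9)
})

test_that("occupancy fractions aggregate per pup and unweighted", {
  dec <- data.frame(id = rep(c("a", "b"), each = 10),
                    state = c(rep(2, 4), rep(1, 6), rep(2, 6), rep(1, 4)),
                    observed = TRUE)
  of <- occupancy_fraction(dec)
  expect_equal(of$per_pup$frac_active, c(0.4, 0.6))
  expect_equal(of$mean_active, 0.5)
  expect_equal(of$mean_inactive, 0.5)
  # all-active decode
  dec$state <- 2
  expect_equal(occupancy_fraction(dec)$mean_active, 1)
  # unobserved steps are excluded
  dec$observed <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(occupancy_fraction(dec)$per_pup$n_obs, c(10L, 0L))
})

test_that("occupancy curves are flat for null covariates and unimodal in hour", {
  spec <- hmm_spec(c("age_z", "hour"), interact = character(0))
  beta <- matrix(0, 2, 4,
                 dimnames = list(NULL, c("(Intercept)", "age_z", "sin1",
                                         "cos1")))
  beta[, 1] <- c(-1.5, -0.7)
  beta[1, "cos1"] <- -0.6
  beta[2, "cos1"] <- 0.5
  fit <- hmm_fit(c(22.5, 75.8), c(22.5, 75.8), beta, spec)
  # age has zero coefficients: curve must be exactly flat
  cv <- occupancy_curve(fit, "age_z", seq(-2, 2, length.out = 9))
  expect_equal(diff(range(cv$point)), 0)
  # a single harmonic through the monotone link has one interior maximum
  ch <- occupancy_curve(fit, "hour", seq(0, 24, by = 0.25))
  dp <- diff(ch$point)
  expect_equal(sum(diff(sign(dp)) < 0), 1)
  expect_equal(which.max(ch$point), which(ch$grid == 12))
  # no covariance: band flagged absent
  expect_false(attr(cv, "band"))
  expect_true(all(is.na(cv$lower)))
})

test_that("Monte Carlo bands stabilize with the number of draws", {
  d <- fit_toy_data(n = 1500)
  set.seed(40)
  d$age_z <- rnorm(nrow(d))
  f <- fit_hmm(d, hmm_spec("age_z", interact = character(0)),
               n_restarts = 2, seed = 6)
  w <- function(n) {
    cv <- occupancy_curve(f, "age_z", 0, n_draws = n, seed = 9)
    cv$upper - cv$lower
  }
  w1 <- w(1000)
  w2 <- w(10000)
  expect_lt(abs(w1 - w2) / w2, 0.10)
})

test_that("pseudo-residuals collapse to the gamma probit when states coincide", {
  spec <- hmm_spec()
  beta <- matrix(c(qlogis(0.3), qlogis(0.4)), 2, 1,
                 dimnames = list(NULL, "(Intercept)"))
  fit <- hmm_fit(c(50, 50 + 1e-9), c(30, 30), beta, spec)
  set.seed(14)
  df <- data.frame(id = "q", burst = 1L, step_m = rgamma_meansd(200, 50, 30))
  z <- pseudo_residuals(fit, df)
  expect_equal(z, qnorm(pgamma_meansd(df$step_m, 50, 30)), tolerance = 1e-6)
})

test_that("pseudo-residuals propagate the filter across missing steps", {
  fit <- logit_fit(c(20, 80), c(15, 50))
  b <- make_logit_burst(30, 77)
  b$step[10] <- NA
  df <- logit_burst_df(b$step, b$g12, b$g21)
  z <- pseudo_residuals(fit, df)
  expect_true(is.na(z[10]))
  expect_true(all(is.finite(z[!is.na(b$step)])))
})

test_that("marginal fit table is a proper probability comparison", {
  d <- fit_toy_data(n = 4000)
  f <- fit_hmm(d, hmm_spec(), n_restarts = 2, seed = 8, hessian = FALSE)
  mf <- marginal_fit(f, d, n_bins = 25)
  expect_equal(sum(mf$table$empirical), 1, tolerance = 1e-6)
  expect_equal(sum(mf$table$model), 1, tolerance = 1e-6)
  expect_equal(sum(mf$weights), 1)
  # self-consistency: data were generated from a 2-state gamma switch
  expect_lt(mf$tv, 0.05)
})
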