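# pupmove

Behavioural-state analysis of regular-interval GPS tracks from Antarctic
fur seal pups — and other land-bound "central place explorers" that
alternate rest at a home patch with short bouts of directed exploration.

The package takes raw hourly fixes, weather series, biometrics and
individual metadata, and answers two questions: *how does movement
decompose into discrete behavioural states?* and *which individual and
environmental covariates drive switching between them?*

## The model

The observed variable is the step length `x_t`: the haversine distance (m)
between consecutive regularized fixes. A two-state hidden Markov model is
fitted to the pooled steps of all individuals:

* **Emissions**: `x_t | S_t = i ~ Gamma(mean mu_i, sd sigma_i)` with
  `mu_1 < mu_2` (state 1 = "inactive", state 2 = "active").
* **Transitions**: a Markov chain with time-varying off-diagonal
  probabilities through a logit link,
  `logit(gamma12_t) = beta_1' x_t`, `logit(gamma21_t) = beta_2' x_t`,
  where the design row `x_t` holds an intercept, standardized covariates
  (age, body condition, temperature, wind), 0/1 indicators (sex, season,
  colony), sine/cosine of the hour of day, and colony-interaction terms.
* **Likelihood**: scaled forward recursion over independent bursts, each
  initialized at the stationary distribution
  `pi(x) = (gamma21, gamma12) / (gamma12 + gamma21)` of its first step's
  transition matrix; maximized directly over
  `theta = (log mu, log sigma, beta)` with BFGS restarts (recursions in
  C++).

Around the model: burst preprocessing with the 400 m/h speed screen and
48 h span filter, Viterbi decoding, stationary occupancy curves with Monte
Carlo confidence bands, forecast pseudo-residuals, an AIC
covariate-exclusion ladder for covariate relevance, post-hoc
random-intercept logistic regressions on the decoded states, and a
synthetic multi-pup track generator with known ground truth
(`simulate_pups()`), so the whole pipeline runs with no external data.

## Worked example

```r
library(pupmove)

# a small synthetic study: 10 pups, two colonies, one season
cfg <- sim_config(counts = data.frame(colony = c("FWB", "SSB"),
                                      year = c("2019", "2019"), n = c(5L, 5L)),
                  duration_range = c(20L, 30L), seed = 42)
sim <- simulate_pups(cfg)

pp  <- preprocess_tracks(sim$fixes, sim$weather, sim$metadata, sim$biometrics)
fit <- fit_hmm(pp$bursts, hmm_spec(c("age_z", "hour"), interact = "age_z"),
               n_restarts = 3, seed = 1)
print(fit)
#> Two-state gamma step-length HMM
#>      inactive (1) active (2)
#> mean      22.6496    91.2902
#> sd        22.6006    72.8853
#>
#> log-likelihood: -26159.46898   AIC: 52350.93795   parameters: 16
#> observed steps: 5570  bursts: 25

dec <- viterbi(fit, pp$bursts)
occ <- occupancy_fraction(dec)
round(100 * c(inactive = occ$mean_inactive, active = occ$mean_active), 1)
#> inactive   active
#>     77.3     22.7
```

Reading the output: the two fitted states separate short resting steps
(mean ~23 m/h) from exploratory movement (mean ~91 m/h on this small
sample; the generator's true active mean is 75.8 m), and the decoded
sequences say these pups spent roughly three quarters of their time
inactive. `pp$report` reconciles every raw sampling interval (kept step
rows + censored steps + dropped intervals), and
`occupancy_curve(fit, "hour", seq(0, 24, 0.5))` traces the diurnal
activity cycle with its 95% Monte Carlo band.

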