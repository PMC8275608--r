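---
title: "Modelling fur seal pup activity with covariate-driven hidden Markov models"
author: "pupmove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fur seal pup activity with covariate-driven hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupmove)
```

## The scientific problem

Antarctic fur seal pups are central place explorers: between birth and
moulting they alternate long rests at a home patch (a suckling location in
or near their natal colony) with short bouts of directed exploration,
producing star-shaped terrestrial tracks. `pupmove` models this behaviour
from regular-interval GPS fixes. The observed variable is the step length —
the great-circle distance between consecutive hourly positions — and the
scientific questions are (i) how activity decomposes into discrete
behavioural states and (ii) which individual and environmental covariates
drive switching between them.

## The model

A two-state hidden Markov model is fitted to the pooled step lengths of all
individuals. Conditional on the latent state $S_t \in \{1, 2\}$
(1 = inactive, 2 = active), the step $X_t$ is gamma distributed with
state-specific mean $\mu_i$ and standard deviation $\sigma_i$ (metres),
with the label convention $\mu_1 < \mu_2$. The state sequence is a Markov
chain whose off-diagonal transition probabilities depend on covariates
through a logit link:

$$\gamma^{(12)}_t = \mathrm{logit}^{-1}(\beta_1' x_t), \qquad
  \gamma^{(21)}_t = \mathrm{logit}^{-1}(\beta_2' x_t),$$

where $x_t$ contains an intercept, main effects, colony-interaction terms
and a trigonometric expansion of the hour of day
($\sin 2\pi h/24$, $\cos 2\pi h/24$; one harmonic pair by default, which is
the smallest expansion able to produce the single midday activity peak seen
in this system). Every term enters both logits: the covariate set per logit
is not separately configurable, which keeps "excluding a covariate" a
well-defined column drop in both rows.

Each burst (see below) is treated as an independent realization whose
initial state follows the stationary distribution of the transition matrix
at its first observation's covariates,
$\pi(x) = (\gamma^{(21)}, \gamma^{(12)}) / (\gamma^{(12)} + \gamma^{(21)})$.
This adds no parameters and is the conventional choice for
covariate-transition HMMs. The likelihood is computed by the scaled forward
recursion (implemented in C++, as is usual for movement HMMs) and maximized
directly over the working vector
$\theta = (\log \mu, \log \sigma, \beta)$ with BFGS.

"State occupancy probability" — the quantity plotted against a covariate —
is the stationary probability $\pi_2(x)$ of the active state at that
covariate configuration with all other covariates held at their mean
(standardized metric covariates at 0) or reference category. Confidence
bands come from Monte Carlo simulation of $\theta$ from a multivariate
normal centred at the MLE with the observed-information covariance;
percentile bands are used rather than a normal approximation so the band
respects $[0, 1]$.

## Preprocessing

The pipeline mirrors the filters a field analyst would apply, in a fixed
order: regularize → steps → censor → split → covariates.

* **Regularization.** Fixes snap to the nearest instant of the nominal
  grid (window = half the interval, nearer fix wins on conflicts); grid
  instants without a fix become explicit missing rows.
* **Step computation.** Haversine distance on the mean Earth radius
  6,371,000 m. At the sub-kilometre scale of pup movement this differs
  from a projected distance by far less than the ~5 m GPS accuracy.
* **Speed screen.** Steps above 400 m/h (the fastest plausible pup
  movement, scaled for other intervals) are set to missing, not deleted:
  censoring creates missing *steps*, never gaps in *fixes*, so it cannot
  change the burst structure regardless of whether it is applied before or
  after splitting. It is applied before.
* **Burst splitting.** Observation gaps above 4 h cut the track; bursts
  spanning less than 48 h first-to-last instant are dropped. Span, not the
  count of non-missing fixes, defines the 48 h criterion.
* **Covariates.** Sex (reference female), season (reference the earlier
  year) and colony (reference configurable) are 0/1 indicators; age is
  whole days since the first grid instant (first capture); condition is
  the most recent scaled mass index, constant between 10-day measurements;
  weather joins by timestamp after linear interpolation of interior gaps
  (edge gaps take the nearest value — interpolation is undefined there).
  Metric covariates are standardized with pooled all-individual constants
  because a single HMM is fitted jointly; the constants are stored in the
  output so later stages reuse identical scaling.

A reconciliation report classifies every grid interval as a kept step row,
a censored step, or a dropped interval, and `report$balanced` asserts the
bookkeeping is exact.

**Zero steps.** The gamma density is degenerate at 0. Steps of exactly 0 m
(rare under 5 m GPS noise) are offset to half the smallest positive
observed step; the count is recorded on the fit object.

## The synthetic study

`sim_config()` / `simulate_pups()` generate a complete synthetic study so
every stage is testable without any external data. The defaults encode the
study conditions this package models:

* 66 pups across two colonies (32 at the reference colony, 34 at the
  other) and two seasons (40/26), hourly fixes, deployment durations drawn
  uniformly from 20–80 days, births staggered over the December pupping
  period.
* Gamma emission means 22.5 m (inactive) and 75.8 m (active), with the
  standard deviations defaulting to the means.
* Transition intercepts corresponding to mean bout durations of roughly
  8 h inactive and 4.3 h active, giving a long-run activity budget of
  about 65% inactive / 35% active; a midday activity peak through the
  hour-of-day harmonics; an age effect confined to the reference colony
  (activity rises with age there and stays flat at the other colony); and
  a season effect strongest at the reference colony.
* Weather as per-season AR(1) streams (temperature mean 3.7 °C, s.d. 1.3
  in the first season; 3.9 °C, s.d. 1.4 in the second; a small diurnal
  cycle) shared by all pups of a season; wind is an AR(1) stream with mean
  7 m/s. These series carry null transition coefficients by default, so
  temperature and wind are "measured but irrelevant" covariates, which is
  exactly what a covariate-relevance analysis needs to discriminate.
* About 20% of pups die early (death day lognormal around 15 days,
  truncated to 4–41); their tracks are truncated before anything is
  written. Doomed pups carry a negative activity offset on the transition
  logits, and steps on days the mother is away at sea carry a small
  positive one — these two shifts live outside the HMM covariate set and
  exist so the post-hoc regressions have real signal to find.
* Degradation: 2% of fixes lost independently, occasional multi-hour
  outages (which create the observation gaps that split tracks into
  bursts), and 0.2% of fixes displaced by 1.2–2.5 km so that every
  implied step fails the 400 m/h screen.
* Geometry: per-pup home patches scatter around the colony reference with
  Rayleigh scales of 40 m (reference colony) and 140 m (other colony);
  active headings persist with a home-attraction term that grows with
  distance (scale 150 m), inactive headings are isotropic. The resulting
  tracks are star-shaped and colony displacement differs between colonies
  in the intended direction, but this excursion geometry is qualitative:
  no quantitative description of excursion lengths or return times was
  available to calibrate against, so positional summaries from the
  generator should be read as order-of-magnitude, not as calibrated
  reproductions.

Because the ground-truth coefficients apply to the *standardized* design
(the generator standardizes its covariates with pooled constants before
simulating states), a refit on the preprocessed data estimates the same
quantities, up to the small difference between the generator's
standardization constants and those recomputed on the retained steps.

What passing tests on these data do **not** show: robustness to GPS error
correlated in time, to behaviour that is not two-state Markov, to
emission distributions that are not gamma, or to covariate measurement
error — none of which the generator emulates.

## Estimation details

* Restarts: emission starting values from a median split of the observed
  steps; transition coefficients start at zero; both are randomly
  perturbed after the first restart. The best converged restart wins, and
  states are relabeled so state 1 has the smaller mean.
* Convergence: BFGS with relative function tolerance `1e-8`, up to 500
  iterations; a fit where no restart converges is an error carrying the
  per-restart trace.
* Uncertainty: covariance of $\theta$ from the inverse numerically
  differentiated observed information; if the Hessian is singular the fit
  is returned with the covariance flagged unavailable (occupancy curves
  then carry no bands).
* Reduced models in the AIC exclusion ladder are warm-started from the
  full fit's surviving coefficients plus fresh restarts, which enforces
  the nesting inequality (reduced log-likelihood never exceeds the full
  one beyond optimizer noise) in practice. The relevance threshold
  (default `dAIC >= 40`) is a reporting convention, configurable, and
  never changes which model is used for inference.
* Pseudo-residuals are the forecast (one-step-ahead) construction — the
  probit of the predictive CDF given the past only — so that under a
  correct model they are standard normal and serially uncorrelated;
  predictive probabilities propagate across missing steps. CDF values are
  clamped to `[1e-12, 1 - 1e-12]`.
* Viterbi ties break toward the lower state index; missing steps carry
  unit emission and still receive a state.

## Post-hoc analyses

Decoded states (active = 1) are regressed on daily maternal attendance
(all steps of a day inherit that day's record) and on survival status,
each with a random intercept per pup, fitted by adaptive Gauss–Hermite
quadrature with 15 nodes (the 1-node special case is the Laplace
approximation; 15 nodes cost little and are more accurate for a single
random effect). A simulation-envelope dispersion ratio on Pearson
residuals provides a lightweight over/under-dispersion check. The
per-group active proportions are reported raw; the headline "x% more
active" contrast is left to the reader because its definition (difference
vs ratio of proportions) is ambiguous.

The colony comparison of per-pup mean natal-colony displacement uses the
two-sided Wilcoxon rank-sum test (exact for small samples without ties,
tie-corrected normal approximation with continuity correction otherwise).

## Problem sizes used in the validation suite

The package's own experiments are scaled to run comfortably on a single
CPU: parameter recovery uses 30 pups × 720 hourly steps; ladder
discrimination 20 pups × ~1000 steps; residual calibration a series of
20,000 steps simulated from a fitted model; GLMM recovery 60 groups × 500
observations, with the permutation size-check at 30 groups × 40
observations over 500 replicates. The likelihood oracle checks use exact
path enumeration up to T = 10.

## Known limitations

* Only the univariate (step length) two-state gamma HMM is supported as an
  analysis path; turning-angle emissions and three-state models are out of
  scope, as are random effects inside the HMM.
* Occupancy is the stationary distribution at fixed covariates, not the
  smoothed posterior state frequency; the two differ when covariates vary
  quickly relative to the chain's mixing time.
* With emission standard deviations as large as the means, the two state
  distributions overlap substantially and per-step decoding accuracy is
  intrinsically limited (around 80% under realistic bout lengths);
  occupancy summaries remain approximately unbiased, but per-step state
  labels should not be over-interpreted in that regime.
* The percentage of time per state is the unweighted mean of per-pup
  fractions; a pooled variant is reported alongside.
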