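#' Viterbi decoding of behavioural states
#'
#' Computes the single most probable state path for every burst under the
#' time-varying transition matrices and gamma emissions of a fitted model,
#' by the log-space Viterbi dynamic program. Missing steps contribute a unit
#' emission and are still assigned a state; ties are broken toward the
#' lower state index.
#'
#' @param fit An `hmm_fit`.
#' @param data Burst table with `id`, `burst`, `step_m` and covariates.
#' @return `data` with two added columns: `state` (1 = inactive,
#'   2 = active) and `observed` (was the step non-missing?).
#' @export
viterbi <- function(fit, data) {
  stopifnot(inherits(fit, "hmm_fit"))
  X <- hmm_design(fit$spec, data)
  if (!identical(attr(X, "signature"), fit$signature))
    stop("design signature of 'data' does not match the fit")
  if (is.null(data$id)) data$id <- "1"
  if (is.null(data$burst)) data$burst <- 1L
  step <- data$step_m
  if (!is.na(fit$zero_offset) && any(step == 0, na.rm = TRUE))
    step[!is.na(step) & step == 0] <- fit$zero_offset
  ld <- .emission_logdens(step, fit$mu, fit$sigma)
  tp <- .trans_probs(fit$beta, X)
  data$state <- hmm_viterbi_cpp(ld, tp$g12, tp$g21, .burst_key(data))
  data$observed <- !is.na(data$step_m)
  data
}

#' Time spent per behavioural state
#'
#' Per-individual fraction of observed steps decoded into each state, with
#' the unweighted mean across individuals ("pups spent on average ...") and
#' the range. A pooled variant (fraction over all observations, ignoring
#' individual identity) is also reported.
#'
#' @param decoded Output of [viterbi()] (must contain `id`, `state`,
#'   `observed`).
#' @return List with `per_pup` (data frame: id, n_obs, frac_inactive,
#'   frac_active), `mean_inactive`, `mean_active`, `range_active`, and
#'   `pooled_active`.
#' @export
occupancy_fraction <- function(decoded) {
  d <- decoded[decoded$observed, , drop = FALSE]
  ids <- unique(decoded$id)
  per <- do.call(rbind, lapply(ids, function(i) {
    s <- d$state[d$id == i]
    data.frame(id = i, n_obs = length(s),
               frac_inactive = mean(s == 1), frac_active = mean(s == 2))
  }))
  list(per_pup = per,
       mean_inactive = mean(per$frac_inactive),
       mean_active = mean(per$frac_active),
       range_active = range(per$frac_active),
       pooled_active = mean(d$state == 2))
}

# baseline covariate row: metric covariates at 0 (their standardized mean),
# categorical indicators at the reference level 0
.baseline_row <- function(spec, fix = list()) {
  vars <- unique(c(spec$covariates,
                   if (length(spec$interact)) "colony"))
  row <- as.data.frame(setNames(as.list(rep(0, length(vars))), vars))
  if (!length(vars)) row <- data.frame(row.names = 1)
  for (nm in names(fix)) row[[nm]] <- fix[[nm]]
  row
}

#' State occupancy probability along one covariate
#'
#' Evaluates the stationary probability of the active state as a function
#' of one covariate, holding all other covariates at their mean
#' (standardized metric covariates at 0) or reference category (indicator
#' 0), and attaches a 95% Monte Carlo confidence band obtained by sampling
#' parameter vectors from a multivariate normal centred at the MLE with the
#' fit's covariance and taking pointwise 2.5/97.5 percentiles.
#'
#' @param fit An `hmm_fit` with available covariance (a fit without one
#'   yields the point curve with the band marked absent).
#' @param covariate Name of the covariate to vary (e.g. `"age_z"`,
#'   `"hour"`).
#' @param grid Numeric grid of covariate values.
#' @param n_draws Monte Carlo draws for the band (default 1000).
#' @param seed Optional seed for the draws.
#' @param fix Named list of values overriding the baseline for the other
#'   covariates (e.g. `list(colony = 1)`).
#' @param stratify_colony If `TRUE`, returns one curve per colony level
#'   (0 and 1).
#' @return Data frame of class `occupancy_curve` with columns `covariate`,
#'   `grid`, `colony`, `point`, `lower`, `upper` (band columns `NA` when no
#'   covariance is available; attribute `band` says whether bands exist).
#' @export
occupancy_curve <- function(fit, covariate, grid, n_draws = 1000,
                            seed = NULL, fix = list(),
                            stratify_colony = FALSE) {
  stopifnot(inherits(fit, "hmm_fit"))
  levels <- if (stratify_colony) c(0, 1) else
    if (!is.null(fix$colony)) fix$colony else 0
  out <- NULL
  if (!is.null(seed)) set.seed(seed)
  draws <- NULL
  if (fit$vcov_ok) {
    draws <- MASS::mvrnorm(n_draws, fit$theta, fit$vcov)
  }
  p <- ncol(fit$beta)
  for (cl in levels) {
    fx <- fix
    fx$colony <- cl
    nd <- .baseline_row(fit$spec, fx)
    nd <- nd[rep(1, length(grid)), , drop = FALSE]
    nd[[covariate]] <- grid
    X <- hmm_design(fit$spec, nd)
    tp <- .trans_probs(fit$beta, X)
    point <- tp$g12 / (tp$g12 + tp$g21)
    lower <- upper <- rep(NA_real_, length(grid))
    if (!is.null(draws)) {
      sims <- apply(draws, 1, function(th) {
        b <- .theta_unpack(th, p)$beta
        tpd <- .trans_probs(b, X)
        tpd$g12 / (tpd$g12 + tpd$g21)
      })
      if (is.null(dim(sims))) sims <- matrix(sims, nrow = 1)
      qs <- apply(sims, 1, quantile, probs = c(0.025, 0.975))
      lower <- qs[1, ]
      upper <- qs[2, ]
    }
    out <- rbind(out, data.frame(covariate = covariate, grid = grid,
                                 colony = cl, point = point,
                                 lower = lower, upper = upper))
  }
  structure(out, band = !is.null(draws), class = c("occupancy_curve",
                                                   "data.frame"))
}

#' @export
plot.occupancy_curve <- function(x, ...) {
  graphics::plot(x$grid, x$point, type = "n", ylim = c(0, 1),
                 xlab = x$covariate[1], ylab = "P(active)", ...)
  for (cl in unique(x$colony)) {
    d <- x[x$colony == cl, ]
    if (attr(x, "band") && all(is.finite(d$lower)))
      graphics::polygon(c(d$grid, rev(d$grid)), c(d$lower, rev(d$upper)),
                        col = grDevices::adjustcolor(cl + 2, 0.2),
                        border = NA)
    graphics::lines(d$grid, d$point, col = cl + 2, lwd = 2)
  }
  invisible(x)
}

#' Forecast pseudo-residuals
#'
#' One-step-ahead pseudo-residuals: `u_t = P(X_t <= x_t | x_1, ..,
#' x_{t-1})` from the normalized forward weights propagated through the
#' transition matrix, transformed to the standard-normal scale by the
#' probit. Under a correctly specified model they are standard normal and
#' serially uncorrelated. Missing steps yield missing residuals while the
#' filter still advances. Values of `u` numerically equal to 0 or 1 are
#' clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param fit An `hmm_fit`.
#' @param data Burst table matching the fit's specification.
#' @return Numeric vector of residuals aligned to `data` rows (`NA` where
#'   the step is missing).
#' @export
pseudo_residuals <- function(fit, data) {
  stopifnot(inherits(fit, "hmm_fit"))
  X <- hmm_design(fit$spec, data)
  if (!identical(attr(X, "signature"), fit$signature))
    stop("design signature of 'data' does not match the fit")
  if (is.null(data$id)) data$id <- "1"
  if (is.null(data$burst)) data$burst <- 1L
  step <- data$step_m
  if (!is.na(fit$zero_offset) && any(step == 0, na.rm = TRUE))
    step[!is.na(step) & step == 0] <- fit$zero_offset
  obs <- !is.na(step)
  ld <- .emission_logdens(step, fit$mu, fit$sigma)
  tp <- .trans_probs(fit$beta, X)
  pred <- hmm_predictive_cpp(ld, obs, tp$g12, tp$g21, .burst_key(data))
  u <- rep(NA_real_, length(step))
  u[obs] <- pred[obs, 1] * pgamma_meansd(step[obs], fit$mu[1], fit$sigma[1]) +
    pred[obs, 2] * pgamma_meansd(step[obs], fit$mu[2], fit$sigma[2])
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  qnorm(u)
}

#' Empirical vs fitted marginal step-length distribution
#'
#' Compares the histogram of observed steps with the model-implied marginal
#' distribution: the two-component gamma mixture weighted by the
#' time-averaged stationary state probabilities over all observed covariate
#' rows. The discrepancy is summarized by the total variation distance on
#' the binning.
#'
#' @param fit An `hmm_fit`.
#' @param data Burst table matching the fit's specification.
#' @param n_bins Number of equal-width bins on `(0, max step]`.
#' @return List with `table` (lower, upper, mid, empirical and model bin
#'   probabilities), `tv` (total variation distance) and `weights`
#'   (time-averaged stationary state probabilities).
#' @export
marginal_fit <- function(fit, data, n_bins = 30) {
  stopifnot(inherits(fit, "hmm_fit"))
  X <- hmm_design(fit$spec, data)
  if (!identical(attr(X, "signature"), fit$signature))
    stop("design signature of 'data' does not match the fit")
  step <- data$step_m
  obs <- !is.na(step)
  tp <- .trans_probs(fit$beta, X)
  pi2 <- tp$g12 / (tp$g12 + tp$g21)
  w <- c(1 - mean(pi2[obs]), mean(pi2[obs]))
  s <- step[obs]
  edges <- seq(0, max(s), length.out = n_bins + 1)
  emp <- tabulate(findInterval(s, edges, rightmost.closed = TRUE,
                               left.open = TRUE) , nbins = n_bins)
  emp <- emp / sum(emp)
  cdf <- function(q) w[1] * pgamma_meansd(q, fit$mu[1], fit$sigma[1]) +
    w[2] * pgamma_meansd(q, fit$mu[2], fit$sigma[2])
  # renormalize the model mass to the binned support (0, max step]
  pm <- diff(cdf(edges)) / (cdf(max(s)) - cdf(0))
  tab <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                    mid = (edges[-1] + edges[-length(edges)]) / 2,
                    empirical = emp, model = pm)
  list(table = tab, tv = 0.5 * sum(abs(emp - pm)), weights = w)
}
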