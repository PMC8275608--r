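# burst key: integer that changes value at every id/burst boundary;
# rows are assumed contiguous within a burst
.burst_key <- function(data) {
  k <- paste(data$id, data$burst, sep = "\r")
  if (!length(k)) return(integer(0))
  cumsum(c(TRUE, k[-1] != k[-length(k)]))
}

# n x 2 log emission densities; missing steps get log(1) = 0 in both states
.emission_logdens <- function(step, mu, sigma) {
  n <- length(step)
  out <- matrix(0, n, 2)
  obs <- !is.na(step)
  if (any(step[obs] <= 0))
    stop("non-positive step lengths; offset zeros before computing the likelihood")
  out[obs, 1] <- dgamma_meansd(step[obs], mu[1], sigma[1], log = TRUE)
  out[obs, 2] <- dgamma_meansd(step[obs], mu[2], sigma[2], log = TRUE)
  out
}

.theta_pack <- function(mu, sigma, beta) {
  c(log(mu), log(sigma), beta[1, ], beta[2, ])
}

.theta_unpack <- function(theta, p) {
  list(mu = exp(theta[1:2]), sigma = exp(theta[3:4]),
       beta = rbind(theta[4 + seq_len(p)], theta[4 + p + seq_len(p)]))
}

.theta_names <- function(cols) {
  c("log_mu1", "log_mu2", "log_sigma1", "log_sigma2",
    paste0("1->2:", cols), paste0("2->1:", cols))
}

#' Forward log-likelihood of a fitted or hypothesized HMM
#'
#' Evaluates the HMM log-likelihood by the scaled forward recursion, summed
#' over all bursts (each burst is an independent realization initialized at
#' the stationary distribution of its first step's transition matrix).
#' Missing steps contribute a unit emission: the transition structure still
#' advances across them.
#'
#' @param object An `hmm_fit` (from [fit_hmm()] or [hmm_fit()]).
#' @param data Burst table with columns `id`, `burst`, `step_m` and the
#'   covariates required by the fit's specification.
#' @return Scalar log-likelihood (`-Inf` if numerically degenerate).
#' @export
forward_loglik <- function(object, data) {
  stopifnot(inherits(object, "hmm_fit"))
  X <- hmm_design(object$spec, data)
  if (!identical(attr(X, "signature"), object$signature))
    stop("design signature of 'data' does not match the fit")
  ld <- .emission_logdens(data$step_m, object$mu, object$sigma)
  tp <- .trans_probs(object$beta, X)
  hmm_forward_cpp(ld, tp$g12, tp$g21, .burst_key(data))
}

#' Construct an HMM object from known parameters
#'
#' Builds an `hmm_fit` object directly from given emission and transition
#' parameters, without estimation. Useful for simulation studies, for
#' evaluating the likelihood at hypothesized values, and for decoding with
#' externally supplied parameters.
#'
#' @param mu,sigma Length-2 positive vectors of per-state gamma means and
#'   standard deviations (metres); state 1 must have the smaller mean.
#' @param beta 2 x p transition coefficient matrix (rows: 1->2, 2->1) whose
#'   columns follow the design of `spec` (see [hmm_design()]).
#' @param spec An [hmm_spec()].
#' @param vcov Optional covariance matrix of the working parameter vector.
#' @return An object of class `hmm_fit`.
#' @export
hmm_fit <- function(mu, sigma, beta, spec, vcov = NULL) {
  stopifnot(length(mu) == 2, length(sigma) == 2,
            all(mu > 0), all(sigma > 0), inherits(spec, "hmm_spec"))
  if (mu[1] >= mu[2])
    stop("state 1 (inactive) must have the smaller mean step length")
  beta <- rbind(beta)
  stopifnot(nrow(beta) == 2)
  cols <- .spec_colnames(spec)
  if (ncol(beta) != length(cols))
    stop("beta has ", ncol(beta), " columns; spec design has ", length(cols))
  colnames(beta) <- cols
  rownames(beta) <- c("1->2", "2->1")
  theta <- .theta_pack(mu, sigma, beta)
  names(theta) <- .theta_names(cols)
  structure(list(mu = setNames(mu, c("inactive", "active")),
                 sigma = setNames(sigma, c("inactive", "active")),
                 beta = beta, theta = theta,
                 loglik = NA_real_, npar = length(theta), aic = NA_real_,
                 vcov = vcov, vcov_ok = !is.null(vcov),
                 spec = spec, signature = paste(cols, collapse = "|"),
                 restarts = NULL, n_zero_offset = 0L, zero_offset = NA_real_,
                 nobs = NA_integer_, nbursts = NA_integer_,
                 call = match.call()),
            class = "hmm_fit")
}

# design column names implied by a spec (without data): built on a 1-row dummy
.spec_colnames <- function(spec) {
  dummy <- as.data.frame(setNames(as.list(rep(0, length(unique(
    c(spec$covariates, if (length(spec$interact)) "colony"))))),
    unique(c(spec$covariates, if (length(spec$interact)) "colony"))))
  if (!nrow(dummy)) dummy <- data.frame(row.names = 1)
  colnames(hmm_design(spec, dummy))
}

#' Fit the two-state gamma HMM by direct maximum likelihood
#'
#' Maximizes the forward log-likelihood over the working parameter vector
#' `theta = (log mu, log sigma, beta)` with BFGS, using several random
#' restarts: emission starting values come from a median split of the
#' observed steps (perturbed multiplicatively after the first restart) and
#' transition coefficients start at zero (perturbed by small noise). The
#' best converged restart is kept and states are relabeled so state 1 has
#' the smaller mean. The covariance of `theta` is the inverse of the
#' numerically differentiated observed information at the optimum.
#'
#' Steps equal to exactly zero are undefined under the gamma density; they
#' are offset to half the smallest positive observed step and the count is
#' recorded in the returned object (`n_zero_offset`).
#'
#' @param data Burst table: one row per step with columns `id`, `burst`,
#'   `step_m` (metres, `NA` for missing) and the covariates named in `spec`.
#' @param spec An [hmm_spec()].
#' @param n_restarts Number of optimizer restarts (default 10).
#' @param seed Optional integer seed controlling restart perturbations;
#'   refitting with the same seed reproduces the fit exactly.
#' @param warm_start Optional list with elements `mu`, `sigma`, `beta` used
#'   as an additional unperturbed starting point (e.g. from a larger model).
#' @param reltol Relative function-change convergence tolerance.
#' @param maxit Maximum BFGS iterations per restart.
#' @param hessian Compute the observed-information covariance?
#' @return An object of class `hmm_fit`.
#' @examples
#' set.seed(1)
#' toy <- data.frame(id = "p1", burst = 1,
#'                   step_m = rgamma_meansd(300, 30, 30), hour = 0)
#' fit <- fit_hmm(toy, hmm_spec(), n_restarts = 2, seed = 1)
#' coef(fit)
#' @export
fit_hmm <- function(data, spec = hmm_spec(), n_restarts = 10, seed = NULL,
                    warm_start = NULL, reltol = 1e-8, maxit = 500,
                    hessian = TRUE) {
  stopifnot(inherits(spec, "hmm_spec"), is.data.frame(data))
  if (is.null(data$id)) data$id <- "1"
  if (is.null(data$burst)) data$burst <- 1L
  step <- data$step_m
  obs <- !is.na(step)
  if (sum(obs) < 2 || length(unique(step[obs])) < 2)
    stop("need at least 2 distinct non-missing step values")
  n_zero <- sum(step[obs] == 0)
  zero_offset <- NA_real_
  if (n_zero > 0) {
    zero_offset <- min(step[obs][step[obs] > 0]) / 2
    step[obs & !is.na(step) & step == 0] <- zero_offset
  }
  X <- hmm_design(spec, data)
  p <- ncol(X)
  bkey <- .burst_key(data)

  nll <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    pars <- .theta_unpack(theta, p)
    # exp() under/overflow of the working scale
    if (any(pars$mu <= 0) || any(pars$sigma <= 0) ||
        any(!is.finite(c(pars$mu, pars$sigma)))) return(1e10)
    # NaNs from extreme transient shape/rate values become -Inf downstream
    ld <- suppressWarnings(.emission_logdens(step, pars$mu, pars$sigma))
    tp <- .trans_probs(pars$beta, X)
    ll <- hmm_forward_cpp(ld, tp$g12, tp$g21, bkey)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # median-split emission starts
  s <- step[obs]
  lo <- s[s <= median(s)]
  hi <- s[s > median(s)]
  mu0 <- c(mean(lo), mean(hi))
  sd0 <- pmax(c(sd(lo), sd(hi)), mu0 * 0.25, 1e-3)
  if (!is.null(seed)) set.seed(seed)

  starts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    if (r == 1) {
      starts[[r]] <- .theta_pack(mu0, sd0, matrix(0, 2, p))
    } else {
      mu_r <- mu0 * exp(rnorm(2, 0, 0.2))
      sd_r <- sd0 * exp(rnorm(2, 0, 0.2))
      starts[[r]] <- .theta_pack(mu_r, sd_r,
                                 matrix(rnorm(2 * p, 0, 0.1), 2, p))
    }
  }
  if (!is.null(warm_start)) {
    wbeta <- rbind(warm_start$beta)
    stopifnot(ncol(wbeta) == p)
    starts <- c(list(.theta_pack(warm_start$mu, warm_start$sigma, wbeta)),
                starts)
  }

  trace <- data.frame(restart = seq_along(starts), loglik = NA_real_,
                      convergence = NA_integer_, fn_evals = NA_integer_)
  best <- NULL
  for (r in seq_along(starts)) {
    opt <- tryCatch(
      optim(starts[[r]], nll, method = "BFGS",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    trace$loglik[r] <- -opt$value
    trace$convergence[r] <- opt$convergence
    trace$fn_evals[r] <- opt$counts[1]
    if (opt$convergence == 0 &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) {
    message(paste(utils::capture.output(print(trace)), collapse = "\n"))
    stop("no restart converged; per-restart trace printed above")
  }

  theta <- best$par
  pars <- .theta_unpack(theta, p)
  # relabel so state 1 is the smaller-mean (inactive) state
  if (pars$mu[1] > pars$mu[2]) {
    pars <- list(mu = rev(pars$mu), sigma = rev(pars$sigma),
                 beta = pars$beta[2:1, , drop = FALSE])
    theta <- .theta_pack(pars$mu, pars$sigma, pars$beta)
  }
  names(theta) <- .theta_names(colnames(X))
  colnames(pars$beta) <- colnames(X)
  rownames(pars$beta) <- c("1->2", "2->1")

  vc <- NULL
  vcov_ok <- FALSE
  if (hessian) {
    H <- tryCatch(optimHess(theta, nll), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc) && all(is.finite(vc))) {
        vc <- (vc + t(vc)) / 2
        dimnames(vc) <- list(names(theta), names(theta))
        vcov_ok <- all(diag(vc) > 0)
      } else vc <- NULL
    }
  }

  ll <- -best$value
  npar <- length(theta)
  structure(list(mu = setNames(pars$mu, c("inactive", "active")),
                 sigma = setNames(pars$sigma, c("inactive", "active")),
                 beta = pars$beta, theta = theta,
                 loglik = ll, npar = npar, aic = -2 * ll + 2 * npar,
                 vcov = vc, vcov_ok = vcov_ok,
                 spec = spec, signature = attr(X, "signature"),
                 restarts = trace,
                 n_zero_offset = n_zero, zero_offset = zero_offset,
                 nobs = sum(obs), nbursts = length(unique(bkey)),
                 call = match.call()),
            class = "hmm_fit")
}
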