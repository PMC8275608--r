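#' @export
print.hmm_fit <- function(x, digits = 4, ...) {
  cat("Two-state gamma step-length HMM\n")
  em <- rbind(mean = x$mu, sd = x$sigma)
  colnames(em) <- c("inactive (1)", "active (2)")
  print(round(em, digits))
  if (!is.na(x$loglik)) {
    cat("\nlog-likelihood:", format(x$loglik, digits = 10),
        "  AIC:", format(x$aic, digits = 10),
        "  parameters:", x$npar, "\n")
    cat("observed steps:", x$nobs, " bursts:", x$nbursts, "\n")
    if (x$n_zero_offset > 0)
      cat("zero steps offset to", format(x$zero_offset, digits = 3),
          "m:", x$n_zero_offset, "\n")
  } else {
    cat("\n(parameters supplied, not estimated)\n")
  }
  invisible(x)
}

#' @export
coef.hmm_fit <- function(object, ...) {
  list(mu = object$mu, sigma = object$sigma, beta = object$beta)
}

#' @export
logLik.hmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$nobs,
            class = "logLik")
}

#' @export
vcov.hmm_fit <- function(object, ...) {
  if (!object$vcov_ok)
    warning("covariance unavailable (singular or missing Hessian)")
  object$vcov
}

#' @export
summary.hmm_fit <- function(object, ...) {
  p <- ncol(object$beta)
  out <- list(fit = object)
  if (object$vcov_ok) {
    se <- sqrt(diag(object$vcov))
    # delta method for the natural-scale emission parameters
    out$emission <- data.frame(
      estimate = c(object$mu, object$sigma),
      se = c(object$mu, object$sigma) * se[1:4],
      row.names = c("mu[inactive]", "mu[active]",
                    "sigma[inactive]", "sigma[active]"))
    bse <- matrix(se[-(1:4)], 2, p, byrow = TRUE)
    z <- object$beta / bse
    out$beta <- data.frame(
      transition = rep(rownames(object$beta), each = p),
      term = rep(colnames(object$beta), 2),
      estimate = c(t(object$beta)), se = c(t(bse)), z = c(t(z)),
      p_value = 2 * pnorm(-abs(c(t(z)))))
  }
  class(out) <- "summary.hmm_fit"
  out
}

#' @export
print.summary.hmm_fit <- function(x, digits = 4, ...) {
  print(x$fit)
  if (!is.null(x$beta)) {
    cat("\nEmission parameters (natural scale):\n")
    print(round(x$emission, digits))
    cat("\nTransition coefficients (logit scale):\n")
    b <- x$beta
    b[, 3:6] <- round(b[, 3:6], digits)
    print(b, row.names = FALSE)
  }
  invisible(x)
}

#' Predicted stationary activity probability
#'
#' For each row of `newdata`, computes the stationary probability of the
#' active state under the transition matrix at that covariate
#' configuration. This is the model's "state occupancy probability".
#'
#' @param object An `hmm_fit`.
#' @param newdata Data frame with the spec's covariate columns.
#' @param ... Unused.
#' @return Numeric vector of active-state probabilities.
#' @export
predict.hmm_fit <- function(object, newdata, ...) {
  X <- hmm_design(object$spec, newdata)
  if (!identical(attr(X, "signature"), object$signature))
    stop("design signature of 'newdata' does not match the fit")
  tp <- .trans_probs(object$beta, X)
  tp$g12 / (tp$g12 + tp$g21)
}

# Markov chain simulation given vectorized transition probabilities;
# each burst starts from the stationary distribution at its first row
.sim_states <- function(g12, g21, bkey) {
  n <- length(g12)
  s <- integer(n)
  for (t in seq_len(n)) {
    if (t == 1 || bkey[t] != bkey[t - 1]) {
      p2 <- g12[t] / (g12[t] + g21[t])
      s[t] <- 1L + (runif(1) < p2)
    } else if (s[t - 1] == 1L) {
      s[t] <- 1L + (runif(1) < g12[t])
    } else {
      s[t] <- 2L - (runif(1) < g21[t])
    }
  }
  s
}

#' Simulate step lengths and states from a fitted HMM
#'
#' Draws a state sequence from the covariate-dependent Markov chain (each
#' burst initialized at its stationary distribution) and gamma step lengths
#' conditional on the states, at the covariate rows of `newdata`.
#'
#' @param object An `hmm_fit`.
#' @param nsim Number of replicate simulations.
#' @param seed Optional seed.
#' @param newdata Burst table providing `id`, `burst` and covariates.
#' @param ... Unused.
#' @return For `nsim = 1`, a data frame with columns `state` and `step_m`
#'   aligned to `newdata`; otherwise a list of such frames.
#' @export
simulate.hmm_fit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata$id)) newdata$id <- "1"
  if (is.null(newdata$burst)) newdata$burst <- 1L
  X <- hmm_design(object$spec, newdata)
  if (!identical(attr(X, "signature"), object$signature))
    stop("design signature of 'newdata' does not match the fit")
  tp <- .trans_probs(object$beta, X)
  bkey <- .burst_key(newdata)
  one <- function() {
    s <- .sim_states(tp$g12, tp$g21, bkey)
    data.frame(state = s,
               step_m = rgamma_meansd(length(s), object$mu[s],
                                      object$sigma[s]))
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @rdname pseudo_residuals
#' @param object An `hmm_fit`.
#' @param ... Unused.
#' @export
residuals.hmm_fit <- function(object, data, ...) {
  pseudo_residuals(object, data)
}

#' Diagnostic plots for a fitted HMM
#'
#' `which = 1` overlays the fitted marginal step-length mixture (weighted by
#' the time-averaged stationary state probabilities) on the empirical step
#' histogram; `which = 2` shows a normal Q-Q plot of the forecast
#' pseudo-residuals; `which = 3` their autocorrelation function.
#'
#' @param x An `hmm_fit`.
#' @param data Burst table used for the fit.
#' @param which Which plot(s) to draw.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.hmm_fit <- function(x, data, which = 1, ...) {
  if (1 %in% which) {
    mf <- marginal_fit(x, data, n_bins = 40)
    tab <- mf$table
    width <- tab$upper - tab$lower
    graphics::plot(tab$mid, tab$empirical / width,
                   type = "h", col = "grey60", lwd = 3,
                   xlab = "step length (m)", ylab = "density", ...)
    graphics::lines(tab$mid, tab$model / width, col = 2, lwd = 2)
    graphics::legend("topright", legend = c("empirical", "fitted mixture"),
                     col = c("grey60", 2), lwd = 2, bty = "n")
  }
  if (any(c(2, 3) %in% which)) {
    z <- pseudo_residuals(x, data)
    z <- z[is.finite(z)]
    if (2 %in% which) {
      stats::qqnorm(z, main = "Forecast pseudo-residuals")
      stats::qqline(z)
    }
    if (3 %in% which) acf(z, main = "Pseudo-residual ACF")
  }
  invisible(x)
}
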