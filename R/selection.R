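#' AIC covariate-exclusion ladder
#'
#' Ranks covariate relevance by refitting the HMM with each covariate's
#' terms removed and recording the AIC increase over the full model. For
#' every non-colony covariate two reduced models are fitted: one dropping
#' only its colony-interaction columns, and one dropping the main effect
#' and the interaction; for colony itself, the colony main effect and
#' every interaction column are dropped. Reduced fits are warm-started
#' from the full fit's surviving coefficients (plus fresh random
#' restarts), which enforces the nesting inequality in practice.
#'
#' A covariate is flagged relevant when its largest exclusion `dAIC`
#' reaches `threshold`; the threshold is a reporting convention, not a
#' model choice — inference stays with the full model.
#'
#' @param data Burst table (see [fit_hmm()]).
#' @param spec Full-model [hmm_spec()] (must include colony interactions
#'   for interaction rows to exist).
#' @param threshold Relevance threshold on `dAIC` (default 40).
#' @param n_restarts Random restarts per reduced fit (in addition to the
#'   warm start).
#' @param seed Optional seed (restart perturbations).
#' @param full_fit Optional precomputed full-model fit.
#' @return Data frame of class `selection_table`: `covariate`, `exclude`,
#'   `npar`, `loglik`, `AIC`, `dAIC`, `relevant`, `converged`. The full
#'   model is the first row with `dAIC = 0`. The full fit is attached as
#'   attribute `full_fit`.
#' @export
exclusion_ladder <- function(data, spec, threshold = 40, n_restarts = 5,
                             seed = NULL, full_fit = NULL) {
  stopifnot(inherits(spec, "hmm_spec"))
  if (is.null(full_fit))
    full_fit <- fit_hmm(data, spec, n_restarts = max(n_restarts, 5),
                        seed = seed, hessian = FALSE)
  rows <- data.frame(covariate = "(full model)", exclude = "",
                     npar = full_fit$npar, loglik = full_fit$loglik,
                     AIC = full_fit$aic, dAIC = 0, relevant = NA,
                     converged = TRUE)
  covs <- setdiff(spec$covariates, "colony")

  reduced_fit <- function(rspec) {
    cols <- .spec_colnames(rspec)
    warm <- list(mu = full_fit$mu, sigma = full_fit$sigma,
                 beta = full_fit$beta[, cols, drop = FALSE])
    tryCatch(fit_hmm(data, rspec, n_restarts = n_restarts, seed = seed,
                     warm_start = warm, hessian = FALSE),
             error = function(e) NULL)
  }
  add_row <- function(covariate, exclude, fit) {
    rows <<- rbind(rows, data.frame(
      covariate = covariate, exclude = exclude,
      npar = if (is.null(fit)) NA else fit$npar,
      loglik = if (is.null(fit)) NA else fit$loglik,
      AIC = if (is.null(fit)) NA else fit$aic,
      dAIC = if (is.null(fit)) NA else fit$aic - full_fit$aic,
      relevant = NA, converged = !is.null(fit)))
  }

  for (cv in covs) {
    if (cv %in% spec$interact) {
      rspec <- hmm_spec(spec$covariates, setdiff(spec$interact, cv),
                        spec$harmonics)
      add_row(cv, "interaction with colony", reduced_fit(rspec))
    }
    rspec <- hmm_spec(setdiff(spec$covariates, cv),
                      setdiff(spec$interact, cv), spec$harmonics)
    add_row(cv, "all terms", reduced_fit(rspec))
  }
  if ("colony" %in% spec$covariates || length(spec$interact)) {
    rspec <- hmm_spec(setdiff(spec$covariates, "colony"), character(0),
                      spec$harmonics)
    add_row("colony", "all terms", reduced_fit(rspec))
  }

  for (cv in unique(rows$covariate[-1])) {
    i <- rows$covariate == cv
    rows$relevant[i] <- isTRUE(max(rows$dAIC[i], na.rm = TRUE) >= threshold)
  }
  attr(rows, "threshold") <- threshold
  attr(rows, "full_fit") <- full_fit
  class(rows) <- c("selection_table", "data.frame")
  rows
}

#' @export
print.selection_table <- function(x, digits = 1, ...) {
  cat("Covariate-exclusion AIC ladder (relevance threshold dAIC >= ",
      attr(x, "threshold"), ")\n\n", sep = "")
  d <- as.data.frame(x)
  d$loglik <- round(d$loglik, 1)
  d$AIC <- round(d$AIC, 1)
  d$dAIC <- round(d$dAIC, digits)
  print(d, row.names = FALSE)
  invisible(x)
}
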