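#' Random-intercept logistic regression on decoded states
#'
#' Fits `state ~ predictor + (1 | group)` with a binomial error
#' distribution and a single normal random intercept per individual,
#' integrated by adaptive Gauss-Hermite quadrature (15 nodes by default;
#' `nagq = 1` is the Laplace approximation). Used post-hoc to test whether
#' maternal attendance or survival status explains variation in the
#' decoded activity states.
#'
#' @param response Binary response per observation (0 = inactive,
#'   1 = active), or a decoded state vector in 1/2 coding (detected and
#'   recoded).
#' @param predictor Binary predictor per observation (e.g. attendance:
#'   0 = mother present ashore, 1 = absent; survival: 0 = died,
#'   1 = survived, constant within individual).
#' @param group Individual identifier per observation (random intercept).
#' @param nagq Number of adaptive Gauss-Hermite quadrature nodes.
#' @return Object of class `glmm_result`: `estimate` (fixed-effect slope,
#'   log-odds), `se`, `z`, `p_value`, `intercept`, `re_sd`, `n_obs`,
#'   `n_groups`, and the underlying `lme4` model as `model`.
#' @export
glmm_logistic <- function(response, predictor, group, nagq = 15) {
  ok <- !is.na(response) & !is.na(predictor) & !is.na(group)
  y <- response[ok]
  if (all(y %in% c(1, 2))) y <- y - 1
  stopifnot(all(y %in% 0:1))
  x <- predictor[ok]
  g <- factor(group[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups for a random intercept")
  if (length(unique(x)) < 2) stop("predictor is constant")
  tab <- table(factor(x), factor(y, levels = 0:1))
  if (nrow(tab) == 2 && ((tab[1, 2] == 0 && tab[2, 1] == 0) ||
                         (tab[1, 1] == 0 && tab[2, 2] == 0)))
    stop("complete separation: the predictor perfectly classifies the response")
  d <- data.frame(y = y, x = x, g = g)
  m <- lme4::glmer(y ~ x + (1 | g), data = d, family = stats::binomial(),
                   nAGQ = nagq)
  cf <- summary(m)$coefficients
  structure(list(estimate = cf["x", "Estimate"],
                 se = cf["x", "Std. Error"],
                 z = cf["x", "z value"],
                 p_value = cf["x", "Pr(>|z|)"],
                 intercept = cf["(Intercept)", "Estimate"],
                 re_sd = sqrt(unname(lme4::VarCorr(m)$g[1])),
                 n_obs = nrow(d), n_groups = nlevels(g), model = m),
            class = "glmm_result")
}

#' @export
print.glmm_result <- function(x, digits = 3, ...) {
  cat("Binomial GLMM with random intercept (", x$n_obs, " obs, ",
      x$n_groups, " groups)\n", sep = "")
  cat("  slope:", round(x$estimate, digits), " s.e.:", round(x$se, digits),
      " z:", round(x$z, 2), " p:", format.pval(x$p_value, digits), "\n")
  cat("  intercept:", round(x$intercept, digits),
      " random-intercept sd:", round(x$re_sd, digits), "\n")
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided rank-sum test (e.g. per-pup mean natal-colony displacement,
#' reference colony vs the other): exact enumeration for small samples
#' without ties, otherwise the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `statistic` (W), `p_value`, and `method`.
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  exact <- length(a) * length(b) <= 10000 &&
    !any(duplicated(c(a, b)))
  wt <- wilcox.test(a, b, exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}

#' Dispersion check for a binomial GLMM by simulation envelope
#'
#' Compares the observed Pearson-residual dispersion ratio with the
#' distribution of the same ratio under data simulated from the fitted
#' model — a lightweight residual diagnostic for over/under-dispersion.
#'
#' @param result A [glmm_logistic()] result.
#' @param n_sim Number of simulated replicates.
#' @param seed Optional seed.
#' @return List with `ratio` (observed), `sim_quantiles` (2.5/50/97.5% of
#'   the simulated ratios) and `p_value` (two-sided simulation p).
#' @export
dispersion_check <- function(result, n_sim = 500, seed = NULL) {
  stopifnot(inherits(result, "glmm_result"))
  if (!is.null(seed)) set.seed(seed)
  m <- result$model
  pr <- stats::residuals(m, type = "pearson")
  ratio <- sum(pr^2) / stats::df.residual(m)
  # condition on the fitted random effects so the envelope matches the
  # fitted means used in the Pearson residuals
  ys <- stats::simulate(m, nsim = n_sim, use.u = TRUE)
  sims <- vapply(ys, function(y) {
    mu <- stats::fitted(m)
    sum(((y - mu) / sqrt(mu * (1 - mu)))^2) / stats::df.residual(m)
  }, 0)
  p <- mean(abs(sims - stats::median(sims)) >= abs(ratio - stats::median(sims)))
  list(ratio = ratio, sim_quantiles = quantile(sims, c(0.025, 0.5, 0.975)),
       p_value = p)
}

#' Join daily maternal attendance to hourly decoded states
#'
#' Attendance is recorded once per day; every step on that calendar day
#' inherits the day's value.
#'
#' @param decoded Output of [viterbi()] (needs `id`, `timestamp`).
#' @param attendance Data frame `id`, `date`, `mother_present` (0/1).
#' @return `decoded` with a `mother_present` column (`NA` where no
#'   attendance record exists).
#' @export
attendance_join <- function(decoded, attendance) {
  key <- paste(attendance$id, as.Date(attendance$date))
  i <- match(paste(decoded$id, as.Date(decoded$timestamp, tz = "UTC")), key)
  decoded$mother_present <- attendance$mother_present[i]
  decoded
}

#' Post-hoc report: attendance and survival GLMMs plus group summaries
#'
#' Runs the two post-hoc random-intercept logistic regressions on the
#' decoded states — activity vs maternal absence (individuals with
#' attendance data) and activity vs survival status — along with the
#' per-group active/inactive proportions behind them.
#'
#' @param decoded Output of [viterbi()].
#' @param attendance Daily attendance table (may cover a subset of
#'   individuals).
#' @param metadata Metadata with `id` and `fate`
#'   (`"survived"`/`"died"`).
#' @param nagq Quadrature nodes for [glmm_logistic()].
#' @return List with `attendance` and `survival` (each a `glmm_result`)
#'   and `proportions` (active fraction per predictor group).
#' @export
posthoc_report <- function(decoded, attendance, metadata, nagq = 15) {
  d <- decoded[decoded$observed, , drop = FALSE]
  d <- attendance_join(d, attendance)
  act <- d$state - 1

  att <- NULL
  ai <- !is.na(d$mother_present)
  if (any(ai)) {
    absent <- 1 - d$mother_present[ai]
    att <- glmm_logistic(act[ai], absent, d$id[ai], nagq = nagq)
  }
  surv <- as.numeric(metadata$fate[match(d$id, metadata$id)] == "survived")
  sv <- glmm_logistic(act, surv, d$id, nagq = nagq)

  props <- data.frame(
    group = c("mother present", "mother absent", "died", "survived"),
    active_proportion = c(
      mean(act[ai][d$mother_present[ai] == 1]),
      mean(act[ai][d$mother_present[ai] == 0]),
      mean(act[surv == 0]), mean(act[surv == 1])),
    n_obs = c(sum(d$mother_present[ai] == 1), sum(d$mother_present[ai] == 0),
              sum(surv == 0), sum(surv == 1)))
  list(attendance = att, survival = sv, proportions = props)
}
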