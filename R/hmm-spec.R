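#' Define a two-state step-length HMM with covariate-dependent transitions
#'
#' Specifies the model that [fit_hmm()] estimates: gamma step-length
#' emissions conditional on two behavioural states ("inactive" = state 1,
#' "active" = state 2) and a Markov state sequence whose off-diagonal
#' transition probabilities are logistic functions of covariates. Each
#' off-diagonal logit (1 to 2, and 2 to 1) receives the same design, with a
#' row of coefficients per transition.
#'
#' The special covariate name `"hour"` expands into `harmonics` pairs of
#' trigonometric columns `sin(2*pi*k*hour/24)`, `cos(2*pi*k*hour/24)`,
#' capturing periodic time-of-day effects. Covariates listed in `interact`
#' additionally enter multiplied by the binary `colony` indicator, so their
#' effect may differ between the reference colony (0) and the other colony
#' (1); the colony main effect is then included automatically.
#'
#' @param covariates Character vector of covariate column names expected in
#'   the burst table (e.g. `"age_z"`, `"temp_z"`, `"sex"`, `"year"`,
#'   `"colony"`, `"hour"`). Metric covariates are expected standardized.
#' @param interact Character vector (subset of `covariates`, excluding
#'   `"colony"`) whose terms also get colony-interaction columns. Defaults
#'   to all non-colony covariates.
#' @param harmonics Number of sine/cosine pairs for the `"hour"` expansion.
#' @param n_states Number of states; only 2 is supported by the fitting and
#'   decoding routines.
#' @return An object of class `hmm_spec`.
#' @seealso [hmm_design()], [fit_hmm()]
#' @export
hmm_spec <- function(covariates = character(),
                     interact = setdiff(covariates, "colony"),
                     harmonics = 1L, n_states = 2L) {
  covariates <- as.character(covariates)
  interact <- as.character(interact)
  if (length(setdiff(interact, covariates)))
    stop("'interact' must be a subset of 'covariates'")
  if ("colony" %in% interact)
    stop("'colony' cannot interact with itself")
  if (length(interact) && !"colony" %in% covariates)
    covariates <- c(covariates, "colony")
  harmonics <- as.integer(harmonics)
  if ("hour" %in% covariates && harmonics < 1L)
    stop("'harmonics' must be >= 1 when 'hour' is included")
  if (n_states != 2L)
    stop("only the two-state model is supported")
  structure(list(covariates = covariates, interact = interact,
                 harmonics = harmonics, n_states = 2L),
            class = "hmm_spec")
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat("Two-state gamma step-length HMM specification\n")
  cat("  transition covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(intercept only)", "\n")
  if (length(x$interact))
    cat("  colony interactions:  ", paste(x$interact, collapse = ", "), "\n")
  if ("hour" %in% x$covariates)
    cat("  time-of-day harmonics:", x$harmonics, "\n")
  invisible(x)
}

# expand one covariate name into its design column(s)
.term_columns <- function(name, data, harmonics) {
  if (name == "hour") {
    h <- data[["hour"]]
    if (is.null(h)) stop("column 'hour' not found in data")
    out <- NULL
    for (k in seq_len(harmonics)) {
      out <- cbind(out, sin(2 * pi * k * h / 24), cos(2 * pi * k * h / 24))
    }
    colnames(out) <- as.vector(rbind(paste0("sin", seq_len(harmonics)),
                                     paste0("cos", seq_len(harmonics))))
    out
  } else {
    v <- data[[name]]
    if (is.null(v)) stop("column '", name, "' not found in data")
    out <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, name))
    out
  }
}

#' Build the transition design matrix for an HMM specification
#'
#' Expands the covariates of an [hmm_spec()] into the numeric design matrix
#' used for both off-diagonal transition logits: an intercept, main-effect
#' columns (with `"hour"` expanded into harmonics), and colony-interaction
#' columns for the terms listed in the spec's `interact`.
#'
#' @param spec An [hmm_spec()].
#' @param data Data frame of per-step covariates (one row per step).
#' @return Numeric matrix with one row per row of `data`; the column-name
#'   signature is attached as attribute `"signature"` and a per-covariate
#'   column map as attribute `"terms"` (used by the exclusion ladder).
#' @export
hmm_design <- function(spec, data) {
  stopifnot(inherits(spec, "hmm_spec"))
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  terms <- list()
  for (nm in spec$covariates) {
    cols <- .term_columns(nm, data, spec$harmonics)
    terms[[nm]] <- list(main = ncol(X) + seq_len(ncol(cols)),
                        inter = integer(0))
    X <- cbind(X, cols)
  }
  if (length(spec$interact)) {
    colony <- as.numeric(data[["colony"]])
    for (nm in spec$interact) {
      cols <- .term_columns(nm, data, spec$harmonics) * colony
      colnames(cols) <- paste0(colnames(cols), ":colony")
      terms[[nm]]$inter <- ncol(X) + seq_len(ncol(cols))
      X <- cbind(X, cols)
    }
  }
  if (anyNA(X)) stop("missing values in transition covariates")
  attr(X, "signature") <- paste(colnames(X), collapse = "|")
  attr(X, "terms") <- terms
  X
}

#' Transition probability matrix at one covariate configuration
#'
#' Maps transition coefficients and a design row to the 2x2 row-stochastic
#' transition matrix via the logit link: the off-diagonal probabilities are
#' `plogis(beta[1,] %*% x)` (1 to 2) and `plogis(beta[2,] %*% x)` (2 to 1),
#' and the diagonal holds the complements (a row-wise multinomial logit with
#' "stay" as reference, which reduces to logistic for two states).
#'
#' @param beta Coefficient matrix with 2 rows (transitions 1->2 and 2->1)
#'   and one column per design column.
#' @param x Numeric design row (same length as `ncol(beta)`).
#' @return 2x2 transition probability matrix.
#' @export
transition_matrix <- function(beta, x) {
  beta <- rbind(beta)
  x <- as.numeric(x)
  if (ncol(beta) != length(x))
    stop("design row length (", length(x),
         ") does not match beta columns (", ncol(beta), ")")
  g12 <- plogis(sum(beta[1, ] * x))
  g21 <- plogis(sum(beta[2, ] * x))
  matrix(c(1 - g12, g21, g12, 1 - g21), 2, 2,
         dimnames = list(c("1", "2"), c("1", "2")))
}

# vectorized off-diagonal transition probabilities for a design matrix
.trans_probs <- function(beta, X) {
  list(g12 = plogis(drop(X %*% beta[1, ])),
       g21 = plogis(drop(X %*% beta[2, ])))
}

#' Stationary distribution of a 2x2 transition matrix
#'
#' For off-diagonal probabilities `g12`, `g21` the stationary (equilibrium)
#' distribution is `(g21, g12) / (g12 + g21)`. Used as the initial state
#' distribution of each burst and as the "state occupancy probability" when
#' expressing covariate effects on activity.
#'
#' @param Gamma 2x2 row-stochastic matrix.
#' @return Length-2 probability vector `pi` with `pi %*% Gamma = pi`.
#' @export
stationary_distribution <- function(Gamma) {
  g12 <- Gamma[1, 2]
  g21 <- Gamma[2, 1]
  if (g12 + g21 <= 0)
    stop("chain has no switching (g12 + g21 = 0); stationary distribution undefined")
  c(g21, g12) / (g12 + g21)
}

#' Gamma density in the mean / standard-deviation parametrization
#'
#' The step-length emission distribution: a gamma with shape
#' `mean^2 / sd^2` and rate `mean / sd^2`.
#'
#' @param x Quantiles (step lengths, metres).
#' @param mean,sd Positive mean and standard deviation, metres.
#' @param log Return the log density?
#' @return Density (or log density) values.
#' @export
dgamma_meansd <- function(x, mean, sd, log = FALSE) {
  if (any(mean <= 0) || any(sd <= 0))
    stop("'mean' and 'sd' must be strictly positive")
  dgamma(x, shape = mean^2 / sd^2, rate = mean / sd^2, log = log)
}

#' @rdname dgamma_meansd
#' @param q Quantiles.
#' @export
pgamma_meansd <- function(q, mean, sd) {
  if (any(mean <= 0) || any(sd <= 0))
    stop("'mean' and 'sd' must be strictly positive")
  pgamma(q, shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' @rdname dgamma_meansd
#' @param n Number of draws.
#' @export
rgamma_meansd <- function(n, mean, sd) {
  if (any(mean <= 0) || any(sd <= 0))
    stop("'mean' and 'sd' must be strictly positive")
  rgamma(n, shape = mean^2 / sd^2, rate = mean / sd^2)
}
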