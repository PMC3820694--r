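#' Construct a set of ensemble-averaged distance restraints
#'
#' A `restraint_set` holds the experimental data of the hierarchical model:
#' atom-pair indices (0-based into the chain), the observed averaged distances
#' `d` (Angstrom), the per-restraint log-scale uncertainty `sigma`, and the
#' averaging type that produced `d` (arithmetic mean of distances, or the
#' NOE-style power average \eqn{\langle r^{-k}\rangle^{-1/k}}).
#'
#' @param pairs two-column integer matrix (or list of length-2 vectors) of
#'   0-based bead indices; indices within a pair must differ.
#' @param d positive numeric vector of observed averaged distances (Angstrom).
#' @param sigma positive numeric vector of log-scale uncertainties, recycled
#'   to the number of restraints.
#' @param averaging `"linear"` or `"power"`.
#' @param k positive integer exponent of the power average (default 6,
#'   the NOE scaling).
#' @return an object of class `restraint_set` with fields `pairs`, `d`,
#'   `sigma`, `averaging`, `k`.
#' @export
restraint_set <- function(pairs, d, sigma, averaging = c("linear", "power"),
                          k = 6L) {
  averaging <- match.arg(averaging)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  m <- nrow(pairs)
  if (m < 1L) stop("a restraint set must contain at least one restraint")
  d <- as.numeric(d)
  sigma <- rep_len(as.numeric(sigma), m)
  if (length(d) != m) stop("length of 'd' must match the number of pairs")
  if (any(!is.finite(d)) || any(d <= 0))
    stop("restraint ", which(!(is.finite(d) & d > 0))[1L],
         ": observed distance must be positive and finite")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("restraint ", which(!(is.finite(sigma) & sigma > 0))[1L],
         ": sigma must be positive and finite")
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("restraint ", which(pairs[, 1L] == pairs[, 2L])[1L],
         ": pair indices must be distinct")
  if (any(pairs < 0L))
    stop("pair indices are 0-based and must be non-negative")
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be a positive integer")
  structure(list(pairs = pairs, d = d, sigma = sigma,
                 averaging = averaging, k = k),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint_set: %d %s-averaged distance restraints (k = %d)\n",
              nrow(x$pairs), x$averaging, x$k))
  print(data.frame(i = x$pairs[, 1L], j = x$pairs[, 2L],
                   d = x$d, sigma = signif(x$sigma, 4L)))
  invisible(x)
}

#' @export
length.restraint_set <- function(x) nrow(x$pairs)

#' Reference distribution over the coarse-grained observable
#'
#' The distribution induced on X by the fine-grained prior alone, used in the
#' denominator of the reference ratio. Either `"uniform"` (a constant,
#' absorbed into the normalization) or a product of independent exponentials
#' with means `beta` (the moment approximation estimated by
#' [estimate_reference()]).
#'
#' @param kind `"uniform"` or `"exponential"`.
#' @param beta positive numeric vector of exponential means, one per
#'   restraint; required for `kind = "exponential"`.
#' @param beta_se optional Monte-Carlo standard errors of `beta`.
#' @return an object of class `reference_model`.
#' @export
reference_model <- function(kind = c("uniform", "exponential"), beta = NULL,
                            beta_se = NULL) {
  kind <- match.arg(kind)
  if (kind == "exponential") {
    if (is.null(beta)) stop("an exponential reference requires 'beta'")
    beta <- as.numeric(beta)
    if (any(!is.finite(beta)) || any(beta <= 0))
      stop("all exponential reference means must be positive and finite")
  } else {
    beta <- NULL
  }
  structure(list(kind = kind, beta = beta, beta_se = beta_se),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  if (x$kind == "uniform") {
    cat("reference_model: uniform\n")
  } else {
    cat("reference_model: product of exponentials, means:\n")
    print(signif(x$beta, 4L))
  }
  invisible(x)
}

#' Posterior mode of the hierarchical model
#'
#' Selects which posterior the sampler targets: `"full"` is the hierarchical
#' model with the auxiliary ensemble average Y, the exponential conditional
#' p(X|Y) scaled by lambda, the Jeffreys prior on Y, and the reference-ratio
#' correction; `"isd"` collapses Y onto X (a Dirac conditional with a uniform
#' Y-prior), recovering inferential structure determination of a single
#' structure; `"maxent"` is the maximum-entropy restrained-simulation energy
#' with a diagonal matrix of Lagrange multipliers and a normal error model
#' whose width `noise_sd` can be taken to zero.
#'
#' @param mode `"full"`, `"isd"` or `"maxent"`.
#' @param lagrange numeric vector of Lagrange multipliers (maxent only).
#' @param noise_sd positive scalar width of the maxent normal error model.
#' @return an object of class `model_mode`.
#' @export
model_mode <- function(mode = c("full", "isd", "maxent"), lagrange = NULL,
                       noise_sd = NULL) {
  mode <- match.arg(mode)
  if (mode == "maxent") {
    if (is.null(lagrange) || any(!is.finite(lagrange)))
      stop("maxent mode requires finite Lagrange multipliers")
    if (is.null(noise_sd) || !is.finite(noise_sd) || noise_sd <= 0)
      stop("maxent mode requires a positive 'noise_sd'")
    lagrange <- as.numeric(lagrange)
  } else {
    lagrange <- NULL
    noise_sd <- NULL
  }
  structure(list(mode = mode, lagrange = lagrange, noise_sd = noise_sd),
            class = "model_mode")
}

.check_positive <- function(x, what) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop(what, ": value at restraint index ", bad[1L],
         " must be positive and finite", call. = FALSE)
  invisible(TRUE)
}

#' Log-normal log-likelihood of observed averaged distances
#'
#' The error model for NOE-derived distances: each observation `d[i]` is
#' log-normally distributed about the predicted observable `y_pred[i]` with
#' log-scale standard deviation `sigma[i]`. Normalization constants are
#' retained.
#'
#' @param d observed distances (Angstrom), positive.
#' @param y_pred predicted observables on the same Angstrom scale, positive.
#' @param sigma log-scale standard deviations, positive.
#' @return scalar log-likelihood, `sum(dlnorm(d, log(y_pred), sigma, log = TRUE))`.
#' @export
loglik_lognormal <- function(d, y_pred, sigma) {
  stopifnot(length(d) == length(y_pred), length(d) == length(sigma))
  .check_positive(d, "loglik_lognormal 'd'")
  .check_positive(y_pred, "loglik_lognormal 'y_pred'")
  .check_positive(sigma, "loglik_lognormal 'sigma'")
  sum(stats::dnorm(log(d), log(y_pred), sigma, log = TRUE) - log(d))
}

#' Log-density of the exponential conditional p(X | Y)
#'
#' X given the ensemble average Y is exponential with mean `lam * y` — the
#' least biasing continuous distribution on the positive real axis given a
#' mean. The scale vector `lam` compensates for the approximate reference
#' distribution.
#'
#' @param x_cg instantaneous coarse-grained observables, positive.
#' @param y ensemble averages, positive, same space as `x_cg`.
#' @param lam positive scale vector.
#' @return scalar log-density `sum(-log(lam*y) - x/(lam*y))`.
#' @export
logprior_x_given_y <- function(x_cg, y, lam) {
  stopifnot(length(x_cg) == length(y), length(x_cg) == length(lam))
  .check_positive(x_cg, "logprior_x_given_y 'x_cg'")
  .check_positive(y, "logprior_x_given_y 'y'")
  .check_positive(lam, "logprior_x_given_y 'lam'")
  mu <- lam * y
  sum(-log(mu) - x_cg / mu)
}

#' Jeffreys-type log-prior on the ensemble average
#'
#' Scale-invariant prior density proportional to 1/Y for the positive
#' auxiliary ensemble average; improper, with posterior propriety supplied by
#' the likelihood.
#'
#' @param y positive numeric vector.
#' @return scalar `sum(-log(y))` (up to an additive constant).
#' @export
logprior_y <- function(y) {
  .check_positive(y, "logprior_y 'y'")
  -sum(log(y))
}

#' Log-density of the reference distribution at X
#'
#' @param x_cg coarse-grained observables, positive.
#' @param ref a [reference_model()].
#' @return 0 for a uniform reference; `sum(-log(beta) - x/beta)` for the
#'   exponential reference.
#' @export
log_reference <- function(x_cg, ref) {
  if (!inherits(ref, "reference_model")) stop("'ref' must be a reference_model")
  .check_positive(x_cg, "log_reference 'x_cg'")
  if (ref$kind == "uniform") return(0)
  if (is.null(ref$beta)) stop("exponential reference has no 'beta'")
  if (length(ref$beta) != length(x_cg))
    stop("reference dimension does not match the observable")
  sum(-log(ref$beta) - x_cg / ref$beta)
}

#' Map a coarse-grained vector back to the Angstrom observable scale
#'
#' Linear averaging leaves distances untouched; inverse-power coarse graining
#' stores \eqn{r^{-k}}, so the comparable observable is \eqn{v^{-1/k}} —
#' applied to the ensemble average Y this realises the power average
#' \eqn{\langle r^{-k}\rangle^{-1/k}}.
#'
#' @param v positive values in coarse-grained space.
#' @param averaging `"linear"` or `"power"`.
#' @param k positive integer power-average exponent.
#' @return positive values on the Angstrom scale.
#' @export
predict_observable <- function(v, averaging = c("linear", "power"), k = 6L) {
  averaging <- match.arg(averaging)
  .check_positive(v, "predict_observable 'v'")
  if (averaging == "linear") return(v)
  if (k < 1L) stop("'k' must be a positive integer")
  v^(-1 / k)
}

#' Joint log-posterior of the hierarchical ensemble model
#'
#' Composes the model densities into the (unnormalized) log-posterior of one
#' conformation and the auxiliary ensemble average, according to `mode`:
#'
#' * `full`: log-normal likelihood of `d` given the back-transformed Y,
#'   plus the exponential conditional p(X|Y), the Jeffreys prior on Y,
#'   minus the reference density at X (the reference ratio), plus the
#'   fine-grained conformational log-prior.
#' * `isd`: the likelihood evaluated directly at the back-transformed X plus
#'   the conformational log-prior (Y collapsed onto X, uniform reference).
#' * `maxent`: normal misfit of `d` against Y plus the Lagrange-linear term
#'   in X plus the conformational log-prior.
#'
#' Normalization constants are retained so reductions between modes can be
#' checked without constant chasing.
#'
#' @param x_logprior fine-grained conformational log-prior ln p(x), may be
#'   `-Inf` for clashing conformations.
#' @param x_cg coarse-grained observables f(x), positive.
#' @param y ensemble average (ignored in `isd` mode; may be `NULL` there).
#' @param restraints a [restraint_set()].
#' @param lam positive scale vector (full mode).
#' @param ref a [reference_model()] (full mode).
#' @param mode a [model_mode()].
#' @param coarse_k inverse-power exponent of the space `x_cg` and `y` live
#'   in (power averaging only); defaults to the restraint set's averaging
#'   exponent. Set to 1 when the coarse variable is the inverse distance
#'   (see [forward_model_for()]).
#' @return scalar log-posterior (may be `-Inf`).
#' @export
log_posterior <- function(x_logprior, x_cg, y, restraints, lam = NULL,
                          ref = NULL, mode = model_mode("full"),
                          coarse_k = NULL) {
  if (is.null(coarse_k)) coarse_k <- restraints$k
  if (!inherits(restraints, "restraint_set"))
    stop("'restraints' must be a restraint_set")
  if (!inherits(mode, "model_mode")) stop("'mode' must be a model_mode")
  if (!is.finite(x_logprior) && x_logprior == -Inf) return(-Inf)
  m <- length(restraints)
  if (length(x_cg) != m) stop("coarse vector length does not match restraints")
  switch(mode$mode,
    full = {
      if (is.null(lam) || is.null(ref))
        stop("full mode requires a scale vector and a reference model")
      if (length(y) != m) stop("'y' length does not match restraints")
      loglik_lognormal(restraints$d,
                       predict_observable(y, restraints$averaging,
                                          coarse_k),
                       restraints$sigma) +
        logprior_x_given_y(x_cg, y, rep_len(lam, m)) +
        logprior_y(y) -
        log_reference(x_cg, ref) +
        x_logprior
    },
    isd = {
      loglik_lognormal(restraints$d,
                       predict_observable(x_cg, restraints$averaging,
                                          coarse_k),
                       restraints$sigma) +
        x_logprior
    },
    maxent = {
      if (length(y) != m) stop("'y' length does not match restraints")
      lag <- rep_len(mode$lagrange, m)
      -0.5 * sum((restraints$d - y)^2) / mode$noise_sd^2 -
        sum(lag * x_cg) +
        x_logprior
    },
    stop("unknown mode"))
}
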