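#' Forward model from conformations to coarse-grained observables
#'
#' A forward model maps a conformation to the M-dimensional instantaneous
#' observable X: either the raw pairwise distances (`"linear"`, Angstrom) or
#' their inverse powers \eqn{r^{-k}} (`"inverse-power"`, Angstrom^-k), the
#' space in which NOE-style power averages are arithmetic means.
#'
#' @param pairs two-column matrix (or list) of 0-based bead index pairs.
#' @param kind `"linear"` or `"inverse-power"`.
#' @param k positive integer exponent (inverse-power only; default 6).
#' @return an object of class `forward_model`.
#' @export
forward_model <- function(pairs, kind = c("linear", "inverse-power"), k = 6L) {
  kind <- match.arg(kind)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("forward model pairs must have distinct indices")
  if (any(pairs < 0L)) stop("pair indices are 0-based and must be >= 0")
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  structure(list(pairs = pairs, kind = kind, k = k), class = "forward_model")
}

#' Forward model matching a restraint set
#'
#' Linear averaging observes plain distances; power averaging observes an
#' inverse power of the distance. By default the coarse-graining exponent
#' equals the restraint set's averaging exponent (X = r^-k, so the ensemble
#' average Y lives in the space where the power mean is arithmetic) — the
#' natural choice for single-structure (ISD) fitting. For the full
#' hierarchical model, `coarse_k` may be set lower: the inverse distance
#' (`coarse_k = 1`) keeps the observable within a narrow bounded band, which
#' the exponential reference distribution approximates well, whereas an
#' r^-6 observable under a hard-sphere prior has a tail so heavy that the
#' exponential reference rewards steric contact catastrophically (the scale
#' vector then cannot compensate; see the vignette).
#'
#' @param restraints a [restraint_set()].
#' @param coarse_k optional inverse-power exponent of the coarse variable,
#'   overriding the restraint set's averaging exponent (power averaging
#'   only; ignored for linear data).
#' @return a [forward_model()].
#' @export
forward_model_for <- function(restraints, coarse_k = NULL) {
  forward_model(restraints$pairs,
                kind = if (restraints$averaging == "power")
                  "inverse-power" else "linear",
                k = if (is.null(coarse_k)) restraints$k else coarse_k)
}

#' Euclidean distances between selected bead pairs
#'
#' @param conf a conformation (n x 3 coordinate matrix, Angstrom).
#' @param pairs two-column matrix of 0-based bead index pairs.
#' @return numeric vector of distances, in pair order.
#' @export
pairwise_distances <- function(conf, pairs) {
  coords <- unclass(conf)
  n <- nrow(coords)
  if (n < 2L) stop("a conformation needs at least two beads")
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs < 0L) || any(pairs >= n))
    stop("pair index out of range for a chain of ", n, " beads")
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("pair indices must be distinct within a pair")
  dxyz <- coords[pairs[, 1L] + 1L, , drop = FALSE] -
    coords[pairs[, 2L] + 1L, , drop = FALSE]
  sqrt(rowSums(dxyz * dxyz))
}

#' Coarse-grain a conformation into the observable space
#'
#' @param conf a conformation.
#' @param fm a [forward_model()].
#' @return positive numeric vector X with attribute `space` set to
#'   `"distance"` or `"inverse-power"`.
#' @export
coarse_grain <- function(conf, fm) {
  r <- pairwise_distances(conf, fm$pairs)
  if (fm$kind == "linear") {
    structure(r, space = "distance")
  } else {
    structure(r^(-fm$k), space = "inverse-power")
  }
}

#' Arithmetic ensemble average of coarse-grained vectors
#'
#' @param ensemble list of equal-length coarse-grained vectors (one space).
#' @return elementwise arithmetic mean, keeping the `space` attribute.
#' @export
linear_average <- function(ensemble) {
  if (length(ensemble) == 0L) stop("cannot average an empty ensemble")
  len <- lengths(ensemble)
  if (any(len != len[1L])) stop("ensemble members differ in length")
  sp <- attr(ensemble[[1L]], "space")
  out <- rowMeans(matrix(unlist(ensemble, use.names = FALSE), nrow = len[1L]))
  structure(out, space = sp)
}

#' NOE-style power average of an ensemble of distances
#'
#' Computes \eqn{(\mathrm{mean}(r^{-k}))^{-1/k}} elementwise; by the
#' power-mean inequality the result never exceeds the arithmetic mean of the
#' same distances.
#'
#' @param distance_ensemble list of equal-length positive distance vectors
#'   (Angstrom).
#' @param k positive integer exponent (default 6).
#' @return positive numeric vector of power-averaged distances (Angstrom).
#' @export
power_average_distance <- function(distance_ensemble, k = 6L) {
  if (length(distance_ensemble) == 0L) stop("cannot average an empty ensemble")
  if (k < 1L) stop("'k' must be >= 1")
  len <- lengths(distance_ensemble)
  if (any(len != len[1L])) stop("ensemble members differ in length")
  mat <- matrix(unlist(distance_ensemble, use.names = FALSE), nrow = len[1L])
  if (any(mat <= 0)) stop("distances must be positive")
  rowMeans(mat^(-k))^(-1 / k)
}
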