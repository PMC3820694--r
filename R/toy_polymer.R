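#' Minimal C-alpha trace polymer model
#'
#' A fine-grained conformational prior p(x) over C-alpha bead chains with
#' fixed virtual bond length, standing in for a trained local-structure
#' prior. The density is defined with respect to the uniform measure on bond
#' directions (the invariant base measure of the rigid-rotation move set) and
#' factorizes over local internal coordinates:
#'
#' * bend angles: a von-Mises-type unimodal term
#'   \eqn{\exp(\kappa \cos(\theta - \mu))} on the interior angle at each bead;
#' * torsions: a mixture of von Mises densities on the virtual dihedral;
#' * a binary clash term: probability zero when any pair of beads at least
#'   three positions apart in sequence is closer than `clash_cutoff`;
#' * optionally a pairwise compaction well (used only for "target" models
#'   that generate synthetic data), adding
#'   \eqn{\mathrm{depth} \sum \exp(-(r_{ij}/\mathrm{range})^2)} over the same
#'   nonbonded pairs.
#'
#' Because the prior is local (angles, torsions, excluded volume only), it
#' does not model long-range distances accurately — exactly the regime the
#' restraint-driven correction must fix.
#'
#' @param n number of beads (>= 3).
#' @param b virtual bond length, Angstrom (default 3.8).
#' @param angle_mu mode of the bend-angle term, radians in (0, pi).
#' @param angle_kappa concentration of the bend-angle term (>= 0).
#' @param angle_min hard lower support bound on bend angles (radians):
#'   interior angles below this are sterically impossible for a C-alpha
#'   trace (intervening-residue excluded volume) and get prior probability
#'   zero. Bounds the distance of sequence-separation-2 pairs away from
#'   zero.
#' @param torsion list with numeric vectors `weights`, `mu`, `kappa`
#'   describing the von Mises mixture on torsions.
#' @param clash_cutoff hard-sphere cutoff (Angstrom) between beads separated
#'   by at least 3 positions; must be smaller than `b`.
#' @param compaction `NULL`, or `list(depth =, range =)` enabling the
#'   pairwise compaction well (depth in units of log-probability per pair,
#'   range in Angstrom).
#' @return an object of class `polymer_model`.
#' @export
polymer_model <- function(n = 14L, b = 3.8,
                          angle_mu = 2.35, angle_kappa = 12.0,
                          angle_min = 1.3,
                          torsion = list(weights = c(0.8, 0.2),
                                         mu = c(3.0, 0.9),
                                         kappa = c(2.0, 2.0)),
                          clash_cutoff = 0.8 * 4.0 * (b / 3.8),
                          compaction = NULL) {
  n <- as.integer(n)
  if (n < 3L) stop("a polymer model needs at least 3 beads")
  if (b <= 0) stop("bond length must be positive")
  if (clash_cutoff >= b) stop("clash cutoff must be smaller than the bond length")
  if (angle_kappa < 0) stop("angle_kappa must be non-negative")
  if (angle_min < 0 || angle_min >= pi)
    stop("angle_min must lie in [0, pi)")
  w <- torsion$weights / sum(torsion$weights)
  stopifnot(length(w) == length(torsion$mu),
            length(w) == length(torsion$kappa),
            all(torsion$kappa >= 0))
  if (!is.null(compaction))
    stopifnot(is.numeric(compaction$depth), is.numeric(compaction$range),
              compaction$range > 0)
  # log-normalizer of the bend-angle term w.r.t. the base measure
  # sin(theta) dtheta / 2, over the truncated support (angle_min, pi)
  za <- stats::integrate(function(th)
    exp(angle_kappa * cos(th - angle_mu)) * sin(th) / 2,
    angle_min, pi, rel.tol = 1e-10)$value
  # nonbonded pair table (1-based, |i - j| >= 3)
  nb <- which(outer(seq_len(n), seq_len(n), function(i, j) j - i >= 3L),
              arr.ind = TRUE)
  structure(list(n = n, b = b, angle_mu = angle_mu,
                 angle_kappa = angle_kappa, angle_min = angle_min,
                 torsion = list(weights = w, mu = torsion$mu,
                                kappa = torsion$kappa,
                                i0 = besselI(torsion$kappa, 0)),
                 clash_cutoff = clash_cutoff, compaction = compaction,
                 log_za = log(za), nb_i = nb[, 1L], nb_j = nb[, 2L],
                 nb_pairs = nb),
            class = "polymer_model")
}

#' @export
print.polymer_model <- function(x, ...) {
  cat(sprintf("polymer_model: %d beads, b = %.2f A, clash < %.2f A%s\n",
              x$n, x$b, x$clash_cutoff,
              if (is.null(x$compaction)) "" else
                sprintf(", compaction well (depth %.2f, range %.1f A)",
                        x$compaction$depth, x$compaction$range)))
  invisible(x)
}

#' Wrap a coordinate matrix as a conformation
#'
#' @param coords n x 3 numeric matrix of bead coordinates (Angstrom).
#' @param b if non-`NULL`, consecutive-bead distances are checked against
#'   this bond length within `tol`.
#' @param tol bond-length tolerance (Angstrom).
#' @return the matrix with class `conformation`.
#' @export
conformation <- function(coords, b = NULL, tol = 1e-6) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) < 2L)
    stop("a conformation is an n x 3 matrix with n >= 2")
  if (!is.null(b)) {
    bl <- sqrt(rowSums(diff(coords)^2))
    if (any(abs(bl - b) > tol))
      stop("bond lengths deviate from b = ", b, " by more than ", tol)
  }
  class(coords) <- c("conformation", "matrix", "array")
  coords
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation: %d beads, Rg = %.2f A\n", nrow(x),
              radius_of_gyration(x)))
  invisible(x)
}

.unit <- function(v) v / sqrt(sum(v * v))

.rotation_matrix <- function(axis, angle) {
  u <- .unit(axis)
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# bond vectors, interior bend angles (beads 2..n-1) and virtual torsions,
# computed in one pass on plain column vectors (hot path)
.internal_coords <- function(coords) {
  n <- nrow(coords)
  ux <- coords[-1L, 1L] - coords[-n, 1L]
  uy <- coords[-1L, 2L] - coords[-n, 2L]
  uz <- coords[-1L, 3L] - coords[-n, 3L]
  m <- n - 1L
  a <- seq_len(m - 1L)
  bb <- a + 1L
  dots <- ux[a] * ux[bb] + uy[a] * uy[bb] + uz[a] * uz[bb]
  bl2 <- ux * ux + uy * uy + uz * uz
  cosang <- -dots / sqrt(bl2[a] * bl2[bb])
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  theta <- acos(cosang)
  phi <- numeric(0L)
  if (n >= 4L) {
    i1 <- seq_len(m - 2L)
    i2 <- i1 + 1L
    i3 <- i1 + 2L
    cx <- uy[i1] * uz[i2] - uz[i1] * uy[i2]
    cy <- uz[i1] * ux[i2] - ux[i1] * uz[i2]
    cz <- ux[i1] * uy[i2] - uy[i1] * ux[i2]
    dx <- uy[i2] * uz[i3] - uz[i2] * uy[i3]
    dy <- uz[i2] * ux[i3] - ux[i2] * uz[i3]
    dz <- ux[i2] * uy[i3] - uy[i2] * ux[i3]
    xnum <- cx * dx + cy * dy + cz * dz
    ynum <- (cx * ux[i3] + cy * uy[i3] + cz * uz[i3]) * sqrt(bl2[i2])
    phi <- atan2(ynum, xnum)
  }
  list(theta = theta, phi = phi)
}

.bend_angles <- function(coords) .internal_coords(coords)$theta

.torsion_angles <- function(coords) .internal_coords(coords)$phi

# log of the torsion mixture density w.r.t. dphi/(2*pi)
.torsion_logdens <- function(phi, tor) {
  if (length(phi) == 0L) return(0)
  dens <- 0
  for (j in seq_along(tor$weights)) {
    dens <- dens + (tor$weights[j] / tor$i0[j]) *
      exp(tor$kappa[j] * cos(phi - tor$mu[j]))
  }
  sum(log(dens))
}

#' Fine-grained conformational log-prior
#'
#' Evaluates ln p(x) of the polymer prior: bend-angle and torsion terms (plus
#' the compaction well when configured), with `-Inf` whenever any nonbonded
#' pair (sequence separation >= 3) is closer than the clash cutoff. The
#' density is normalized with respect to the uniform measure on bond
#' directions, so the implied stationary bend-angle distribution carries the
#' geometric sin(theta) factor.
#'
#' @param conf a conformation with `model$n` beads.
#' @param model a [polymer_model()].
#' @return finite scalar, or `-Inf` on clash.
#' @export
log_prior_conformation <- function(conf, model) {
  coords <- unclass(conf)
  if (nrow(coords) != model$n)
    stop("conformation has ", nrow(coords), " beads; model expects ", model$n)
  i <- model$nb_i
  j <- model$nb_j
  ax <- coords[i, 1L] - coords[j, 1L]
  ay <- coords[i, 2L] - coords[j, 2L]
  az <- coords[i, 3L] - coords[j, 3L]
  r2 <- ax * ax + ay * ay + az * az
  if (any(r2 < model$clash_cutoff^2)) return(-Inf)
  ic <- .internal_coords(coords)
  theta <- ic$theta
  if (any(theta < model$angle_min)) return(-Inf)
  lp <- sum(model$angle_kappa * cos(theta - model$angle_mu)) -
    length(theta) * model$log_za +
    .torsion_logdens(ic$phi, model$torsion)
  if (!is.null(model$compaction))
    lp <- lp + model$compaction$depth *
      sum(exp(-r2 / model$compaction$range^2))
  lp
}

# sample a bend angle from density ~ exp(kappa*cos(theta-mu)) * sin(theta)
# on the truncated support (theta_min, pi)
.sample_bend <- function(mu, kappa, theta_min = 0) {
  repeat {
    th <- stats::runif(1, theta_min, pi)
    if (stats::runif(1) < exp(kappa * (cos(th - mu) - 1)) * sin(th)) return(th)
  }
}

# sample a torsion from the von Mises mixture (rejection from uniform)
.sample_torsion <- function(tor) {
  j <- sample.int(length(tor$weights), 1L, prob = tor$weights)
  repeat {
    phi <- stats::runif(1, -pi, pi)
    if (stats::runif(1) < exp(tor$kappa[j] * (cos(phi - tor$mu[j]) - 1)))
      return(phi)
  }
}

# place the next bead from the last three, interior angle theta, torsion phi
.place_next <- function(p1, p2, p3, b, theta, phi) {
  bc <- .unit(p3 - p2)
  nrm <- .unit(c(
    (p2 - p1)[2L] * bc[3L] - (p2 - p1)[3L] * bc[2L],
    (p2 - p1)[3L] * bc[1L] - (p2 - p1)[1L] * bc[3L],
    (p2 - p1)[1L] * bc[2L] - (p2 - p1)[2L] * bc[1L]))
  mperp <- c(nrm[2L] * bc[3L] - nrm[3L] * bc[2L],
             nrm[3L] * bc[1L] - nrm[1L] * bc[3L],
             nrm[1L] * bc[2L] - nrm[2L] * bc[1L])
  d2 <- b * c(cos(pi - theta), sin(pi - theta) * cos(phi),
              sin(pi - theta) * sin(phi))
  p3 + d2[1L] * bc + d2[2L] * mperp + d2[3L] * nrm
}

#' Build an initial clash-free chain
#'
#' Grows the chain bead by bead, drawing bend angles and torsions from the
#' model's local priors; on a clash the whole chain is regrown. Deterministic
#' given `seed`.
#'
#' @param model a [polymer_model()].
#' @param seed optional integer seed.
#' @param max_retries maximum number of regrow attempts.
#' @return a clash-free [conformation()] with exact bond lengths.
#' @export
build_chain <- function(model, seed = NULL, max_retries = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  n <- model$n
  b <- model$b
  for (attempt in seq_len(max_retries)) {
    coords <- matrix(0, n, 3L)
    coords[2L, ] <- c(b, 0, 0)
    th <- .sample_bend(model$angle_mu, model$angle_kappa, model$angle_min)
    coords[3L, ] <- coords[2L, ] +
      b * c(cos(pi - th), sin(pi - th), 0)
    ok <- TRUE
    if (n >= 4L) {
      for (i in 4L:n) {
        th <- .sample_bend(model$angle_mu, model$angle_kappa, model$angle_min)
        phi <- .sample_torsion(model$torsion)
        coords[i, ] <- .place_next(coords[i - 3L, ], coords[i - 2L, ],
                                   coords[i - 1L, ], b, th, phi)
        if (i >= 4L) {
          prev <- 1L:(i - 3L)
          d2 <- rowSums((coords[prev, , drop = FALSE] -
                           matrix(coords[i, ], length(prev), 3L,
                                  byrow = TRUE))^2)
          if (any(d2 < model$clash_cutoff^2)) { ok <- FALSE; break }
        }
      }
    }
    if (ok) return(conformation(coords, b = b))
  }
  stop("failed to build a clash-free chain in ", max_retries, " attempts")
}

#' Propose a bond-preserving conformational move
#'
#' Pivot: a randomly chosen bead becomes a hinge and the segment on one
#' (random) side is rigidly rotated about a random axis through it.
#' Crankshaft: the beads strictly between two chain positions are rotated
#' about the axis joining those positions, leaving both endpoints fixed.
#' Both moves are rigid rotations, so bond lengths are preserved exactly and
#' the proposal is symmetric (log proposal ratio 0).
#'
#' @param conf a conformation.
#' @param move `"pivot"` or `"crankshaft"`.
#' @param max_angle maximum rotation amplitude (radians); the angle is drawn
#'   uniformly from (-max_angle, max_angle).
#' @return `list(conf =, log_ratio = 0)`.
#' @export
propose_move <- function(conf, move = "pivot", max_angle = 1.0) {
  if (!move %in% c("pivot", "crankshaft")) stop("unknown move: ", move)
  coords <- unclass(conf)
  n <- nrow(coords)
  ang <- stats::runif(1, -max_angle, max_angle)
  if (move == "pivot") {
    j <- sample.int(n, 1L)
    idx <- if (stats::runif(1) < 0.5) {
      if (j < n) (j + 1L):n else integer(0L)
    } else {
      if (j > 1L) 1L:(j - 1L) else integer(0L)
    }
    if (length(idx)) {
      R <- .rotation_matrix(stats::rnorm(3L), ang)
      coords <- .rotate_rows(coords, idx, coords[j, ], R)
    }
  } else {
    if (n < 3L) stop("crankshaft needs at least 3 beads")
    i <- sample.int(n - 2L, 1L)
    j <- i + 1L + sample.int(n - i - 1L, 1L)  # j in (i+2)..n, axis i--j
    R <- .rotation_matrix(coords[j, ] - coords[i, ], ang)
    coords <- .rotate_rows(coords, (i + 1L):(j - 1L), coords[i, ], R)
  }
  attr(coords, "class") <- class(conf)
  list(conf = coords, log_ratio = 0)
}

# rotate the rows `idx` of a coordinate matrix about `origin` by R
.rotate_rows <- function(coords, idx, origin, R) {
  cc <- coords[idx, , drop = FALSE]
  cc[, 1L] <- cc[, 1L] - origin[1L]
  cc[, 2L] <- cc[, 2L] - origin[2L]
  cc[, 3L] <- cc[, 3L] - origin[3L]
  cc <- cc %*% t(R)
  cc[, 1L] <- cc[, 1L] + origin[1L]
  cc[, 2L] <- cc[, 2L] + origin[2L]
  cc[, 3L] <- cc[, 3L] + origin[3L]
  coords[idx, ] <- cc
  coords
}

#' Radius of gyration of a conformation
#'
#' Root-mean-square bead distance from the centroid; used as a
#' cross-validation observable that is never part of the restraints.
#'
#' @param conf a conformation with >= 2 beads.
#' @return positive scalar (Angstrom).
#' @export
radius_of_gyration <- function(conf) {
  coords <- unclass(conf)
  if (nrow(coords) < 2L) stop("radius of gyration needs at least 2 beads")
  centered <- sweep(coords, 2L, colMeans(coords))
  sqrt(mean(rowSums(centered * centered)))
}
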