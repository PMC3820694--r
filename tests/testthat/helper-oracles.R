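# Independent quadrature oracles and small utilities shared by the tests.
# The densities are written out long-hand here (dlnorm/dexp arithmetic), not
# through the package's composed log-posterior, so that sampler and density
# implementations are checked against an independent integration route.

# unnormalized log-joint of (r, Y) for the two-bead, one-restraint, full
# hierarchical model with linear averaging, lambda = 1 and an exponential
# reference with mean beta
two_bead_logjoint <- function(r, y, d, sigma, beta, prior_density) {
  stats::dlnorm(d, log(y), sigma, log = TRUE) +   # d | Y
    stats::dexp(r, 1 / y, log = TRUE) -           # X | Y (X = r, lam = 1)
    log(y) -                                      # Jeffreys p(Y)
    stats::dexp(r, 1 / beta, log = TRUE) +        # minus reference g(X)
    log(prior_density(r))                         # fine-grained prior p(r)
}

# grid quadrature of the two-bead joint; returns marginal CDF functions
two_bead_quadrature <- function(d, sigma, beta, prior_density,
                                r_max = 30, y_max = 40, n_grid = 800L) {
  r <- seq(r_max / n_grid, r_max, length.out = n_grid)
  y <- seq(y_max / n_grid, y_max, length.out = n_grid)
  lj <- outer(r, y, function(rr, yy)
    two_bead_logjoint(rr, yy, d, sigma, beta, prior_density))
  w <- exp(lj - max(lj))
  w <- w / sum(w)
  cdf_from_grid <- function(grid, probs) {
    cs <- cumsum(probs)
    stats::approxfun(grid, cs / cs[length(cs)], yleft = 0, yright = 1,
                     rule = 2)
  }
  list(r = r, y = y,
       cdf_r = cdf_from_grid(r, rowSums(w)),
       cdf_y = cdf_from_grid(y, colSums(w)))
}

# 1-D quadrature CDF for the single-structure (ISD) posterior of r
isd_quadrature <- function(d, sigma, prior_density, r_max = 30,
                           n_grid = 4000L) {
  r <- seq(r_max / n_grid, r_max, length.out = n_grid)
  lp <- stats::dlnorm(d, log(r), sigma, log = TRUE) + log(prior_density(r))
  w <- exp(lp - max(lp))
  cs <- cumsum(w)
  stats::approxfun(r, cs / cs[length(cs)], yleft = 0, yright = 1, rule = 2)
}

# truncated bend-angle CDF of the polymer prior:
# density ~ exp(kappa*cos(theta-mu)) * sin(theta) on (angle_min, pi)
bend_angle_cdf <- function(model, n_grid = 2000L) {
  th <- seq(model$angle_min, pi, length.out = n_grid)
  w <- exp(model$angle_kappa * cos(th - model$angle_mu)) * sin(th)
  cs <- cumsum(w)
  stats::approxfun(th, cs / cs[length(cs)], yleft = 0, yright = 1, rule = 2)
}

# small deterministic helix-like chain used where an arbitrary but valid
# conformation is needed
fixture_chain <- function(n = 6L, b = 3.8) {
  build_chain(polymer_model(n = n, b = b), seed = 42)
}
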