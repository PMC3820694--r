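#' Bundle a conformational system with the data model
#'
#' A model bundle collects everything the sampler needs: the fine-grained
#' log-prior and a symmetric (or Hastings-corrected) move proposal for the
#' conformational degrees of freedom, the forward model, and the data-side
#' components (restraints, scale vector, reference, mode). With
#' `restraints = NULL` the bundle is prior-only and sampling reduces to
#' sampling the conformational prior.
#'
#' @param log_prior_fn function(conf) returning ln p(x) (may be `-Inf`).
#' @param propose_fn function(conf) returning `list(conf =, log_ratio =)`.
#' @param init_conf starting conformation.
#' @param fm a [forward_model()] (required when restraints are present).
#' @param restraints a [restraint_set()] or `NULL` for prior-only sampling.
#' @param lam positive scale vector (full mode); defaults to all ones.
#' @param ref a [reference_model()]; defaults to uniform.
#' @param mode a [model_mode()].
#' @return an object of class `model_bundle`.
#' @export
model_bundle <- function(log_prior_fn, propose_fn, init_conf, fm = NULL,
                         restraints = NULL, lam = NULL, ref = NULL,
                         mode = model_mode("full")) {
  stopifnot(is.function(log_prior_fn), is.function(propose_fn))
  if (!is.null(restraints)) {
    if (!inherits(restraints, "restraint_set"))
      stop("'restraints' must be a restraint_set or NULL")
    if (is.null(fm)) fm <- forward_model_for(restraints)
    m <- length(restraints)
    if (is.null(lam)) lam <- rep(1, m)
    if (restraints$averaging == "linear" && mode$mode == "full" &&
        any(lam != 1))
      stop("the scale vector is frozen at 1 for linearly averaged data")
    if (is.null(ref)) ref <- reference_model("uniform")
    lam <- rep_len(as.numeric(lam), m)
    .check_positive(lam, "model_bundle 'lam'")
  }
  structure(list(log_prior_fn = log_prior_fn, propose_fn = propose_fn,
                 init_conf = init_conf, fm = fm, restraints = restraints,
                 lam = lam, ref = ref, mode = mode),
            class = "model_bundle")
}

#' Bundle a polymer model with restraints
#'
#' Convenience constructor wiring [log_prior_conformation()] and
#' [propose_move()] (pivot and crankshaft drawn with equal probability) into
#' a [model_bundle()].
#'
#' @param model a [polymer_model()].
#' @param restraints a [restraint_set()] or `NULL`.
#' @param lam,ref,mode passed to [model_bundle()].
#' @param max_angle move amplitude (radians).
#' @param init_seed seed for building the initial chain (`NULL` draws from
#'   the current RNG stream).
#' @param coarse_k optional coarse-graining exponent passed to
#'   [forward_model_for()] (e.g. 1 to use the inverse distance as the
#'   coarse variable of the full hierarchical model).
#' @return a [model_bundle()].
#' @export
polymer_bundle <- function(model, restraints = NULL, lam = NULL, ref = NULL,
                           mode = model_mode("full"), max_angle = 1.0,
                           init_seed = NULL, coarse_k = NULL) {
  model_bundle(
    log_prior_fn = function(conf) log_prior_conformation(conf, model),
    propose_fn = function(conf)
      propose_move(conf,
                   move = if (stats::runif(1) < 0.5) "pivot" else "crankshaft",
                   max_angle = max_angle),
    init_conf = build_chain(model, seed = init_seed),
    fm = if (!is.null(restraints)) forward_model_for(restraints, coarse_k),
    restraints = restraints, lam = lam, ref = ref, mode = mode)
}

#' Two-bead single-distance system
#'
#' The smallest possible "molecule": two beads whose only degree of freedom
#' is their separation r, with a truncated log-normal prior on r and a
#' symmetric random-walk proposal. Used to validate the sampler against
#' direct numerical quadrature of the posterior.
#'
#' The support is truncated to `(r_min, r_max)`. Hard bounds keep every
#' coarse-grained observable (r itself, or r^-k) bounded, which the
#' reference-ratio construction requires for a proper posterior: dividing by
#' an exponential reference density rewards large observable values, and
#' only a conformational prior of bounded support (as for a clash-limited
#' polymer) guarantees that this reward is capped.
#'
#' @param meanlog,sdlog parameters of the log-normal prior on r.
#' @param step half-width of the uniform random-walk proposal (Angstrom).
#' @param r0 initial separation.
#' @param r_min,r_max hard support bounds on r (Angstrom).
#' @return list with `log_prior_fn`, `propose_fn`, `init_conf`, and
#'   `prior_density` (the normalized density of r, for quadrature oracles;
#'   zero outside the support).
#' @export
two_bead_system <- function(meanlog = log(6), sdlog = 0.4, step = 1.0,
                            r0 = exp(meanlog), r_min = 0.5, r_max = 25) {
  stopifnot(r_min >= 0, r_max > r_min, r0 > r_min, r0 < r_max)
  mk <- function(r) conformation(rbind(c(0, 0, 0), c(r, 0, 0)))
  log_mass <- log(stats::plnorm(r_max, meanlog, sdlog) -
                    stats::plnorm(r_min, meanlog, sdlog))
  list(
    log_prior_fn = function(conf) {
      r <- unclass(conf)[2L, 1L]
      if (r <= r_min || r >= r_max) -Inf
      else stats::dlnorm(r, meanlog, sdlog, log = TRUE) - log_mass
    },
    propose_fn = function(conf) {
      r <- unclass(conf)[2L, 1L] + stats::runif(1, -step, step)
      list(conf = mk(r), log_ratio = 0)
    },
    init_conf = mk(r0),
    prior_density = function(r)
      ifelse(r > r_min & r < r_max,
             stats::dlnorm(r, meanlog, sdlog) / exp(log_mass), 0))
}

#' Sampler configuration
#'
#' @param n_steps total Metropolis-Hastings steps.
#' @param thin record every `thin`-th post-burn-in state.
#' @param burn_in steps discarded before recording (default 10% of
#'   `n_steps`).
#' @param sigma_c log-scale width of the multiplicative Y proposal; should be
#'   of the same order as the experimental uncertainty.
#' @param p_y_move probability of attempting a Y move rather than a
#'   conformational move (ignored when the mode has no Y).
#' @param seed optional integer seed; identical seeds give identical chains.
#' @param y_hastings include the Hastings correction of the multiplicative
#'   Y proposal. Only ever set to `FALSE` as a deliberate negative control.
#' @param store_conf keep the recorded conformations (set `FALSE` to save
#'   memory when only X and Y are needed).
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_steps, thin = 1L,
                           burn_in = max(1L, round(0.1 * n_steps)),
                           sigma_c = 0.1, p_y_move = 0.2, seed = NULL,
                           y_hastings = TRUE, store_conf = TRUE) {
  stopifnot(n_steps >= 1L, thin >= 1L, burn_in >= 0L,
            sigma_c > 0, p_y_move > 0, p_y_move < 1)
  structure(list(n_steps = as.integer(n_steps), thin = as.integer(thin),
                 burn_in = as.integer(burn_in), sigma_c = sigma_c,
                 p_y_move = p_y_move, seed = seed,
                 y_hastings = isTRUE(y_hastings),
                 store_conf = isTRUE(store_conf)),
            class = "sampler_config")
}

#' Multiplicative log-normal proposal for the ensemble average
#'
#' Each component of Y is multiplied by an independent factor c with
#' ln c ~ Normal(0, sigma_c^2). The move is reversible in log space; its
#' Hastings correction, `sum(log(y_new / y))`, must be added to the
#' log-posterior difference before the Metropolis test.
#'
#' @param y current positive ensemble average.
#' @param sigma_c positive proposal width (log scale).
#' @return `list(y =, log_hastings =)`.
#' @export
propose_y_update <- function(y, sigma_c) {
  lc <- stats::rnorm(length(y), 0, sigma_c)
  list(y = y * exp(lc), log_hastings = sum(lc))
}

# attach precomputed constants used by the per-step fast path
.prep_bundle <- function(bundle) {
  if (isTRUE(bundle$prepped)) return(bundle)
  rs <- bundle$restraints
  if (!is.null(rs)) {
    m <- length(rs)
    bundle$log_d <- log(rs$d)
    bundle$lik_const <- sum(-log(rs$d * rs$sigma) - 0.5 * log(2 * pi))
    bundle$inv2s2 <- 1 / (2 * rs$sigma^2)
    # observable back-transform follows the coarse space of the forward
    # model (which may use a lower exponent than the data averaging)
    bundle$obs_logscale <- if (!is.null(bundle$fm) &&
                               bundle$fm$kind == "inverse-power")
      -1 / bundle$fm$k else 1
    bundle$ref_beta <- if (!is.null(bundle$ref) &&
                           bundle$ref$kind == "exponential") bundle$ref$beta
    if (bundle$mode$mode == "maxent")
      bundle$lagrange_vec <- rep_len(bundle$mode$lagrange, m)
  }
  if (!is.null(bundle$fm)) {
    bundle$fm_i1 <- bundle$fm$pairs[, 1L] + 1L
    bundle$fm_j1 <- bundle$fm$pairs[, 2L] + 1L
    bundle$fm_power <- bundle$fm$kind == "inverse-power"
    bundle$fm_k <- bundle$fm$k
  }
  bundle$prepped <- TRUE
  bundle
}

# forward model evaluation on the fast path (validation done at construction)
.cg_fast <- function(coords, bundle) {
  dx <- coords[bundle$fm_i1, 1L] - coords[bundle$fm_j1, 1L]
  dy <- coords[bundle$fm_i1, 2L] - coords[bundle$fm_j1, 2L]
  dz <- coords[bundle$fm_i1, 3L] - coords[bundle$fm_j1, 3L]
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (bundle$fm_power) r^(-bundle$fm_k) else r
}

# x-dependent part of the log-posterior (everything that changes under a
# conformational move), given cached x_lp and x_cg
.x_terms <- function(x_lp, x_cg, y, bundle) {
  if (x_lp == -Inf) return(-Inf)
  rs <- bundle$restraints
  if (is.null(rs)) return(x_lp)
  md <- bundle$mode$mode
  if (md == "full") {
    mu <- bundle$lam * y
    v <- x_lp - sum(log(mu) + x_cg / mu)
    if (!is.null(bundle$ref_beta))
      v <- v + sum(log(bundle$ref_beta) + x_cg / bundle$ref_beta)
    v
  } else if (md == "isd") {
    x_lp + bundle$lik_const -
      sum((bundle$log_d - bundle$obs_logscale * log(x_cg))^2 * bundle$inv2s2)
  } else {
    x_lp - sum(bundle$lagrange_vec * x_cg)
  }
}

# y-dependent-only part (changes under a Y move, excluding p(X|Y))
.y_terms <- function(y, bundle) {
  md <- bundle$mode$mode
  if (md == "full") {
    logy <- log(y)
    bundle$lik_const -
      sum((bundle$log_d - bundle$obs_logscale * logy)^2 * bundle$inv2s2) -
      sum(logy)
  } else if (md == "maxent") {
    -0.5 * sum((bundle$restraints$d - y)^2) / bundle$mode$noise_sd^2
  } else 0
}

.has_y <- function(bundle) {
  !is.null(bundle$restraints) && bundle$mode$mode %in% c("full", "maxent")
}

# initial sampler state for a bundle: Y starts at the observed data mapped
# into coarse-grained space
.init_state <- function(bundle) {
  bundle <- .prep_bundle(bundle)
  conf <- bundle$init_conf
  x_lp <- bundle$log_prior_fn(conf)
  if (!is.finite(x_lp))
    stop("initial conformation has zero prior probability")
  x_cg <- if (!is.null(bundle$fm)) as.numeric(coarse_grain(conf, bundle$fm))
  y <- NULL
  if (.has_y(bundle)) {
    rs <- bundle$restraints
    y <- if (isTRUE(bundle$fm_power) && bundle$mode$mode == "full")
      rs$d^(-bundle$fm_k) else rs$d
  }
  st <- list(conf = conf, x_lp = x_lp, x_cg = x_cg, y = y)
  st$log_post <- .x_terms(x_lp, x_cg, y, bundle) +
    (if (.has_y(bundle)) .y_terms(y, bundle) else 0)
  st
}

#' Perform one Metropolis-Hastings step
#'
#' With probability `p_y_move` (when the mode carries an ensemble average) a
#' joint multiplicative Y move is attempted, otherwise a conformational move
#' from the bundle's proposal; either is accepted by the Metropolis rule on
#' the cached log-posterior, with the Hastings correction for the Y move.
#' Clashing proposals (prior `-Inf`) are always rejected.
#'
#' @param state sampler state as returned by [mcmc_step()] or created
#'   internally by [run_chain()]: `list(conf, x_lp, x_cg, y, log_post)`.
#' @param bundle a [model_bundle()].
#' @param cfg a [sampler_config()].
#' @return updated state with attribute `accepted` (logical) and
#'   `move` (`"conf"` or `"y"`).
#' @export
mcmc_step <- function(state, bundle, cfg) {
  bundle <- .prep_bundle(bundle)
  if (is.null(state)) state <- .init_state(bundle)
  do_y <- .has_y(bundle) && stats::runif(1) < cfg$p_y_move
  if (do_y) {
    prop <- propose_y_update(state$y, cfg$sigma_c)
    dlp <- .y_terms(prop$y, bundle) - .y_terms(state$y, bundle)
    if (bundle$mode$mode == "full")
      dlp <- dlp + logprior_x_given_y(state$x_cg, prop$y, bundle$lam) -
        logprior_x_given_y(state$x_cg, state$y, bundle$lam)
    logr <- dlp + if (cfg$y_hastings) prop$log_hastings else 0
    acc <- is.finite(logr) && log(stats::runif(1)) < logr
    if (acc) {
      state$y <- prop$y
      state$log_post <- state$log_post + dlp
    }
  } else {
    prop <- bundle$propose_fn(state$conf)
    x_lp <- bundle$log_prior_fn(prop$conf)
    if (is.finite(x_lp)) {
      x_cg <- if (!is.null(bundle$fm)) .cg_fast(unclass(prop$conf), bundle)
      dlp <- .x_terms(x_lp, x_cg, state$y, bundle) -
        .x_terms(state$x_lp, state$x_cg, state$y, bundle)
      acc <- is.finite(dlp) && log(stats::runif(1)) < dlp + prop$log_ratio
      if (acc) {
        state$conf <- prop$conf
        state$x_lp <- x_lp
        state$x_cg <- x_cg
        state$log_post <- state$log_post + dlp
      }
    } else acc <- FALSE
  }
  attr(state, "accepted") <- acc
  attr(state, "move") <- if (do_y) "y" else "conf"
  state
}

#' Run a Metropolis-Hastings chain
#'
#' Iterates [mcmc_step()] for `cfg$n_steps` steps, recording every
#' `cfg$thin`-th state after `cfg$burn_in`. Deterministic given `cfg$seed`.
#'
#' @param bundle a [model_bundle()].
#' @param cfg a [sampler_config()].
#' @return list with `conformations` (list, or `NULL` if not stored), `x`
#'   and `y` (matrices, samples in rows; `NULL` when absent), `log_post`,
#'   `acceptance` (per move type), and `n_samples`.
#' @export
run_chain <- function(bundle, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  bundle <- .prep_bundle(bundle)
  state <- .init_state(bundle)
  n_rec <- max(0L, (cfg$n_steps - cfg$burn_in) %/% cfg$thin)
  m <- if (!is.null(bundle$fm)) nrow(bundle$fm$pairs) else 0L
  xs <- if (m > 0L) matrix(NA_real_, n_rec, m)
  ys <- if (.has_y(bundle)) matrix(NA_real_, n_rec, m)
  lps <- numeric(n_rec)
  confs <- if (cfg$store_conf) vector("list", n_rec)
  att <- c(conf = 0L, y = 0L)
  acc <- c(conf = 0L, y = 0L)
  irec <- 0L
  for (step in seq_len(cfg$n_steps)) {
    state <- mcmc_step(state, bundle, cfg)
    mv <- attr(state, "move")
    att[mv] <- att[mv] + 1L
    acc[mv] <- acc[mv] + attr(state, "accepted")
    if (step > cfg$burn_in && (step - cfg$burn_in) %% cfg$thin == 0L &&
        irec < n_rec) {
      irec <- irec + 1L
      if (!is.null(xs)) xs[irec, ] <- state$x_cg
      if (!is.null(ys)) ys[irec, ] <- state$y
      lps[irec] <- state$log_post
      if (!is.null(confs)) confs[[irec]] <- state$conf
    }
  }
  list(conformations = confs, x = xs, y = ys, log_post = lps,
       acceptance = ifelse(att > 0L, acc / pmax(att, 1L), NA_real_),
       n_samples = irec, final_state = state)
}

# batch-means Monte-Carlo standard errors for columns of a sample matrix
.batch_se <- function(mat, n_batches = 20L) {
  n <- nrow(mat)
  nb <- min(n_batches, n)
  grp <- rep(seq_len(nb), each = ceiling(n / nb))[seq_len(n)]
  bm <- apply(mat, 2L, function(col) tapply(col, grp, mean))
  apply(bm, 2L, stats::sd) / sqrt(nb)
}

#' Estimate the reference distribution by prior-only sampling
#'
#' Samples conformations from the fine-grained prior alone, coarse-grains
#' them, and fits a product of exponentials by moment matching: each
#' reference mean beta_i is the sample mean of X_i. Monte-Carlo standard
#' errors (batch means) are attached.
#'
#' @param bundle a prior-only [model_bundle()] (restraints are stripped if
#'   present).
#' @param fm the [forward_model()] defining X.
#' @param n_steps MCMC steps for the prior-only chain.
#' @param seed optional seed.
#' @param thin thinning interval.
#' @param burn_in burn-in steps (default 10%).
#' @param min_samples minimum recorded samples below which estimation fails.
#' @return a [reference_model()] of kind `"exponential"`, with `beta_se`.
#' @export
estimate_reference <- function(bundle, fm, n_steps, seed = NULL, thin = 10L,
                               burn_in = max(1L, round(0.1 * n_steps)),
                               min_samples = 100L) {
  prior_bundle <- model_bundle(bundle$log_prior_fn, bundle$propose_fn,
                               bundle$init_conf, fm = fm, restraints = NULL,
                               mode = bundle$mode)
  prior_bundle$fm <- fm
  cfg <- sampler_config(n_steps = n_steps, thin = thin, burn_in = burn_in,
                        seed = seed, store_conf = FALSE)
  res <- run_chain(prior_bundle, cfg)
  if (res$n_samples < min_samples)
    stop("too few prior samples (", res$n_samples, " < ", min_samples,
         ") to estimate the reference distribution")
  reference_model("exponential", beta = colMeans(res$x),
                  beta_se = .batch_se(res$x))
}

#' Moment-matching update of the scale vector
#'
#' One empirical-Bayes update: `lam * mean_y / mean_x`, driving the
#' posterior expectation of X toward that of Y (the fixed point has
#' mean_x = mean_y). Scale-equivariant: rescaling both expectations leaves
#' the update unchanged.
#'
#' @param lam current positive scale vector.
#' @param mean_x posterior expectation of the coarse-grained observable.
#' @param mean_y target expectation (posterior mean of Y, or the observed
#'   data mapped to coarse space).
#' @return updated scale vector.
#' @export
update_lambda <- function(lam, mean_x, mean_y) {
  stopifnot(length(lam) == length(mean_x), length(lam) == length(mean_y))
  .check_positive(lam, "update_lambda 'lam'")
  .check_positive(mean_x, "update_lambda 'mean_x'")
  .check_positive(mean_y, "update_lambda 'mean_y'")
  lam * mean_y / mean_x
}

#' Empirical-Bayes estimation of the scale vector
#'
#' Starting from the all-ones vector, alternates posterior sampling at the
#' current scale vector with the moment-matching update of [update_lambda()]
#' until the maximum relative change of lambda falls below `tol`, or
#' `max_iter` is reached (flagged as non-converged). For linearly averaged
#' data the scale vector is the all-ones vector and no sampling is done.
#'
#' @param bundle a full-mode [model_bundle()] with restraints.
#' @param max_iter maximum EB iterations.
#' @param steps_per_iter MCMC steps per iteration.
#' @param tol convergence tolerance on the relative change of lambda;
#'   defaults to the mean relative experimental uncertainty of the data.
#' @param fixed_point `"y"` targets mean(X) = mean(Y) (default); `"data"`
#'   targets mean(X) = d mapped into coarse space.
#' @param sampler_args list of overrides passed to [sampler_config()]
#'   (e.g. `thin`, `sigma_c`, `p_y_move`).
#' @param seed optional seed for the whole loop.
#' @return list with `lambda`, `trace` (one row per iteration: lambda,
#'   mean_x, mean_y, acceptance rates, relative change), `converged`,
#'   `iterations`, and the final iteration's chain as `last_run`.
#' @export
run_empirical_bayes <- function(bundle, max_iter = 30L, steps_per_iter = 5e4,
                                tol = NULL, fixed_point = c("y", "data"),
                                sampler_args = list(), seed = NULL) {
  fixed_point <- match.arg(fixed_point)
  rs <- bundle$restraints
  if (is.null(rs)) stop("empirical Bayes requires restraints")
  if (bundle$mode$mode != "full")
    stop("empirical Bayes applies to the full hierarchical mode")
  m <- length(rs)
  if (rs$averaging == "linear") {
    return(list(lambda = rep(1, m), trace = NULL, converged = TRUE,
                iterations = 0L, last_run = NULL))
  }
  if (is.null(tol)) tol <- mean(rs$sigma)
  if (!is.null(seed)) set.seed(seed)
  lam <- rep(1, m)
  fm <- if (is.null(bundle$fm)) forward_model_for(rs) else bundle$fm
  d_cg <- rs$d^(-fm$k)
  trace <- vector("list", max_iter)
  converged <- FALSE
  last <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    bundle$lam <- lam
    cfg_args <- utils::modifyList(
      list(n_steps = steps_per_iter, thin = 10L,
           sigma_c = mean(rs$sigma), store_conf = FALSE),
      sampler_args)
    cfg <- do.call(sampler_config, cfg_args)
    res <- run_chain(bundle, cfg)
    mean_x <- colMeans(res$x)
    mean_y <- colMeans(res$y)
    target <- if (fixed_point == "y") mean_y else d_cg
    lam_new <- update_lambda(lam, mean_x, target)
    rel <- max(abs(lam_new - lam) / lam)
    trace[[it]] <- data.frame(iteration = it, restraint = seq_len(m),
                              lambda = lam, mean_x = mean_x,
                              mean_y = mean_y, rel_change = rel,
                              acc_conf = res$acceptance[["conf"]],
                              acc_y = res$acceptance[["y"]])
    # warm start the next iteration from the final state of this one
    bundle$init_conf <- res$final_state$conf
    last <- res
    lam <- lam_new
    if (rel <= tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("empirical Bayes did not converge within ", max_iter,
            " iterations (last relative change ",
            signif(trace[[it]]$rel_change[1L], 3L), ")")
  list(lambda = lam, trace = do.call(rbind, trace[seq_len(it)]),
       converged = converged, iterations = it, last_run = last)
}
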