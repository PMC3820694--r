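test_that("multiplicative Y proposal and its Hastings term are exact", {
  y <- c(2, 5, 0.5)
  set.seed(41)
  prop <- propose_y_update(y, sigma_c = 0.3)
  set.seed(41)
  lc <- stats::rnorm(3, 0, 0.3)
  expect_equal(prop$y, y * exp(lc))
  expect_equal(prop$log_hastings, sum(lc))
  expect_true(all(prop$y > 0))
})

test_that("scale-vector update matches its closed form and is equivariant", {
  expect_equal(update_lambda(1, mean_x = 2, mean_y = 1), 0.5)
  expect_equal(update_lambda(c(1, 2), c(4, 3), c(2, 3)), c(0.5, 2))
  lam <- c(0.7, 1.3)
  mx <- c(2.2, 0.9)
  my <- c(1.8, 1.1)
  expect_equal(update_lambda(lam, 10 * mx, 10 * my),
               update_lambda(lam, mx, my))
  # at the fixed point the update is the identity
  expect_equal(update_lambda(lam, my, my), lam)
  expect_error(update_lambda(1, c(1, 2), 1), "length")
  expect_error(update_lambda(-1, 1, 1), "positive")
})

test_that("sampler and bundle constructors validate their inputs", {
  expect_error(sampler_config(0), "n_steps")
  expect_error(sampler_config(100, sigma_c = 0), "sigma_c")
  expect_error(sampler_config(100, p_y_move = 1), "p_y_move")
  sys <- two_bead_system()
  rs <- restraint_set(cbind(0, 1), d = 6, sigma = 0.2, averaging = "linear")
  expect_error(
    model_bundle(sys$log_prior_fn, sys$propose_fn, sys$init_conf,
                 restraints = rs, lam = 2),
    "frozen at 1")
  expect_error(
    model_bundle(sys$log_prior_fn, sys$propose_fn, sys$init_conf,
                 restraints = list(d = 6)),
    "restraint_set")
})

test_that("run_chain is seed-deterministic and bookkeeps correctly", {
  sys <- two_bead_system()
  rs <- restraint_set(cbind(0, 1), d = 6, sigma = 0.2, averaging = "linear")
  bundle <- model_bundle(sys$log_prior_fn, sys$propose_fn, sys$init_conf,
                         restraints = rs)
  cfg <- sampler_config(n_steps = 4000, thin = 5, burn_in = 500, seed = 7)
  r1 <- run_chain(bundle, cfg)
  r2 <- run_chain(bundle, cfg)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$y, r2$y)
  expect_equal(r1$n_samples, (4000 - 500) %/% 5)
  expect_equal(nrow(r1$x), r1$n_samples)
  expect_equal(length(r1$conformations), r1$n_samples)
  expect_true(all(r1$acceptance > 0 & r1$acceptance < 1))
  expect_true(all(is.finite(r1$log_post)))
  # store_conf = FALSE drops the conformations but keeps X and Y
  r3 <- run_chain(bundle, sampler_config(n_steps = 1000, thin = 5,
                                         seed = 7, store_conf = FALSE))
  expect_null(r3$conformations)
  expect_false(is.null(r3$x))
})

test_that("prior-only sampling carries no X or Y blocks", {
  model <- polymer_model(n = 6L)
  res <- run_chain(polymer_bundle(model, init_seed = 1),
                   sampler_config(n_steps = 2000, thin = 10, seed = 2))
  expect_null(res$x)
  expect_null(res$y)
  expect_equal(res$acceptance[["y"]], NA_real_)
  expect_true(res$acceptance[["conf"]] > 0)
})

test_that("mcmc_step accepts no-op proposals and rejects clashes", {
  sys <- two_bead_system()
  rs <- restraint_set(cbind(0, 1), d = 6, sigma = 0.2, averaging = "linear")
  noop <- modifyList(sys, list(propose_fn = function(conf)
    list(conf = conf, log_ratio = 0)))
  b_noop <- model_bundle(noop$log_prior_fn, noop$propose_fn, noop$init_conf,
                         restraints = rs)
  cfg <- sampler_config(n_steps = 10, p_y_move = 0.2)
  set.seed(3)
  st <- NULL
  for (i in 1:50) {
    st <- mcmc_step(st, b_noop, cfg)
    if (attr(st, "move") == "conf") expect_true(attr(st, "accepted"))
  }
  # proposals into the zero-probability region are always rejected
  bad <- modifyList(sys, list(propose_fn = function(conf)
    list(conf = conformation(rbind(c(0, 0, 0), c(-1, 0, 0))), log_ratio = 0)))
  b_bad <- model_bundle(bad$log_prior_fn, bad$propose_fn, bad$init_conf,
                        restraints = rs)
  st <- NULL
  for (i in 1:50) {
    st <- mcmc_step(st, b_bad, cfg)
    if (attr(st, "move") == "conf") expect_false(attr(st, "accepted"))
  }
  expect_equal(unclass(st$conf)[2, 1], 6)  # never left the start
})

test_that("an initial state of zero prior probability is an error", {
  sys <- two_bead_system()
  bad_init <- conformation(rbind(c(0, 0, 0), c(-1, 0, 0)))
  bundle <- model_bundle(sys$log_prior_fn, sys$propose_fn, bad_init)
  expect_error(run_chain(bundle, sampler_config(100)), "zero prior")
  expect_error(two_bead_system(r0 = -1), "r0")
})

test_that("reference estimation recovers a known prior mean", {
  # two-bead prior: r ~ lognormal => E[r] known in closed form
  meanlog <- log(6)
  sdlog <- 0.4
  sys <- two_bead_system(meanlog = meanlog, sdlog = sdlog)
  bundle <- model_bundle(sys$log_prior_fn, sys$propose_fn, sys$init_conf)
  fm <- forward_model(cbind(0, 1), "linear")
  ref <- estimate_reference(bundle, fm, n_steps = 40000, seed = 51, thin = 5)
  truth <- exp(meanlog + sdlog^2 / 2)
  expect_identical(ref$kind, "exponential")
  expect_lt(abs(ref$beta - truth), 4 * ref$beta_se)
  expect_true(ref$beta_se < 0.1 * ref$beta)
  # doubling the chain length must agree within joint Monte-Carlo error
  ref2 <- estimate_reference(bundle, fm, n_steps = 80000, seed = 52, thin = 5)
  expect_lt(abs(ref2$beta - ref$beta),
            4 * sqrt(ref$beta_se^2 + ref2$beta_se^2))
  expect_error(estimate_reference(bundle, fm, n_steps = 200, seed = 53),
               "too few")
})

test_that("empirical Bayes short-circuits for linearly averaged data", {
  sys <- two_bead_system()
  rs <- restraint_set(cbind(0, 1), d = 6, sigma = 0.2, averaging = "linear")
  bundle <- model_bundle(sys$log_prior_fn, sys$propose_fn, sys$init_conf,
                         restraints = rs)
  fit <- run_empirical_bayes(bundle)
  expect_identical(fit$lambda, 1)
  expect_true(fit$converged)
  expect_identical(fit$iterations, 0L)
  expect_null(fit$trace)
  # but it refuses non-full modes and missing restraints
  expect_error(run_empirical_bayes(
    model_bundle(sys$log_prior_fn, sys$propose_fn, sys$init_conf)),
    "requires restraints")
  rsp <- restraint_set(cbind(0, 1), d = 6, sigma = 0.2, averaging = "power")
  bi <- model_bundle(sys$log_prior_fn, sys$propose_fn, sys$init_conf,
                     restraints = rsp, mode = model_mode("isd"))
  expect_error(run_empirical_bayes(bi), "full hierarchical")
})

test_that("empirical Bayes reaches its moment-matching fixed point", {
  # two-bead system with one power-averaged restraint (k = 1 keeps the
  # observable within a narrow bounded band): small enough that a few cheap
  # iterations give a tight fixed point
  sys <- two_bead_system(meanlog = log(6), sdlog = 0.3, r_min = 2,
                         r_max = 15)
  rs <- restraint_set(cbind(0, 1), d = 5.5, sigma = 0.1, averaging = "power",
                      k = 1L)
  beta <- stats::integrate(function(r) sys$prior_density(r) / r,
                           2, 15)$value
  ref <- reference_model("exponential", beta = beta)
  bundle <- model_bundle(sys$log_prior_fn, sys$propose_fn, sys$init_conf,
                         restraints = rs, ref = ref)
  fit <- run_empirical_bayes(bundle, max_iter = 20, steps_per_iter = 20000,
                             sampler_args = list(thin = 5, sigma_c = 0.1),
                             seed = 61)
  expect_true(fit$converged)
  expect_true(fit$lambda > 0)
  tail_row <- fit$trace[nrow(fit$trace), ]
  gap <- abs(tail_row$mean_x - tail_row$mean_y) / tail_row$mean_y
  expect_lt(gap, 2 * mean(rs$sigma))
  # the trace is one tidy row per (iteration, restraint)
  expect_identical(names(fit$trace)[1:2], c("iteration", "restraint"))
  expect_equal(fit$trace$iteration[nrow(fit$trace)], fit$iterations)
})
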