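# Shared end-to-end pipeline fixture for the statistical acceptance checks.
# Computed lazily once per test run (several blocks examine different
# aspects of the same inference) and cached in this environment.
.pipeline_cache <- new.env(parent = emptyenv())

acceptance_pipeline <- function() {
  if (!is.null(.pipeline_cache$fx)) return(.pipeline_cache$fx)
  tm <- default_target_model()
  cfg <- synthetic_config(target_model = tm, n_ensemble = 1000, thin = 50,
                          burn_in = 5000, seed = 101)
  target <- simulate_target_ensemble(cfg)
  rs_pow <- make_restraints(target, default_pairs(), "power",
                            rel_noise = 0.05, seed = 102)
  rs_lin <- make_restraints(target, default_pairs(), "linear",
                            rel_noise = 0.05, seed = 103)
  pm <- polymer_model()
  prior_bundle <- polymer_bundle(pm, init_seed = 104)
  ref <- estimate_reference(prior_bundle, forward_model_for(rs_pow, 1),
                            n_steps = 200000, seed = 105, thin = 10)
  bf <- polymer_bundle(pm, restraints = rs_pow, ref = ref, init_seed = 106,
                       coarse_k = 1)
  fit <- suppressWarnings(
    run_empirical_bayes(bf, max_iter = 25, steps_per_iter = 40000,
                        seed = 107, sampler_args = list(thin = 10)))
  bf$lam <- fit$lambda
  bf$init_conf <- fit$last_run$final_state$conf
  prod_pow <- run_chain(bf, sampler_config(n_steps = 200000, thin = 25,
                                           sigma_c = mean(rs_pow$sigma),
                                           seed = 108))
  bl <- polymer_bundle(pm, restraints = rs_lin, init_seed = 109)
  fit_lin <- run_empirical_bayes(bl, seed = 120)
  prod_lin <- run_chain(bl, sampler_config(n_steps = 200000, thin = 25,
                                           sigma_c = mean(rs_lin$sigma),
                                           seed = 110))
  prior_run <- run_chain(prior_bundle,
                         sampler_config(n_steps = 100000, thin = 25,
                                        seed = 113))
  .pipeline_cache$fx <- list(
    target = target, rs_pow = rs_pow, rs_lin = rs_lin, ref = ref,
    fit = fit, fit_lin = fit_lin, prod_pow = prod_pow, prod_lin = prod_lin,
    prior_run = prior_run)
  .pipeline_cache$fx
}
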