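test_that("polymer model and conformation constructors validate inputs", {
  expect_error(polymer_model(n = 2), "at least 3")
  expect_error(polymer_model(b = -1), "positive")
  expect_error(polymer_model(clash_cutoff = 3.9), "smaller than the bond")
  expect_error(polymer_model(angle_min = 3.2), "angle_min")
  expect_error(conformation(matrix(0, 3, 2)), "n x 3")
  # bond-length check fires only when b is supplied
  bad <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_silent(conformation(bad))
  expect_error(conformation(bad, b = 3.8), "deviate")
})

test_that("build_chain is deterministic, clash-free and bond-exact", {
  model <- polymer_model(n = 14L)
  c1 <- build_chain(model, seed = 5)
  c2 <- build_chain(model, seed = 5)
  c3 <- build_chain(model, seed = 6)
  expect_identical(unclass(c1), unclass(c2))
  expect_false(isTRUE(all.equal(unclass(c1), unclass(c3))))
  expect_true(is.finite(log_prior_conformation(c1, model)))
  bl <- sqrt(rowSums(diff(unclass(c1))^2))
  expect_equal(bl, rep(model$b, 13L), tolerance = 1e-9)
  # every nonbonded pair respects the cutoff and every bend the hard bound
  pd <- as.matrix(dist(unclass(c1)))
  nb <- abs(row(pd) - col(pd)) >= 3
  expect_true(all(pd[nb] >= model$clash_cutoff))
})

test_that("clashes and violated angle bounds zero the prior", {
  model <- polymer_model(n = 4L)
  b <- model$b
  # beads 1 and 4 coincide: sequence separation 3 => clash
  clash <- conformation(rbind(c(0, 0, 0), c(b, 0, 0), c(b, b, 0),
                              c(0.1, 0.1, 0)))
  expect_identical(log_prior_conformation(clash, model), -Inf)
  # a 3-bead chain with bend angle below angle_min
  m3 <- polymer_model(n = 3L, angle_min = 1.3)
  th <- 1.0
  sharp <- conformation(rbind(
    c(0, 0, 0), c(b, 0, 0),
    c(b, 0, 0) + b * c(cos(pi - th), sin(pi - th), 0)))
  expect_identical(log_prior_conformation(sharp, m3), -Inf)
  # wrong bead count is an error, not -Inf
  expect_error(log_prior_conformation(sharp, model), "beads")
})

test_that("bend-angle term matches its closed form on a 3-bead chain", {
  m3 <- polymer_model(n = 3L, angle_mu = 2.0, angle_kappa = 2.0)
  b <- m3$b
  mk <- function(th) conformation(rbind(
    c(0, 0, 0), c(b, 0, 0),
    c(b, 0, 0) + b * c(cos(pi - th), sin(pi - th), 0)))
  lp <- function(th) log_prior_conformation(mk(th), m3)
  # difference of the log-prior is kappa * (cos(t1 - mu) - cos(t2 - mu))
  expect_equal(lp(2.0) - lp(2.8), 2.0 * (1 - cos(2.8 - 2.0)))
  expect_gt(lp(2.0), lp(2.9))
  expect_gt(lp(2.0), lp(1.5))
  # absolute value includes the truncated-support normalizer
  expect_equal(lp(2.2), 2.0 * cos(0.2) - m3$log_za)
})

test_that("compaction well adds depth * sum(exp(-r^2/range^2))", {
  base <- polymer_model(n = 6L)
  comp <- polymer_model(n = 6L, compaction = list(depth = 0.3, range = 8))
  conf <- build_chain(base, seed = 9)
  pd2 <- as.matrix(dist(unclass(conf)))^2
  idx <- which(col(pd2) - row(pd2) >= 3, arr.ind = TRUE)
  want <- 0.3 * sum(exp(-pd2[idx] / 64))
  expect_equal(log_prior_conformation(conf, comp) -
                 log_prior_conformation(conf, base), want)
})

test_that("moves are rigid, symmetric and move a contiguous interior block", {
  model <- polymer_model(n = 14L)
  conf <- build_chain(model, seed = 11)
  set.seed(12)
  for (i in 1:200) {
    mv <- if (i %% 2 == 0) "pivot" else "crankshaft"
    prop <- propose_move(conf, move = mv, max_angle = 1.0)
    expect_identical(prop$log_ratio, 0)
    new <- unclass(prop$conf)
    old <- unclass(conf)
    bl <- sqrt(rowSums(diff(new)^2))
    expect_equal(bl, rep(model$b, 13L), tolerance = 1e-9)
    moved <- which(rowSums((new - old)^2) > 1e-18)
    if (length(moved)) {
      expect_true(all(diff(moved) == 1L))  # contiguous block
      if (mv == "pivot") {
        # prefix or suffix of the chain
        expect_true(moved[1L] == 1L || moved[length(moved)] == 14L)
      } else {
        # strictly interior: both axis endpoints stay fixed
        expect_gt(moved[1L], 1L)
        expect_lt(moved[length(moved)], 14L)
      }
    }
    conf <- prop$conf
  }
  expect_error(propose_move(conf, move = "flip"), "unknown move")
})

test_that("bond lengths do not drift over a long move sequence", {
  model <- polymer_model(n = 14L)
  conf <- build_chain(model, seed = 13)
  set.seed(14)
  for (i in 1:2000)
    conf <- propose_move(conf,
                         move = if (i %% 2) "pivot" else "crankshaft")$conf
  bl <- sqrt(rowSums(diff(unclass(conf))^2))
  expect_lt(max(abs(bl - model$b)), 1e-6)
})

test_that("radius of gyration matches hand values and is invariant", {
  expect_equal(radius_of_gyration(conformation(rbind(c(0, 0, 0),
                                                     c(2, 0, 0)))), 1)
  tri <- conformation(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(tri), sqrt(2 / 3))
  conf <- fixture_chain(n = 8)
  rg <- radius_of_gyration(conf)
  shifted <- conformation(unclass(conf) +
                            matrix(c(5, -3, 11), 8, 3, byrow = TRUE))
  expect_equal(radius_of_gyration(shifted), rg)
  R <- refens:::.rotation_matrix(c(1, 2, 3), 0.7)
  rotated <- conformation(unclass(conf) %*% t(R))
  expect_equal(radius_of_gyration(rotated), rg)
})

test_that("prior-only MCMC reproduces the stationary bend-angle law", {
  model <- polymer_model(n = 5L)
  bundle <- polymer_bundle(model, init_seed = 20)
  res <- run_chain(bundle, sampler_config(n_steps = 120000, thin = 25,
                                          seed = 21))
  th <- unlist(lapply(res$conformations,
                      function(cf) refens:::.bend_angles(unclass(cf))))
  cdf <- bend_angle_cdf(model)
  u <- cdf(th)
  ks <- max(abs(sort(u) - seq_along(u) / length(u)),
            abs(sort(u) - (seq_along(u) - 1L) / length(u)))
  expect_lt(ks, 0.03)
  expect_gte(min(th), model$angle_min)
})

test_that("two independent prior chains agree in distribution", {
  model <- polymer_model(n = 14L)
  r1 <- run_chain(polymer_bundle(model, init_seed = 30),
                  sampler_config(n_steps = 60000, thin = 25, seed = 31))
  r2 <- run_chain(polymer_bundle(model, init_seed = 32),
                  sampler_config(n_steps = 60000, thin = 25, seed = 33))
  rg1 <- vapply(r1$conformations, radius_of_gyration, numeric(1))
  rg2 <- vapply(r2$conformations, radius_of_gyration, numeric(1))
  # thin further to reduce autocorrelation before the two-sample test
  p <- suppressWarnings(stats::ks.test(rg1[seq(1, length(rg1), 4)],
                                       rg2[seq(1, length(rg2), 4)]))$p.value
  expect_gt(p, 0.001)
})
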