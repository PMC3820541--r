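test_that("the generator has zero row sums and the full lattice of states", {
  m <- phosphorelay(30, params_ctmc())
  cfg <- stochastic_config(N = 3)
  gen <- build_generator(m, ks = 0.5, cfg)
  expect_equal(nrow(gen$Q), 4^4)
  expect_lt(max(abs(Matrix::rowSums(gen$Q))), 1e-12)
  expect_error(build_generator(m, 1, stochastic_config(N = 50)), "cap")
  # unequal totals cannot map every layer to N molecules
  m2 <- phosphorelay(30, relay_parameters(k2 = 1, k3 = 1, k4 = 1, k3r = 2,
                                          k4r = 2, kh1 = 0.5, kh2 = 0.5,
                                          HK_tot = 2))
  expect_error(build_generator(m2, 1, cfg), "equal")
})

test_that("at zero signal the empty state absorbs all stationary mass", {
  m <- phosphorelay(30, params_ctmc())
  nz <- stationary_noise(m, signals = 0, config = stochastic_config(N = 3))
  expect_equal(nz$mean_fraction, 0)
  expect_equal(nz$sd_fraction, 0)
})

test_that("stationary distributions are proper and solver-consistent", {
  m <- phosphorelay(30, params_ctmc())
  gen <- build_generator(m, ks = 1, stochastic_config(N = 4))
  pi <- phosphorelay:::stationary_distribution(gen$Q)
  expect_true(all(pi >= 0))
  expect_lt(abs(sum(pi) - 1), 1e-10)
  expect_lt(max(abs(as.numeric(pi %*% gen$Q))), 1e-10)
})

test_that("stationary mean approaches the deterministic fraction as N grows", {
  m <- phosphorelay(30, params_ctmc())
  det <- predict(m, 1) / m$params[["RR_tot"]]
  means <- vapply(c(4L, 8L), function(N) {
    stationary_noise(m, signals = 1,
                     config = stochastic_config(N = N))$mean_fraction
  }, 0)
  expect_lt(abs(means[2] - det), abs(means[1] - det))
})

test_that("Gillespie trajectories are seed-reproducible and respect frozen systems", {
  m <- phosphorelay(30, params_ctmc())
  t1 <- simulate(m, nsim = 1, seed = 4, ks = 1, t_end = 20)
  t2 <- simulate(m, nsim = 1, seed = 4, ks = 1, t_end = 20)
  expect_identical(t1, t2)
  # no signal, empty start: nothing ever fires
  t0 <- simulate(m, nsim = 1, seed = 4, ks = 0, t_end = 20)[[1]]
  expect_true(all(t0[, c("HKp", "RECp", "Hptp", "RRp")] == 0))
})

test_that("Gillespie moments agree with the exact stationary solve", {
  set.seed(21)
  for (rep in 1:2) {
    p <- sample_parameter_sets(relay_topology(30), n = 1, seed = 300 + rep,
      scheme = sampling_scheme(bimolecular = c(0.3, 3),
                               hydrolysis = c(0.3, 3),
                               totals = c(0.5, 2)))[[1]]
    m <- phosphorelay(30, p)
    ks <- signal_for_response(m, 0.5 * maximal_response(m))
    cfg <- stochastic_config(N = 6)
    exact <- stationary_noise(m, signals = ks, config = cfg)
    emp <- ssa_moments(m, ks, cfg, t_burn = 100, t_end = 2000,
                       n_samples = 4000)
    expect_lt(abs(emp$mean - exact$mean_fraction), 3 * emp$se_mean + 1e-3)
  }
})
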