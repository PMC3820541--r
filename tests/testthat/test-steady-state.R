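test_that("the elimination map starts at the zero-flux fixed point", {
  m <- phosphorelay(30, params_s2c())
  d <- signal_for_response(m, 0, details = TRUE)
  expect_equal(d$ks, 0)
  expect_equal(d$HKp + d$RECp + d$Hptp, 0)
})

test_that("elimination agrees with ODE steady states on a worked instance", {
  m <- phosphorelay(30, params_s2c())
  alpha <- maximal_response(m)
  for (frac in c(0.25, 0.5, 0.9)) {
    rr <- frac * alpha
    ks <- signal_for_response(m, rr)
    expect_lt(abs(ode_rr_at(m$params, ks) - rr) / rr, 1e-6)
  }
})

test_that("maximal response matches the large-signal ODE limit", {
  m <- phosphorelay(30, params_s2c())
  alpha <- maximal_response(m)
  expect_gt(alpha, 0)
  expect_lte(alpha, m$params[["RR_tot"]])
  expect_lt(abs(ode_rr_at(m$params, 1e6) - alpha) / alpha, 1e-4)
})

test_that("maximal response never increases with the RR hydrolysis rate", {
  base <- unclass(params_s2c())
  alphas <- vapply(c(0.001, 0.01, 0.1, 1, 10), function(kh2) {
    p <- base; p[["kh2"]] <- kh2
    maximal_response(phosphorelay(30, relay_parameters(
      k2 = p[["k2"]], k3 = p[["k3"]], k4 = p[["k4"]], k2r = p[["k2r"]],
      k3r = p[["k3r"]], k4r = p[["k4r"]], kh1 = p[["kh1"]], kh2 = kh2,
      HK_tot = p[["HK_tot"]], REC_tot = p[["REC_tot"]],
      Hpt_tot = p[["Hpt_tot"]], RR_tot = p[["RR_tot"]])))
  }, 0)
  expect_true(all(diff(alphas) <= 0))
})

test_that("without RR hydrolysis the first elimination step reduces as expected", {
  # topology 14: kh2 = 0, so Hpt~P carries only the reverse-transfer load
  p <- bind_parameters(14, relay_parameters(
    k2 = 1, k3 = 0.5, k4 = 0.5, k3r = 5, k4r = 5, kh1 = 1, kh2 = 1))
  m <- phosphorelay(14, p)
  alpha <- maximal_response(m)
  rr <- alpha / 3
  d <- signal_for_response(m, rr, details = TRUE)
  hp_expected <- rr * p[["k4r"]] * p[["Hpt_tot"]] /
    (p[["k4"]] * (p[["RR_tot"]] - rr) + p[["k4r"]] * rr)
  expect_equal(d$Hptp, hp_expected, tolerance = 1e-12)
  expect_gt(d$ks, 0)   # the REC hydrolysis still drives a positive signal
})

test_that("curves use the standard grid and are strictly increasing", {
  m <- phosphorelay(30, params_s2c())
  crv <- signal_response_curve(m)
  expect_equal(nrow(crv), 96L)
  expect_equal(crv$ks[1], 0)
  expect_true(all(diff(crv$ks) > 0))
  alpha <- attr(crv, "alpha")
  expect_equal(max(crv$rr), 0.95 * alpha, tolerance = 1e-12)
  # spot-check grid points against the ODE oracle
  for (i in c(20L, 60L, 90L)) {
    expect_lt(abs(ode_rr_at(m$params, crv$ks[i]) - crv$rr[i]) / crv$rr[i],
              1e-6)
  }
})

test_that("with matched rates, dual hydrolysis saturates at a lower response", {
  p <- relay_parameters(k2 = 1, k3 = 0.5, k4 = 0.5, k3r = 5, k4r = 5,
                        kh1 = 1, kh2 = 1)
  a14 <- maximal_response(phosphorelay(14, p))
  a30 <- maximal_response(phosphorelay(30, p))
  expect_lt(a30, a14)
})

test_that("numerical screen agrees with the structural predicate on all 32", {
  screen <- vapply(1:32, function(id) responsiveness_screen(id), TRUE)
  expect_false(anyNA(screen))
  expect_equal(screen, relay_topologies()$responsive)
  expect_equal(sum(!screen), 14L)
})

test_that("steady-state response is non-decreasing in the signal", {
  set.seed(42)
  tab <- relay_topologies()
  for (id in sample(tab$id[tab$responsive], 4)) {
    m <- phosphorelay(id, random_params(relay_topology(id),
                                        seed = 500 + id))
    ks <- signal_for_response(m, seq(0.05, 0.9, by = 0.05) *
                                maximal_response(m))
    expect_true(all(diff(ks) > 0))
  }
})
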