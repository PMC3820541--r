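variant_zoo <- function() {
  list(variant_spec("turnover", delta = 0),
       variant_spec("hk_autodephos", kd = 0),
       variant_spec("hpt_autodephos", kd = 0),
       variant_spec("complexes"))
}

test_that("every variant reduces exactly to the simple model at zero extras", {
  p <- params_s2c()
  times <- seq(0, 20, length.out = 15)
  rhs <- function(variant) {
    function(t, y, parms) list(relay_derivatives(y, p, ks = 1, variant))
  }
  base <- deSolve::lsoda(relay_state(p), times, rhs(NULL), parms = NULL,
                         rtol = 1e-11, atol = 1e-13)
  for (v in variant_zoo()) {
    init <- c(relay_state(p), variant_extra_state(v))
    sol <- deSolve::lsoda(init, times, rhs(v), parms = NULL,
                          rtol = 1e-11, atol = 1e-13)
    expect_lt(max(abs(sol[, colnames(base)[-1]] - base[, -1])), 1e-9)
  }
  # bifunctional with binding but no catalysis or unbinding cannot be
  # reduced; with k5 = 0 it never forms complex
  p0 <- params_s2a(); p0[["k5"]] <- 0
  v <- variant_spec("bifunctional_hk")
  init <- c(relay_state(p0), C = 0)
  sol <- deSolve::lsoda(init, times, function(t, y, parms)
    list(relay_derivatives(y, p0, 1, v)), parms = NULL,
    rtol = 1e-11, atol = 1e-16)
  expect_true(all(sol[, "C"] == 0))
})

test_that("bifunctional trajectories conserve the extended classes", {
  p <- params_s2a()
  v <- variant_spec("bifunctional_hk")
  init <- c(relay_state(p), C = 0)
  times <- seq(0, 2000, length.out = 20)
  sol <- deSolve::lsoda(init, times, function(t, y, parms)
    list(relay_derivatives(y, p, ks = 0.01, v)), parms = NULL,
    rtol = 1e-11, atol = 1e-18)
  hk_class <- sol[, "HK"] + sol[, "HKp"] + sol[, "C"]
  rec_class <- sol[, "REC"] + sol[, "RECp"] + sol[, "C"]
  expect_lt(max(abs(hk_class - p[["HK_tot"]])) / p[["HK_tot"]], 1e-8)
  expect_lt(max(abs(rec_class - p[["REC_tot"]])) / p[["REC_tot"]], 1e-8)
  # the fast-kinetics set settles with measurable complex occupancy
  ss <- phosphorelay:::ode_steady_state(p, ks = 0.01, variant = v)
  expect_true(ss$converged)
  expect_gt(ss$state[["C"]], 0)
})

test_that("drain-variant eliminations agree with their own ODE steady states", {
  p <- params_s2c()
  for (v in list(variant_spec("turnover", delta = 0.05),
                 variant_spec("hpt_autodephos", kd = 0.3),
                 variant_spec("hk_autodephos", kd = 0.3))) {
    m <- phosphorelay(30, p, v)
    alpha <- maximal_response(m)
    rr <- 0.4 * alpha
    ks <- signal_for_response(m, rr)
    ss <- phosphorelay:::ode_steady_state(p, ks, v)
    expect_true(ss$converged)
    expect_lt(abs(ss$state[["RRp"]] - rr) / rr, 1e-6)
  }
})

test_that("a bifunctional kinase shifts the curve right without changing its ceiling", {
  p <- params_s2a()
  mono_p <- p; mono_p[["k5"]] <- 0; mono_p[["k5r"]] <- 0; mono_p[["k6"]] <- 0
  mono <- phosphorelay(30, mono_p)
  bif <- phosphorelay(30, p, variant_spec("bifunctional_hk"))
  a_mono <- maximal_response(mono)
  a_bif <- maximal_response(bif)
  expect_equal(a_bif, a_mono, tolerance = 1e-6)
  expect_gt(half_maximal_signal(bif), half_maximal_signal(mono))
  # semi-analytic bifunctional elimination against the ODE oracle
  rr <- 0.5 * a_bif
  ks <- signal_for_response(bif, rr)
  ss <- phosphorelay:::ode_steady_state(p, ks,
                                        variant_spec("bifunctional_hk"))
  expect_true(ss$converged)
  expect_lt(abs(ss$state[["RRp"]] - rr) / rr, 1e-5)
})

test_that("relaxed-assumption variants admit sigmoidality beyond the simple rules", {
  chk_hpt <- variant_condition_checks("hpt_autodephos", seed = 31,
                                      n_draws = 300, n_witness = 500)
  expect_true(chk_hpt$witness_kh1_k3r_zero$satisfied)
  expect_true(chk_hpt$necessity$satisfied)
  w <- chk_hpt$witness_kh1_k3r_zero$witness
  expect_identical(unname(w$params[c("kh1", "k3r")]), c(0, 0))
  expect_gt(w$params[["k4r"]], w$params[["k4"]])

  chk_to <- variant_condition_checks("turnover", seed = 32,
                                     n_draws = 300, n_witness = 500)
  expect_true(chk_to$witness_kh1_k3r_zero$satisfied)
  expect_true(chk_to$necessity$satisfied)

  chk_hk <- variant_condition_checks("hk_autodephos", seed = 33,
                                     n_draws = 400)
  expect_true(chk_hk$necessity$satisfied)

  # the HK-mediated dephosphorylation can stand in for REC hydrolysis
  chk_bf <- variant_condition_checks("bifunctional_hk", seed = 44,
                                     n_witness = 300)
  expect_true(chk_bf$witness_no_rec_hydrolysis$satisfied)
  expect_identical(chk_bf$witness_no_rec_hydrolysis$witness$params[["kh1"]], 0)
})

test_that("variant curves are monotone in the signal", {
  p <- params_s2c()
  m <- phosphorelay(30, p, variant_spec("complexes", on = c(5, 5, 5),
                                        off = c(1, 1, 1), cat = c(2, 2, 2)))
  crv <- variant_steady_curve(m, n_points = 9, span = 1.5)
  expect_true(all(diff(crv$rr) > 0))
  expect_true(all(crv$rr < attr(crv, "alpha") * (1 + 1e-6)))
})
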