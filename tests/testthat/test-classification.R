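# A minimal analytic stand-in: a "phosphorelay" whose elimination map f is
# given in closed form, for validating the classifiers against curves with
# known shape.
analytic_relay <- function(f, alpha = 1) {
  structure(list(f = function(rr) list(ks = f(rr),
                                       feasible = rr >= 0 & rr < alpha),
                 responsive = TRUE, alpha = alpha,
                 params = c(RR_tot = alpha), kind = "analytic"),
            class = "phosphorelay")
}

test_that("sign-change classification separates saturating from inflected curves", {
  mm <- analytic_relay(function(rr) rr / (1 - rr))          # R = s/(1+s)
  hill2 <- analytic_relay(function(rr) sqrt(rr / (1 - rr))) # R = s^2/(1+s^2)
  expect_equal(classify(mm, method = "sign_change")$label, "hyperbolic")
  expect_equal(classify(hill2, method = "sign_change")$label, "sigmoidal")
})

test_that("Hill coefficients of reference curves are exact", {
  mm <- function(s) s / (1 + s)
  hill2 <- function(s) s^2 / (1 + s^2)
  hill4 <- function(s) s^4 / (1 + s^4)
  expect_equal(hill_coefficient(mm, alpha = 1), 1, tolerance = 1e-6)
  expect_equal(hill_coefficient(hill2, alpha = 1), 2, tolerance = 1e-6)
  expect_equal(hill_coefficient(hill4, alpha = 1), 4, tolerance = 1e-6)
})

test_that("Hill coefficient from a sampled curve matches the exact map", {
  m <- phosphorelay(30, params_s2c())
  dense <- signal_response_curve(m, n_intervals = 10000L)
  expect_equal(hill_coefficient(dense), hill_coefficient(m),
               tolerance = 1e-6)
  # curves stopping short of 90% of alpha cannot support the estimate
  short <- signal_response_curve(m, upper = 0.5)
  expect_true(is.na(hill_coefficient(short)))
})

test_that("necessary conditions follow the printed rule with strict inequalities", {
  ok <- necessary_conditions(relay_parameters(
    k2 = 2, k3 = 1, k4 = 0.5, k2r = 1, k3r = 2, k4r = 0.5, kh1 = 1))
  expect_true(ok$sigmoidal_possible)
  # kh1 = 0 fails condition (i)
  expect_false(necessary_conditions(relay_parameters(
    k2 = 2, k3 = 1, k4 = 0.5, k2r = 1, k3r = 2, kh1 = 0))$sigmoidal_possible)
  # boundary equalities fail (iii)
  expect_false(necessary_conditions(relay_parameters(
    k2 = 2, k3 = 1, k4 = 1, k2r = 1, k3r = 1, k4r = 1,
    kh1 = 1))$sigmoidal_possible)
  # k3r = 0 is ruled out even when the sums favor reversal
  res <- necessary_conditions(relay_parameters(
    k2 = 2, k3 = 0.1, k4 = 0.1, k2r = 0, k3r = 0, k4r = 10, kh1 = 1))
  expect_false(res$sigmoidal_possible)
  expect_false(res$conditions[["k3r_positive"]])
})

test_that("violating any printed condition forces negative curvature at zero", {
  set.seed(7)
  tab <- relay_topologies()
  resp <- tab$id[tab$responsive]
  n_checked <- 0L
  for (rep in 1:60) {
    id <- sample(resp, 1)
    topo <- relay_topology(id)
    p <- unclass(random_params(topo, seed = 900 + rep))
    mode <- sample(c("kh1", "k2r", "forward"), 1)
    if (mode == "kh1" && topo$h1 == 1L) next   # cannot zero a flagged rate
    if (mode == "kh1") p[["kh1"]] <- 0
    if (mode == "k2r") {
      if (topo$r2 == 0L) next
      p[["k2r"]] <- p[["k2"]] * (1 + runif(1))          # k2 < k2r
    }
    if (mode == "forward") {                            # k3 > k3r, k3 k4 > k3r k4r
      p[["k3"]] <- max(p[["k3"]], p[["k3r"]]) * (1 + runif(1))
      p[["k4"]] <- max(p[["k4"]], p[["k4r"]]) * (1 + runif(1))
    }
    m <- phosphorelay(topo, do.call(relay_parameters, as.list(p)))
    curv <- tryCatch(curvature_at_zero(m), error = function(e) NA_real_)
    if (is.na(curv)) next
    expect_lt(curv, 0)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 20L)
})

test_that("exact curvature agrees with an ODE finite-difference oracle in sign and value", {
  for (p in list(params_s2c(),
                 bind_parameters(14, relay_parameters(
                   k2 = 1, k3 = 0.5, k4 = 0.5, k3r = 5, k4r = 5,
                   kh1 = 1, kh2 = 1)))) {
    id <- if (p[["kh2"]] > 0) 30 else 14
    m <- phosphorelay(id, p)
    curv <- curvature_at_zero(m)
    alpha <- maximal_response(m)
    h <- signal_for_response(m, 0.02 * alpha) / 3
    rr <- vapply(h * (0:3), function(ks)
      if (ks == 0) 0 else ode_rr_at(m$params, ks), 0)
    d2 <- (2 * rr[1] - 5 * rr[2] + 4 * rr[3] - rr[4]) / h^2
    expect_equal(sign(d2), sign(curv))
    expect_equal(d2, curv, tolerance = 0.05)
  }
})

test_that("both classifiers label a sigmoidal-regime worked instance alike", {
  m <- phosphorelay(30, params_s2c())
  expect_equal(classify(m)$label, "sigmoidal")
  expect_equal(classify(m, method = "sign_change")$label, "sigmoidal")
  expect_gt(hill_coefficient(m), 1)
})
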