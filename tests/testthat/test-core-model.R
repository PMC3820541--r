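test_that("mass-action derivatives respect the conservation classes", {
  set.seed(11)
  for (rep in 1:20) {
    topo <- relay_topology(sample(32, 1))
    p <- random_params(topo, seed = 100 + rep)
    s <- relay_state(p, HKp = runif(1) * p[["HK_tot"]],
                     RECp = runif(1) * p[["REC_tot"]],
                     Hptp = runif(1) * p[["Hpt_tot"]],
                     RRp = runif(1) * p[["RR_tot"]])
    d <- relay_derivatives(s, p, ks = runif(1))
    expect_equal(d[["HK"]] + d[["HKp"]], 0)
    expect_equal(d[["REC"]] + d[["RECp"]], 0, tolerance = 1e-12)
    expect_equal(d[["Hpt"]] + d[["Hptp"]], 0)
    expect_equal(d[["RR"]] + d[["RRp"]], 0, tolerance = 1e-12)
  }
})

test_that("zero-flux and isolated-hydrolysis limits are exact", {
  p <- params_s2c()
  d0 <- relay_derivatives(relay_state(p), p, ks = 0)
  expect_true(all(d0 == 0))
  # only RR~P present: its derivative is pure first-order hydrolysis
  s <- relay_state(p, RRp = 0.3)
  s[["Hpt"]] <- 0  # remove the reverse-transfer partner
  d <- relay_derivatives(s, p, ks = 0)
  expect_equal(d[["RRp"]], -p[["kh2"]] * 0.3)
})

test_that("trajectories conserve totals and stay non-negative", {
  p <- params_s2c()
  rhs <- function(t, y, parms) list(relay_derivatives(y, p, ks = 1))
  sol <- deSolve::lsoda(relay_state(p), seq(0, 50, length.out = 40), rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  y <- sol[, -1]
  expect_true(all(y > -1e-10))
  totals <- cbind(y[, "HK"] + y[, "HKp"], y[, "REC"] + y[, "RECp"],
                  y[, "Hpt"] + y[, "Hptp"], y[, "RR"] + y[, "RRp"])
  ref <- matrix(p[c("HK_tot", "REC_tot", "Hpt_tot", "RR_tot")],
                nrow(totals), 4, byrow = TRUE)
  expect_lt(max(abs(totals - ref) / ref), 1e-8)
})
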