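test_that("sampling is seeded, respects the scheme and the topology flags", {
  topo <- relay_topology(14)
  a <- sample_parameter_sets(topo, n = 20, seed = 5)
  b <- sample_parameter_sets(topo, n = 20, seed = 5)
  expect_identical(a, b)
  c1 <- sample_parameter_sets(topo, n = 20, seed = 6)
  expect_false(identical(unclass(a[[1]]), unclass(c1[[1]])))
  for (p in a) {
    expect_identical(unname(p[c("k2r", "kh2")]), c(0, 0))
    expect_true(all(p[c("k3r", "k4r", "kh1")] > 0))
    totals <- p[c("HK_tot", "REC_tot", "Hpt_tot", "RR_tot")]
    expect_equal(max(totals) - min(totals), 0)   # equal-totals mode
  }
  free <- sample_parameter_sets(topo, n = 5, seed = 5,
                                scheme = sampling_scheme(totals_mode = "free"))
  spread <- vapply(free, function(p)
    diff(range(p[c("HK_tot", "REC_tot", "Hpt_tot", "RR_tot")])), 0)
  expect_true(all(spread > 0))
  expect_error(sampling_scheme(bimolecular = c(2, 1)), "low < high")
})

test_that("draws honor the configured ranges", {
  sc <- sampling_scheme(bimolecular = c(0.5, 2), hydrolysis = c(0.1, 0.2),
                        totals = c(1, 3))
  # topology 32 keeps every reaction, so all rates must land in-range
  sets <- sample_parameter_sets(relay_topology(32), n = 50, seed = 2,
                                scheme = sc)
  for (p in sets) {
    expect_true(all(p[c("k2", "k3", "k4", "k2r", "k3r", "k4r")] >= 0.5 &
                      p[c("k2", "k3", "k4", "k2r", "k3r", "k4r")] <= 2))
    expect_true(all(p[c("kh1", "kh2")] >= 0.1 & p[c("kh1", "kh2")] <= 0.2))
    expect_true(p[["HK_tot"]] >= 1 && p[["HK_tot"]] <= 3)
  }
})

test_that("surveys are reproducible and structural zeros are exact", {
  s1 <- survey_topologies(ids = c(8, 25), n = 200, seed = 3)
  s2 <- survey_topologies(ids = c(8, 25), n = 200, seed = 3)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # kh1 == 0 (topology 8) and k3r == 0 (topology 25) forbid sigmoidality
  expect_equal(s1$pct_sigmoidal, c(0, 0))
  s3 <- survey_topologies(ids = c(8, 25), n = 200, seed = 77,
                          scheme = sampling_scheme(bimolecular = c(1e-3, 1e3)))
  expect_equal(s3$pct_sigmoidal, c(0, 0))
  expect_error(survey_topologies(ids = 9, n = 10, seed = 1),
               "non-responsive")
})

test_that("the tunable topologies carry the largest sigmoidal fractions", {
  sv <- survey_topologies(ids = c(14, 16, 26, 29, 30, 32), n = 400, seed = 9)
  top2 <- sv$id[order(sv$pct_sigmoidal, decreasing = TRUE)][1:2]
  expect_setequal(top2, c(14, 30))
})

test_that("reverse transfer dominates the forward rates in the sigmoidal regime", {
  for (id in c(14, 30)) {
    rs <- regime_ratio_summary(id, n = 300, seed = 11)
    means <- rs[rs$stat == "mean", ]
    expect_true(all(means$sigmoidal < means$hyperbolic))
    # ratio distributions are heavy-tailed over the broad ranges, so the
    # regime signature is cleanest in the medians: reverse-dominant
    # (ratio < 1) in the sigmoidal regime, forward-dominant above 1
    topo <- relay_topology(id)
    sets <- sample_parameter_sets(topo, n = 300, seed = 11 + id)
    lab <- vapply(sets, function(p)
      classify(phosphorelay(topo, p))$label, "")
    for (ratio in list(c("k3", "k3r"), c("k4", "k4r"))) {
      r <- vapply(sets, function(p) p[[ratio[1]]] / p[[ratio[2]]], 0)
      expect_lt(stats::median(r[lab == "sigmoidal"]), 1)
      expect_gt(stats::median(r[lab == "hyperbolic"]), 1)
    }
  }
})
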