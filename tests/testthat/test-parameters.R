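test_that("binding zeroes absent rates and rejects degenerate instances", {
  p <- relay_parameters(k2 = 1, k3 = 1, k4 = 1, k2r = 7, k3r = 2, k4r = 2,
                        kh1 = 1, kh2 = 1)
  b14 <- bind_parameters(14, p)
  expect_identical(b14[["k2r"]], 0)   # topology 14 has no HK<-REC reverse
  expect_identical(b14[["kh2"]], 0)
  expect_identical(b14[["k3r"]], 2)
  # worked set for topology 30 passes through unchanged
  expect_equal(unclass(bind_parameters(30, params_s2c())),
               unclass(params_s2c()))
  # hydrolysis-free block zeroes both hydrolysis rates
  b19 <- bind_parameters(relay_topology(rev = c(0, 0, 1), hyd = c(0, 0)), p)
  expect_identical(unname(b19[c("kh1", "kh2")]), c(0, 0))
  # a rate the topology requires must be positive
  p0 <- p; p0[["k3r"]] <- 0
  expect_error(bind_parameters(14, p0), "degenerate")
  expect_error(relay_parameters(k2 = 0, k3 = 1, k4 = 1), "> 0")
})

test_that("parameter sets round-trip through CSV and config files", {
  p <- params_s2c()
  csv <- tempfile(fileext = ".csv")
  df <- as.data.frame(as.list(unclass(p)))
  write.csv(df, csv, row.names = FALSE)
  got <- read_parameter_sets(csv)
  expect_length(got, 1L)
  expect_equal(unclass(got[[1]]), unclass(p))

  cfg <- tempfile(fileext = ".yml")
  writeLines(sprintf("%s: %.10g", names(p), as.numeric(p)), cfg)
  expect_equal(unclass(read_relay_config(cfg)), unclass(p))
  writeLines(c("k2: 1", "bogus: 3"), cfg)
  expect_error(read_relay_config(cfg), "unknown parameter")
})
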