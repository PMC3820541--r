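# Shared fixtures: worked parameter sets and small oracles.

# Strong-reverse-transfer relay (tunable regime), topology 30
params_s2c <- function() {
  relay_parameters(k2 = 5, k3 = 0.1, k4 = 0.01, k2r = 0, k3r = 10,
                   k4r = 0.10, kh1 = 10, kh2 = 0.001,
                   HK_tot = 5, REC_tot = 1, Hpt_tot = 1, RR_tot = 10)
}

# Fast-kinetics set with bifunctional rates (sigmoidal regime)
params_s2a <- function() {
  relay_parameters(k2 = 9343, k3 = 30201, k4 = 35826, k2r = 0, k3r = 7192,
                   k4r = 99251, kh1 = 0.0302, kh2 = 0.00234,
                   k5 = 1000, k5r = 0.012, k6 = 3.5,
                   HK_tot = 1.2748e-4, REC_tot = 1.5755e-4,
                   Hpt_tot = 1.3634e-4, RR_tot = 1.2516e-4)
}

# Moderate equal-totals set usable for CTMC work, topology 30
params_ctmc <- function() {
  relay_parameters(k2 = 1, k3 = 1, k4 = 1, k3r = 2, k4r = 2,
                   kh1 = 0.5, kh2 = 0.5)
}

ode_rr_at <- function(params, ks, variant = NULL) {
  ss <- phosphorelay:::ode_steady_state(params, ks, variant)
  expect_true(ss$converged)
  ss$state[["RRp"]]
}

# Random bound parameter set for a topology (present rates positive).
random_params <- function(topology, seed) {
  sample_parameter_sets(topology, n = 1L, seed = seed)[[1]]
}
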