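#' @useDynLib phosphorelay, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

species_names <- function() {
  c("HK", "HKp", "REC", "RECp", "Hpt", "Hptp", "RR", "RRp")
}

#' Assemble a full relay state from phosphorylated amounts
#'
#' @param params A `"relay_parameters"` vector (totals are taken from it).
#' @param HKp,RECp,Hptp,RRp Phosphorylated concentrations (default 0).
#' @return Named numeric state vector `(HK, HKp, REC, RECp, Hpt, Hptp, RR,
#'   RRp)` satisfying the per-layer conservation laws.
#' @export
relay_state <- function(params, HKp = 0, RECp = 0, Hptp = 0, RRp = 0) {
  p <- as_relay_parameters(params)
  s <- c(HK = p[["HK_tot"]] - HKp, HKp = HKp,
         REC = p[["REC_tot"]] - RECp, RECp = RECp,
         Hpt = p[["Hpt_tot"]] - Hptp, Hptp = Hptp,
         RR = p[["RR_tot"]] - RRp, RRp = RRp)
  if (any(s < -1e-12 * max(p[c("HK_tot", "REC_tot", "Hpt_tot", "RR_tot")])))
    stop("phosphorylated amounts exceed layer totals")
  s
}

# Mass-action right-hand side of the simple (monofunctional) relay.
# state: (HK, HKp, REC, RECp, Hpt, Hptp, RR, RRp); ks is the signal.
relay_rhs_simple <- function(state, p, ks) {
  J2 <- p[["k2"]] * state[["HKp"]] * state[["REC"]] -
    p[["k2r"]] * state[["HK"]] * state[["RECp"]]
  J3 <- p[["k3"]] * state[["RECp"]] * state[["Hpt"]] -
    p[["k3r"]] * state[["REC"]] * state[["Hptp"]]
  J4 <- p[["k4"]] * state[["Hptp"]] * state[["RR"]] -
    p[["k4r"]] * state[["RRp"]] * state[["Hpt"]]
  h1 <- p[["kh1"]] * state[["RECp"]]
  h2 <- p[["kh2"]] * state[["RRp"]]
  auto <- ks * state[["HK"]]
  c(HK = -auto + J2, HKp = auto - J2,
    REC = -J2 + J3 + h1, RECp = J2 - J3 - h1,
    Hpt = -J3 + J4, Hptp = J3 - J4,
    RR = -J4 + h2, RRp = J4 - h2)
}

#' Time derivatives of a relay state
#'
#' Evaluates the mass-action right-hand side of the relay ODE system at a
#' given state.  Within each conservation class (one per layer) the
#' derivatives sum exactly to zero for the conserved variants.
#'
#' @param state Named state vector as produced by [relay_state()] (variants
#'   append their extra species, see [variant_state()]).
#' @param params Parameter vector.
#' @param ks Signal: the HK auto-phosphorylation rate constant (time^-1).
#' @param variant `NULL` for the simple model, or a `"variant_spec"`.
#' @return Named vector of time derivatives.
#' @export
relay_derivatives <- function(state, params, ks, variant = NULL) {
  p <- as_relay_parameters(params)
  if (is.null(variant)) return(relay_rhs_simple(state, p, ks))
  variant_rhs(state, p, ks, variant)
}

# Integrate to steady state: advance the stiff solver over a doubling
# horizon until the derivative norm criterion max|ds/dt| < rtol * scale is
# met (scale = largest layer total).  Returns the state plus diagnostics.
ode_steady_state <- function(params, ks, variant = NULL, init = NULL,
                             rtol = 1e-9, t0 = NULL, max_doublings = 48L) {
  p <- as_relay_parameters(params)
  if (is.null(init)) init <- initial_state(p, variant)
  scale <- max(p[c("HK_tot", "REC_tot", "Hpt_tot", "RR_tot")])
  rhs <- function(t, y, parms) list(relay_derivatives(y, p, ks, variant))
  # initial horizon spanning the slowest first-order scale present
  if (is.null(t0)) {
    first_order <- c(ks, p[c("kh1", "kh2", "k6")],
                     p[c("k2", "k3", "k4")] * scale)
    first_order <- first_order[first_order > 0]
    t0 <- 1 / min(first_order)
  }
  y <- init
  t_end <- t0
  for (i in seq_len(max_doublings)) {
    sol <- deSolve::lsoda(y, c(0, t_end), rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12 * scale, maxsteps = 5e5)
    y <- sol[nrow(sol), -1L]
    dy <- relay_derivatives(y, p, ks, variant)
    if (max(abs(dy)) < rtol * scale) {
      # a small derivative can mask glacial drift (or a truncated stiff
      # integration); confirm by integrating one more horizon
      sol2 <- deSolve::lsoda(y, c(0, t_end), rhs, parms = NULL,
                             rtol = 1e-10, atol = 1e-12 * scale,
                             maxsteps = 5e5)
      y2 <- sol2[nrow(sol2), -1L]
      if (max(abs(y2 - y)) < 1e-8 * scale)
        return(list(state = pmax(y2, 0), converged = TRUE, t = t_end))
      y <- y2
    }
    t_end <- t_end * 2
  }
  list(state = pmax(y, 0), converged = FALSE, t = t_end)
}

initial_state <- function(p, variant = NULL) {
  s <- relay_state(p)
  if (!is.null(variant)) s <- c(s, variant_extra_state(variant))
  s
}
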