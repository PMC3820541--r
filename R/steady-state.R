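# Layer-by-layer flux-balance elimination.
#
# At steady state the net phosphotransfer flux into each layer balances the
# first-order losses below it, which makes the system triangular when read
# from the bottom (RR) up: given the response level rr = [RR~P], each
# phosphorylated intermediate solves a single linear equation, and the
# signal ks follows from the HK balance.  The function f with ks = f(rr) is
# the inverse of the signal-response curve.
#
# `drains` carries optional extra first-order losses (turnover dilution and
# auto-dephosphorylation variants): d_hk on HK~P, d_rec on REC~P, d_hpt on
# Hpt~P, d_rr on RR~P.  The simple model has all four at zero.

zero_drains <- function() c(d_hk = 0, d_rec = 0, d_hpt = 0, d_rr = 0)

# Vectorized over rr.  Returns list of vectors: ks, Hptp, RECp, HKp, feasible.
relay_eliminate <- function(rr, p, drains = zero_drains()) {
  h2 <- p[["kh2"]] + drains[["d_rr"]]
  h1 <- p[["kh1"]] + drains[["d_rec"]]
  HKt <- p[["HK_tot"]]; RECt <- p[["REC_tot"]]
  Hptt <- p[["Hpt_tot"]]; RRt <- p[["RR_tot"]]

  den1 <- p[["k4"]] * (RRt - rr) + p[["k4r"]] * rr
  hp <- rr * (h2 + p[["k4r"]] * Hptt) / den1

  rhs2 <- h2 * rr + drains[["d_hpt"]] * hp
  den2 <- p[["k3"]] * (Hptt - hp) + p[["k3r"]] * hp
  rp <- (rhs2 + p[["k3r"]] * hp * RECt) / den2

  J2 <- rhs2 + h1 * rp
  den3 <- p[["k2"]] * (RECt - rp) + p[["k2r"]] * rp
  kp <- (J2 + p[["k2r"]] * rp * HKt) / den3

  ks <- (J2 + drains[["d_hk"]] * kp) / (HKt - kp)

  tol <- 1e-12
  feasible <- is.finite(ks) & ks >= 0 & rr >= 0 & rr <= RRt &
    den1 > 0 & den2 > 0 & den3 > 0 &
    hp >= -tol * Hptt & hp <= Hptt * (1 + tol) &
    rp >= -tol * RECt & rp <= RECt * (1 + tol) &
    kp >= -tol * HKt & kp < HKt
  list(ks = ks, Hptp = hp, RECp = rp, HKp = kp, feasible = feasible)
}

# Same elimination on second-order jets at a point rr0 (usually 0):
# returns the jets of ks and of the intermediates.
relay_eliminate_jet <- function(rr0, p, drains = zero_drains()) {
  h2 <- p[["kh2"]] + drains[["d_rr"]]
  h1 <- p[["kh1"]] + drains[["d_rec"]]
  HKt <- p[["HK_tot"]]; RECt <- p[["REC_tot"]]
  Hptt <- p[["Hpt_tot"]]; RRt <- p[["RR_tot"]]
  rr <- jet_var(rr0)

  den1 <- jet_add(jet_mul(jet_const(p[["k4"]]), jet_sub(jet_const(RRt), rr)),
                  jet_mul(jet_const(p[["k4r"]]), rr))
  hp <- jet_div(jet_mul(rr, jet_const(h2 + p[["k4r"]] * Hptt)), den1)

  rhs2 <- jet_add(jet_mul(jet_const(h2), rr),
                  jet_mul(jet_const(drains[["d_hpt"]]), hp))
  den2 <- jet_add(jet_mul(jet_const(p[["k3"]]), jet_sub(jet_const(Hptt), hp)),
                  jet_mul(jet_const(p[["k3r"]]), hp))
  rp <- jet_div(jet_add(rhs2, jet_mul(jet_const(p[["k3r"]] * RECt), hp)), den2)

  J2 <- jet_add(rhs2, jet_mul(jet_const(h1), rp))
  den3 <- jet_add(jet_mul(jet_const(p[["k2"]]), jet_sub(jet_const(RECt), rp)),
                  jet_mul(jet_const(p[["k2r"]]), rp))
  kp <- jet_div(jet_add(J2, jet_mul(jet_const(p[["k2r"]] * HKt), rp)), den3)

  ks <- jet_div(jet_add(J2, jet_mul(jet_const(drains[["d_hk"]]), kp)),
                jet_sub(jet_const(HKt), kp))
  list(ks = ks, Hptp = hp, RECp = rp, HKp = kp)
}

#' Signal required for a given steady-state response
#'
#' Evaluates the steady-state relation `ks = f(rr)`: the HK
#' auto-phosphorylation rate that holds phosphorylated RR at level `rr`.
#' Computed by exact sequential solution of the per-layer flux balances from
#' the bottom of the relay upward.
#'
#' @param object A `"phosphorelay"` model.
#' @param rr Response level(s), concentrations of phosphorylated RR in
#'   `[0, alpha)`.
#' @param details If `TRUE`, also return the steady-state phosphorylated
#'   intermediates.
#' @return Numeric vector of signals, or (with `details`) a data frame with
#'   columns `rr`, `ks`, `HKp`, `RECp`, `Hptp`, `feasible`.  Infeasible `rr`
#'   (at or beyond the maximal response) yield `NA`.
#' @seealso [maximal_response()], [signal_response_curve()]
#' @export
signal_for_response <- function(object, rr, details = FALSE) {
  stopifnot(inherits(object, "phosphorelay"))
  e <- object$f(rr)
  if (details)
    return(data.frame(rr = rr, ks = ifelse(e$feasible, e$ks, NA_real_),
                      HKp = e$HKp, RECp = e$RECp, Hptp = e$Hptp,
                      feasible = e$feasible))
  ifelse(e$feasible, e$ks, NA_real_)
}

# Feasibility bisection for the maximal response: alpha is the supremum of
# response levels rr for which the elimination stays within the physical
# simplex and the signal is finite.  lo is always feasible, hi infeasible.
alpha_bisect <- function(fun, RRt, rtol = 1e-10) {
  if (fun(RRt)) return(RRt)
  lo <- 0; hi <- RRt
  while ((hi - lo) > rtol * hi) {
    mid <- 0.5 * (lo + hi)
    if (fun(mid)) lo <- mid else hi <- mid
    if (hi < .Machine$double.xmin) break
  }
  0.5 * (lo + hi)
}

#' Maximal steady-state response
#'
#' The maximal possible level of phosphorylated RR, `alpha`: the supremum of
#' response levels attainable at any finite signal, equal to the
#' large-signal limit of steady-state RR~P.  Located by bisection on the
#' feasibility boundary of the elimination, to relative tolerance 1e-10.
#'
#' @param object A responsive `"phosphorelay"` model.
#' @return `alpha`, a concentration in `(0, RR_tot]`.
#' @export
maximal_response <- function(object) {
  stopifnot(inherits(object, "phosphorelay"))
  if (!object$responsive)
    stop("non-responsive relay: the response is at its maximum for any ",
         "positive signal, so no signal-response curve exists")
  if (!is.null(object$alpha)) return(object$alpha)
  alpha_bisect(function(r) object$f(r)$feasible[1], object$params[["RR_tot"]])
}

#' Steady-state signal-response curve
#'
#' Samples the signal-response relation on the standard grid: response
#' levels from 0 to `0.95 * alpha` in steps of `alpha / 100` (96 points),
#' with the matching signals from the exact elimination.  By the plotting
#' convention the signal goes on the x axis and the response on y.
#'
#' @param object A responsive `"phosphorelay"` model.
#' @param n_intervals Number of `alpha/n` increments per step (default 100,
#'   giving the 0, alpha/100, ..., 0.95 alpha grid).
#' @param upper Top of the grid as a fraction of `alpha` (default 0.95).
#' @return A data frame of class `"signal_response_curve"` with columns
#'   `rr` (response), `fraction` (`rr / RR_tot`) and `ks` (signal), plus
#'   attributes `alpha`, `topology_id` and `parameters`.
#' @examples
#' m <- phosphorelay(30, relay_parameters(
#'   k2 = 5, k3 = 0.1, k4 = 0.01, k3r = 10, k4r = 0.1, kh1 = 10,
#'   kh2 = 0.001, HK_tot = 5, REC_tot = 1, Hpt_tot = 1, RR_tot = 10))
#' crv <- signal_response_curve(m)
#' head(crv)
#' @export
signal_response_curve <- function(object, n_intervals = 100L, upper = 0.95) {
  stopifnot(inherits(object, "phosphorelay"))
  alpha <- maximal_response(object)
  rr <- seq(0, upper * alpha, by = alpha / n_intervals)
  e <- object$f(rr)
  if (!all(e$feasible))
    stop("infeasible grid point below 0.95 alpha; alpha location failed")
  structure(data.frame(rr = rr, fraction = rr / object$params[["RR_tot"]],
                       ks = e$ks),
            alpha = alpha, topology_id = object$topology$id,
            parameters = object$params,
            class = c("signal_response_curve", "data.frame"))
}

#' @export
plot.signal_response_curve <- function(x, ...,
                                       xlab = "signal k_s",
                                       ylab = "phosphorylated RR") {
  graphics::plot(x$ks, x$rr, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Numerical responsiveness screen
#'
#' Integrates the relay ODE to steady state at two widely separated signals
#' (six decades apart by default) and reports the relay responsive when the
#' steady-state phosphorylated RR levels differ by more than 1% of the RR
#' total.  With generic positive parameters this agrees with the structural
#' predicate [is_responsive()] on all 32 topologies.
#'
#' @param topology A `"relay_topology"` or integer id.
#' @param params Parameters; default: every rate present in the topology set
#'   to 1 and all totals 1.
#' @param signals Length-2 signal vector (default `c(1e-6, 1)`).
#' @param tol_fraction Response difference (as a fraction of `RR_tot`)
#'   above which the relay counts as responsive.
#' @return `TRUE`/`FALSE`, or `NA` when either integration failed to reach
#'   steady state (indeterminate).
#' @export
responsiveness_screen <- function(topology, params = NULL,
                                  signals = c(1e-6, 1),
                                  tol_fraction = 0.01) {
  topology <- as_relay_topology(topology)
  if (is.null(params)) params <- generic_parameters(topology)
  p <- bind_parameters(topology, params)
  ss <- lapply(signals, function(ks) ode_steady_state(p, ks))
  if (!all(vapply(ss, `[[`, TRUE, "converged"))) return(NA)
  rrp <- vapply(ss, function(s) s$state[["RRp"]], 0)
  abs(diff(range(rrp))) > tol_fraction * p[["RR_tot"]]
}

generic_parameters <- function(topology) {
  topology <- as_relay_topology(topology)
  relay_parameters(k2 = 1, k3 = 1, k4 = 1,
                   k2r = topology$r2, k3r = topology$r3, k4r = topology$r4,
                   kh1 = topology$h1, kh2 = topology$h2,
                   HK_tot = 1, REC_tot = 1, Hpt_tot = 1, RR_tot = 1)
}
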