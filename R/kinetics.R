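#' Step-response switching time
#'
#' Time for the relay output to settle at a new steady state after a 10%
#' step in the signal.  The basal operating point is specified as a
#' fraction of the maximal response: the basal signal is
#' `ks* = f(basal_fraction * alpha)` (the signal that holds the output at
#' that response level), which keeps the protocol dimensionally consistent
#' across parameter sets.  The system starts at the exact steady state for
#' `ks*`, the signal steps to `1.1 ks*` (up) or `0.9 ks*` (down), and the
#' stiff ODE is integrated until phosphorylated RR stays within a band of
#' 1% of the net change around the new steady state; settlement is
#' confirmed over a doubled horizon before the time is returned.
#'
#' @param object A responsive simple-model `"phosphorelay"` (or a
#'   drain-type variant with a closed elimination).
#' @param basal_fraction Basal response level as a fraction of `alpha`
#'   (0.2, 0.5 or 0.8 in the standard protocol).
#' @param direction `"up"` (10% signal increase) or `"down"` (decrease).
#' @param step_size Relative step (default 0.1).
#' @param n_out Output-grid size per integration window.
#' @return A list of class `"response_time"`: `time` (settling time),
#'   `basal_fraction`, `direction`, `ks_basal`, `ks_new`, `rr_basal`,
#'   `rr_new`.
#' @export
response_time <- function(object, basal_fraction = 0.5,
                          direction = c("up", "down"), step_size = 0.1,
                          n_out = 256L) {
  direction <- match.arg(direction)
  stopifnot(inherits(object, "phosphorelay"))
  if (is.null(object$f)) stop("requires a model with a closed elimination")
  alpha <- maximal_response(object)
  rr0 <- basal_fraction * alpha
  e0 <- object$f(rr0)
  if (!e0$feasible) stop("basal point infeasible")
  ks0 <- e0$ks
  ks1 <- if (direction == "up") (1 + step_size) * ks0
         else (1 - step_size) * ks0
  if (ks1 == ks0)
    return(structure(list(time = 0, basal_fraction = basal_fraction,
                          direction = direction, ks_basal = ks0,
                          ks_new = ks1, rr_basal = rr0, rr_new = rr0),
                     class = "response_time"))
  rr1 <- predict(object, ks1)
  band <- 0.01 * abs(rr1 - rr0)
  if (band == 0) stop("step produces no net change at the reported tolerance")

  p <- object$params
  init <- relay_state(p, HKp = e0$HKp, RECp = e0$RECp, Hptp = e0$Hptp,
                      RRp = rr0)
  if (!is.null(object$variant)) init <- c(init, variant_extra_state(object$variant))
  rhs <- function(t, y, parms) list(relay_derivatives(y, p, ks1, object$variant))
  scale <- max(p[c("HK_tot", "REC_tot", "Hpt_tot", "RR_tot")])

  # integrate in doubling segments, carrying the state forward, until the
  # trajectory has settled; then locate the first time after which the
  # output never leaves the band, and confirm over a doubled horizon
  seg_start <- 0; seg_len <- 1 / ks1
  state <- init
  times_all <- 0; rr_all <- rr0
  for (i in 1:60) {
    times <- seq(seg_start, seg_start + seg_len, length.out = n_out)
    sol <- deSolve::lsoda(state, times, rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-11 * scale, maxsteps = 5e5)
    state <- sol[nrow(sol), -1L]
    times_all <- c(times_all, times[-1])
    rr_all <- c(rr_all, sol[-1, "RRp"])
    seg_start <- seg_start + seg_len
    seg_len <- seg_start           # horizon doubles each pass
    settled <- abs(state[["RRp"]] - rr1) <= band &&
      max(abs(relay_derivatives(state, p, ks1, object$variant))) <
        1e-8 * scale * max(ks1, 1)
    if (settled) {
      inside <- abs(rr_all - rr1) <= band
      t_settle <- times_all[max(c(0L, which(!inside))) + 1L]
      t2 <- seq(seg_start, 2 * seg_start, length.out = 64L)
      sol2 <- deSolve::lsoda(state, t2, rhs, parms = NULL,
                             rtol = 1e-8, atol = 1e-11 * scale,
                             maxsteps = 5e5)
      if (all(abs(sol2[, "RRp"] - rr1) <= band))
        return(structure(list(time = t_settle,
                              basal_fraction = basal_fraction,
                              direction = direction, ks_basal = ks0,
                              ks_new = ks1, rr_basal = rr0, rr_new = rr1),
                         class = "response_time"))
    }
  }
  stop("no settlement within the integration horizon")
}

#' @export
print.response_time <- function(x, ...) {
  cat(sprintf(
    "Switch-%s time %.6g (basal %.0f%% of alpha: ks %.4g -> %.4g, RR~P %.4g -> %.4g)\n",
    x$direction, x$time, 100 * x$basal_fraction, x$ks_basal, x$ks_new,
    x$rr_basal, x$rr_new))
  invisible(x)
}

#' Response times across hyperbolic and sigmoidal regimes
#'
#' Draws parameter sets for one topology, classifies them, takes `n_each`
#' from each regime and measures the step-response time of every draw under
#' a common protocol.
#'
#' @param id Topology id.
#' @param n_each Draws per regime.
#' @param basal_fraction,direction Protocol (see [response_time()]).
#' @param scheme,seed Sampling scheme and seed.
#' @param max_draws Sampling cap while collecting the regimes.
#' @return A long-format data frame with columns `regime`, `draw`, `time`.
#' @export
response_time_by_regime <- function(id, n_each = 100L, basal_fraction = 0.5,
                                    direction = "up",
                                    scheme = sampling_scheme(), seed,
                                    max_draws = 1000L) {
  if (missing(seed)) stop("a seed is required")
  picks <- regime_draws(id, n_each, scheme, seed, max_draws)
  one <- function(m) {
    tryCatch(response_time(m, basal_fraction, direction)$time,
             error = function(e) NA_real_)
  }
  data.frame(
    regime = rep(c("hyperbolic", "sigmoidal"), each = n_each),
    draw = rep(seq_len(n_each), 2L),
    time = c(vapply(picks$hyperbolic, one, 0),
             vapply(picks$sigmoidal, one, 0)))
}
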