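#' Construct a phosphorelay model instance
#'
#' The central object of the package: a four-layered phosphorelay
#' (HK -> REC -> Hpt -> RR) with a fixed topology, a bound parameter set and
#' optionally a model variant.  The returned object carries the exact
#' steady-state relation `ks = f(rr)` (signal as a function of response)
#' where the model structure admits the layer-by-layer elimination -- the
#' simple monofunctional model, the turnover variant and both
#' auto-dephosphorylation variants do; the bifunctional-HK variant solves a
#' one-dimensional inner root problem per response level; the
#' encounter-complex variant is handled purely numerically through
#' [variant_steady_curve()].
#'
#' @param topology A `"relay_topology"` object or an integer id in 1..32.
#' @param params A `"relay_parameters"` vector; rate constants for reactions
#'   absent from the topology are forced to zero ([bind_parameters()]).
#' @param variant `NULL` (simple model) or a [variant_spec()].
#' @return An object of class `"phosphorelay"` with elements `topology`,
#'   `params`, `variant`, `drains`, `responsive`, `alpha` (maximal response;
#'   `NULL` until needed for the complex variant) and the elimination
#'   closure `f`.
#' @examples
#' m <- phosphorelay(14, relay_parameters(
#'   k2 = 1, k3 = 0.5, k4 = 0.5, k3r = 5, k4r = 5, kh1 = 1,
#'   HK_tot = 1, REC_tot = 1, Hpt_tot = 1, RR_tot = 1))
#' m
#' predict(m, signal = 0.5)
#' @export
phosphorelay <- function(topology, params, variant = NULL) {
  topology <- as_relay_topology(topology)
  p <- bind_parameters(topology, params)
  if (!is.null(variant) && !inherits(variant, "variant_spec"))
    stop("`variant` must come from variant_spec()")
  drains <- variant_drains(variant)
  kind <- if (is.null(variant)) "simple" else variant$kind

  obj <- structure(list(topology = topology, params = p, variant = variant,
                        drains = drains, kind = kind),
                   class = "phosphorelay")

  obj$responsive <- relay_responsive(obj)
  obj$f <- switch(kind,
    bifunctional_hk = {
      if (p[["k5"]] <= 0 || p[["k6"]] <= 0)
        stop("bifunctional variant requires k5 > 0 and k6 > 0")
      function(rr) bifunctional_eliminate(rr, p)
    },
    complexes = NULL,
    function(rr) relay_eliminate(rr, p, drains))
  if (obj$responsive && !is.null(obj$f))
    obj$alpha <- alpha_bisect(function(r) obj$f(r)$feasible[1], p[["RR_tot"]])
  obj
}

# Generalized structural responsiveness: phosphate must be able to leave
# the output layer and then drain out of the relay somewhere upstream.
relay_responsive <- function(obj) {
  p <- obj$params; d <- obj$drains
  bif_sink <- obj$kind == "bifunctional_hk" && p[["k5"]] > 0 && p[["k6"]] > 0
  s1 <- d[["d_hk"]] > 0
  s2 <- (p[["kh1"]] + d[["d_rec"]] > 0) || bif_sink || (p[["k2r"]] > 0 && s1)
  s3 <- d[["d_hpt"]] > 0 || (p[["k3r"]] > 0 && s2)
  (p[["kh2"]] + d[["d_rr"]] > 0) || (p[["k4r"]] > 0 && s3)
}

# Steady-state elimination for the bifunctional HK: given rr, the lower two
# layers solve as in the simple model; the HK.REC~P complex couples the top
# two conservation classes, leaving one scalar root problem in the complex
# concentration C.
bifunctional_eliminate <- function(rr, p) {
  out <- lapply(rr, function(r) bifunctional_eliminate1(r, p))
  list(ks = vapply(out, `[[`, 0, "ks"),
       Hptp = vapply(out, `[[`, 0, "Hptp"),
       RECp = vapply(out, `[[`, 0, "RECp"),
       HKp = vapply(out, `[[`, 0, "HKp"),
       C = vapply(out, `[[`, 0, "C"),
       feasible = vapply(out, `[[`, TRUE, "feasible"))
}

bifunctional_eliminate1 <- function(rr, p) {
  bad <- list(ks = NA_real_, Hptp = NA_real_, RECp = NA_real_,
              HKp = NA_real_, C = NA_real_, feasible = FALSE)
  HKt <- p[["HK_tot"]]; RECt <- p[["REC_tot"]]
  Hptt <- p[["Hpt_tot"]]; RRt <- p[["RR_tot"]]
  if (rr < 0 || rr > RRt) return(bad)
  if (rr == 0)
    return(list(ks = 0, Hptp = 0, RECp = 0, HKp = 0, C = 0, feasible = TRUE))
  den1 <- p[["k4"]] * (RRt - rr) + p[["k4r"]] * rr
  if (den1 <= 0) return(bad)
  hp <- rr * (p[["kh2"]] + p[["k4r"]] * Hptt) / den1
  if (hp < 0 || hp > Hptt) return(bad)
  den2 <- p[["k3"]] * (Hptt - hp) + p[["k3r"]] * hp
  if (den2 <= 0) return(bad)
  rp_of <- function(C) (p[["kh2"]] * rr + p[["k3r"]] * hp * (RECt - C)) / den2
  resid <- function(C) {
    rp <- rp_of(C)
    if (rp <= 0 || rp + C > RECt) return(-Inf)
    HK <- C * (p[["k5r"]] + p[["k6"]]) / (p[["k5"]] * rp)
    kp <- HKt - C - HK
    if (kp < 0) return(-Inf)
    REC <- RECt - rp - C
    p[["k2"]] * kp * REC - p[["k2r"]] * HK * rp -
      (p[["kh2"]] * rr + p[["kh1"]] * rp + p[["k6"]] * C)
  }
  # bracket: resid -> +Inf-like as C -> 0+ (kp -> HK_tot), and negative at
  # the largest admissible C; bisect on [tiny, Cmax]
  Cmax <- min(HKt, RECt)
  lo <- Cmax * 1e-300; hi <- Cmax
  rlo <- resid(lo)
  if (!is.finite(rlo) || rlo < 0) return(bad)
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    rm <- resid(mid)
    if (is.finite(rm) && rm > 0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-15 * Cmax) break
  }
  C <- 0.5 * (lo + hi)
  rp <- rp_of(C)
  HK <- C * (p[["k5r"]] + p[["k6"]]) / (p[["k5"]] * rp)
  kp <- HKt - C - HK
  ks <- (p[["kh2"]] * rr + p[["kh1"]] * rp + p[["k6"]] * C) / HK
  feas <- is.finite(ks) && ks >= 0 && rp >= 0 && rp + C <= RECt &&
    kp >= 0 && kp + C < HKt
  list(ks = ks, Hptp = hp, RECp = rp, HKp = kp, C = C, feasible = feas)
}

#' @export
print.phosphorelay <- function(x, ...) {
  cat(sprintf("Phosphorelay model (topology %d: rev %d%d%d, hyd %d%d)\n",
              x$topology$id, x$topology$r2, x$topology$r3, x$topology$r4,
              x$topology$h1, x$topology$h2))
  if (x$kind != "simple") cat("  variant:", x$kind, "\n")
  if (!x$responsive) {
    cat("  non-responsive: output saturates for any positive signal\n")
  } else if (!is.null(x$alpha)) {
    cat(sprintf("  responsive; maximal response alpha = %.6g (%.1f%% of RR_tot)\n",
                x$alpha, 100 * x$alpha / x$params[["RR_tot"]]))
  } else {
    cat("  responsive\n")
  }
  invisible(x)
}

#' @export
coef.phosphorelay <- function(object, ...) {
  p <- unclass(object$params)
  if (!is.null(object$variant)) p <- c(p, variant_rates(object$variant))
  p
}

#' Steady-state response at given signals
#'
#' Inverts the steady-state relation `ks = f(rr)`: for each signal value,
#' the steady-state concentration of phosphorylated RR.
#'
#' @param object A responsive `"phosphorelay"`.
#' @param signal Numeric vector of signal values (`ks`, time^-1).
#' @param ... Unused.
#' @return Numeric vector of steady-state RR~P concentrations.
#' @export
predict.phosphorelay <- function(object, signal, ...) {
  if (!object$responsive) stop("non-responsive relay: nothing to predict")
  if (is.null(object$f)) stop("no closed steady-state map for this variant; ",
                              "use variant_steady_curve()")
  alpha <- maximal_response(object)
  vapply(signal, function(s) {
    if (s < 0) stop("signal must be >= 0")
    if (s == 0) return(0)
    lo <- 0; hi <- alpha * (1 - 1e-9)
    fhi <- object$f(hi)
    if (fhi$feasible && fhi$ks <= s) return(hi)
    for (i in 1:100) {
      mid <- 0.5 * (lo + hi)
      fm <- object$f(mid)
      if (fm$feasible && fm$ks < s) lo <- mid else hi <- mid
    }
    0.5 * (lo + hi)
  }, 0)
}

#' @export
plot.phosphorelay <- function(x, ...) {
  plot(signal_response_curve(x), ...)
}

#' @export
summary.phosphorelay <- function(object, ...) {
  out <- list(topology = object$topology, kind = object$kind,
              responsive = object$responsive, params = object$params)
  if (object$responsive && !is.null(object$f)) {
    out$alpha <- maximal_response(object)
    out$classification <- classify(object)
    out$hill <- tryCatch(hill_coefficient(object), error = function(e) NA_real_)
    out$conditions <- necessary_conditions(object$params)
  }
  structure(out, class = "summary.phosphorelay")
}

#' @export
print.summary.phosphorelay <- function(x, ...) {
  print.phosphorelay(structure(list(topology = x$topology, kind = x$kind,
                                    responsive = x$responsive,
                                    params = x$params, alpha = x$alpha),
                               class = "phosphorelay"))
  if (!is.null(x$classification)) {
    cat(sprintf("  signal-response curve: %s (curvature at zero %+.3g)\n",
                x$classification$label, x$classification$curvature))
    cat(sprintf("  Hill coefficient n_H = %.4g\n", x$hill))
    cat(sprintf("  necessary conditions for sigmoidality %s\n",
                if (x$conditions$sigmoidal_possible) "satisfied"
                else "violated"))
  }
  invisible(x)
}

#' Stochastic trajectories of the relay (Gillespie simulation)
#'
#' Simulates exact stochastic trajectories of the molecular-count version of
#' the relay (see [stochastic_config()]) with the direct Gillespie method.
#'
#' @param object A `"phosphorelay"` (simple model only).
#' @param nsim Number of trajectories.
#' @param seed Optional integer seed.
#' @param ks Signal value.
#' @param config A [stochastic_config()].
#' @param t_end End time of each trajectory.
#' @param n_out Number of equally spaced recording times.
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `time`, `HKp`, `RECp`,
#'   `Hptp`, `RRp` (molecule counts).
#' @export
simulate.phosphorelay <- function(object, nsim = 1, seed = NULL, ks,
                                  config = stochastic_config(),
                                  t_end = 100, n_out = 200L, ...) {
  if (object$kind != "simple")
    stop("stochastic simulation is implemented for the simple model")
  if (!is.null(seed)) set.seed(seed)
  rates <- ctmc_rates(object$params, config, ks)
  times <- seq(0, t_end, length.out = n_out)
  lapply(seq_len(nsim), function(i) {
    m <- ssa_path(c(0L, 0L, 0L, 0L), rates$N, rates$rates, times)
    data.frame(time = times, HKp = m[, 1], RECp = m[, 2],
               Hptp = m[, 3], RRp = m[, 4])
  })
}
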