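#' Curvature of the signal-response curve at zero signal
#'
#' Computes the second derivative of the steady-state response `RR~P(ks)`
#' at `ks = 0` via the inverse-function rule
#' `d2R/dks2 = -f''(0) / f'(0)^3`, with `f'(0)` and `f''(0)` obtained by
#' exact second-order forward differentiation of the flux-balance
#' elimination (no finite differencing).  A positive value marks a
#' sigmoidal curve (inflection at positive signal); a negative value a
#' hyperbolic one.
#'
#' For the bifunctional variant, whose elimination contains an inner root
#' solve, the derivatives of `f` at zero are estimated by high-order
#' one-sided finite differences on a small response grid instead.
#'
#' @param object A responsive `"phosphorelay"`.
#' @return Signed curvature (second derivative of response w.r.t. signal at
#'   zero signal).
#' @export
curvature_at_zero <- function(object) {
  stopifnot(inherits(object, "phosphorelay"))
  if (!object$responsive) stop("non-responsive relay has no response curve")
  if (object$kind == "complexes")
    stop("use sign-change classification on variant_steady_curve() for the ",
         "complex-formation variant")
  if (object$kind == "bifunctional_hk") {
    alpha <- maximal_response(object)
    h <- 1e-4 * alpha
    ks <- object$f(h * (0:3))$ks
    f1 <- (-11 * ks[1] + 18 * ks[2] - 9 * ks[3] + 2 * ks[4]) / (6 * h)
    f2 <- (2 * ks[1] - 5 * ks[2] + 4 * ks[3] - ks[4]) / h^2
  } else {
    j <- relay_eliminate_jet(0, object$params, object$drains)
    f1 <- j$ks[2]; f2 <- j$ks[3]
  }
  if (!is.finite(f1) || f1 <= 0)
    stop("degenerate instance: f'(0) <= 0, curvature indeterminate")
  -f2 / f1^3
}

#' Classify a signal-response curve as hyperbolic or sigmoidal
#'
#' Two classifiers are available.  `"curvature_at_zero"` uses only the sign
#' of the second derivative of the response curve at zero signal (exact for
#' all models with a closed elimination).  `"sign_change"` estimates the
#' second derivative numerically along the whole curve -- central
#' differences on a uniform 200-point signal grid spanning
#' `[0, f(0.95 alpha)]` -- and reports sigmoidal when it changes sign from
#' positive to negative, requiring two consecutive same-signed points on
#' each side of the change to suppress single-point numerical flips.
#'
#' @param object A responsive `"phosphorelay"`.
#' @param method `"curvature_at_zero"` (default) or `"sign_change"`.
#' @param n_grid Signal-grid size for the sign-change method.
#' @return A list of class `"relay_classification"`: `label` (`"hyperbolic"`
#'   or `"sigmoidal"`), `curvature` (value at zero; `NA` for the sign-change
#'   method), `curvature_sign_at_zero` (-1/0/+1), `sign_change_detected`,
#'   and `method`.
#' @export
classify <- function(object, method = c("curvature_at_zero", "sign_change"),
                     n_grid = 200L) {
  method <- match.arg(method)
  stopifnot(inherits(object, "phosphorelay"))
  if (method == "curvature_at_zero") {
    curv <- curvature_at_zero(object)
    res <- list(label = if (curv > 0) "sigmoidal" else "hyperbolic",
                curvature = curv, curvature_sign_at_zero = sign(curv),
                sign_change_detected = NA, method = method)
  } else {
    sc <- detect_sign_change(object, n_grid)
    res <- list(label = if (sc) "sigmoidal" else "hyperbolic",
                curvature = NA_real_, curvature_sign_at_zero = NA_integer_,
                sign_change_detected = sc, method = method)
  }
  structure(res, class = "relay_classification")
}

#' @export
print.relay_classification <- function(x, ...) {
  cat(sprintf("Signal-response classification: %s (method: %s)\n",
              x$label, x$method))
  if (!is.na(x$curvature))
    cat(sprintf("  curvature of response at zero signal: %+.4g\n",
                x$curvature))
  if (!is.na(x$sign_change_detected))
    cat(sprintf("  +/- sign change along curve: %s\n",
                x$sign_change_detected))
  invisible(x)
}

# Numerically estimated second derivative of the response along the curve.
detect_sign_change <- function(object, n_grid = 200L) {
  alpha <- maximal_response(object)
  top <- 0.95 * alpha
  ks_max <- object$f(top)$ks
  ks <- seq(0, ks_max, length.out = n_grid)
  rr <- invert_f(object, ks, top)
  d2 <- diff(diff(rr))                       # uniform grid: sign only
  thr <- 1e-9 * max(abs(d2))
  pos <- d2 > thr
  neg <- d2 < -thr
  pos2 <- which(pos[-length(pos)] & pos[-1])         # two consecutive +
  neg2 <- which(neg[-length(neg)] & neg[-1])         # two consecutive -
  length(pos2) > 0 && length(neg2) > 0 && min(pos2) < max(neg2) &&
    any(neg2 > min(pos2))
}

# Vectorized monotone inversion of f on [0, top] by bisection.
invert_f <- function(object, ks, top) {
  lo <- rep(0, length(ks)); hi <- rep(top, length(ks))
  for (i in 1:60) {
    mid <- 0.5 * (lo + hi)
    e <- object$f(mid)
    below <- e$feasible & e$ks < ks
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  out <- 0.5 * (lo + hi)
  out[ks == 0] <- 0
  out
}

#' Analytic necessary conditions for sigmoidality
#'
#' A sigmoidal signal-response relationship in the simple (monofunctional,
#' conserved-totals) relay requires all of: (i) hydrolysis at REC,
#' `kh1 > 0`; (ii) forward dominance at the top transfer, `k2 > k2r`;
#' (iii) reverse dominance below, `k3r > k3` or `k3r * k4r > k3 * k4`; and
#' additionally `k3r > 0`.  If any condition fails the curve is hyperbolic:
#' the curvature of the response at zero signal is negative exactly when
#' `k3 > k3r` and `k3 k4 > k3r k4r` (or (i)/(ii) fail), so condition (iii)
#' is the product form, not the frequently quoted additive comparison of
#' the rate sums -- relays without output hydrolysis and with very strong
#' reverse transfer at the bottom interface can be sigmoidal while
#' `k3r + k4r < k3 + k4`.  These conditions are necessary, not sufficient.
#'
#' @param params A `"relay_parameters"` vector (or coercible).
#' @return A list with `sigmoidal_possible` (logical) and `conditions`, a
#'   named logical vector with the per-condition breakdown.
#' @export
necessary_conditions <- function(params) {
  p <- as_relay_parameters(params)
  conds <- c(
    kh1_positive = p[["kh1"]] > 0,
    k2_gt_k2r = p[["k2"]] > p[["k2r"]],
    reverse_dominance = p[["k3r"]] > p[["k3"]] ||
      (p[["k3r"]] * p[["k4r"]]) > (p[["k3"]] * p[["k4"]]),
    k3r_positive = p[["k3r"]] > 0)
  list(sigmoidal_possible = all(conds), conditions = conds)
}

#' Tabulate classifications for a batch of parameter sets
#'
#' Builds one row per parameter set: topology id, classification method,
#' label, the sign of the curvature at zero and the Hill coefficient.
#' Suitable for writing straight to CSV.
#'
#' @param topology A `"relay_topology"` or integer id.
#' @param param_sets A list of parameter sets (e.g. from
#'   [sample_parameter_sets()]).
#' @param method Classifier, as in [classify()].
#' @return A data frame with columns `topology_id`, `method`, `label`,
#'   `curvature_sign`, `n_H` (rows with failed classification carry `NA`).
#' @export
classification_report <- function(topology, param_sets,
                                  method = c("curvature_at_zero",
                                             "sign_change")) {
  method <- match.arg(method)
  topology <- as_relay_topology(topology)
  rows <- lapply(param_sets, function(p) {
    out <- tryCatch({
      m <- phosphorelay(topology, p)
      cls <- classify(m, method = method)
      data.frame(topology_id = topology$id, method = method,
                 label = cls$label,
                 curvature_sign = if (is.na(cls$curvature)) NA_integer_
                                  else as.integer(sign(cls$curvature)),
                 n_H = hill_coefficient(m))
    }, error = function(e)
      data.frame(topology_id = topology$id, method = method,
                 label = NA_character_, curvature_sign = NA_integer_,
                 n_H = NA_real_))
    out
  })
  do.call(rbind, rows)
}

#' Hill coefficient of a signal-response curve
#'
#' The steepness summary `n_H = log(81) / log(input90 / input10)`, where
#' `input10` and `input90` are the signals producing 10% and 90% of the
#' maximal response `alpha`.  A hyperbolic (Michaelis-Menten) curve gives
#' exactly 1; steeper, sigmoidal curves exceed 1.
#'
#' @param x A `"phosphorelay"` (signals evaluated exactly through `f`), a
#'   `"signal_response_curve"` (monotone interpolation on the sampled grid),
#'   or a function `response(signal)` (signals found by root bracketing).
#' @param ... Passed to methods.
#' @return `n_H` (dimensionless), or `NA` if the curve does not reach 90%
#'   of its maximum on the available domain.
#' @export
hill_coefficient <- function(x, ...) UseMethod("hill_coefficient")

#' @export
hill_coefficient.phosphorelay <- function(x, ...) {
  alpha <- maximal_response(x)
  s <- x$f(c(0.1, 0.9) * alpha)
  if (!all(s$feasible)) return(NA_real_)
  log(81) / log(s$ks[2] / s$ks[1])
}

#' @rdname hill_coefficient
#' @param alpha Maximal response; for curve input defaults to its `alpha`
#'   attribute.
#' @export
hill_coefficient.signal_response_curve <- function(x, alpha = NULL, ...) {
  if (is.null(alpha)) alpha <- attr(x, "alpha")
  if (max(x$rr) < 0.9 * alpha) return(NA_real_)
  sf <- stats::splinefun(x$rr, x$ks, method = "hyman")
  log(81) / log(sf(0.9 * alpha) / sf(0.1 * alpha))
}

#' @rdname hill_coefficient
#' @param interval Signal search interval for the function method.
#' @export
hill_coefficient.function <- function(x, alpha, interval = c(0, 1e12), ...) {
  sig_at <- function(level) {
    stats::uniroot(function(s) x(s) - level, interval = interval,
                   tol = .Machine$double.eps^0.75)$root
  }
  log(81) / log(sig_at(0.9 * alpha) / sig_at(0.1 * alpha))
}
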