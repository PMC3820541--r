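#' Specify a model variant relaxing an assumption of the simple relay
#'
#' Five variants are supported:
#' \describe{
#'   \item{`bifunctional_hk`}{Unphosphorylated HK binds REC~P
#'     (rate `k5`), the complex dissociates (`k5r`) or catalyzes
#'     dephosphorylation (`k6`); the three rates live in the parameter set.}
#'   \item{`complexes`}{An encounter-complex channel alongside each forward
#'     phosphotransfer: donor~P + acceptor bind (`on`), dissociate (`off`)
#'     or transfer irreversibly (`cat`), per interface (HK-REC, REC-Hpt,
#'     Hpt-RR).}
#'   \item{`turnover`}{Production of each unphosphorylated species and
#'     first-order removal (rate `delta`) of every form; production rates
#'     are `delta * total` so the stated totals are the steady-state
#'     totals.}
#'   \item{`hk_autodephos`}{First-order auto-dephosphorylation of HK~P at
#'     rate `kd`.}
#'   \item{`hpt_autodephos`}{First-order auto-dephosphorylation of Hpt~P at
#'     rate `kd`.}
#' }
#' All variants reduce exactly to the simple model when their extra rates
#' are zero.
#'
#' @param kind Variant name (see above).
#' @param delta Turnover rate (turnover variant), time^-1.
#' @param kd Auto-dephosphorylation rate (autodephos variants), time^-1.
#' @param on,off,cat Length-3 rate vectors for the complex channels at
#'   interfaces 2, 3, 4 (complexes variant).
#' @return A list of class `"variant_spec"`.
#' @export
variant_spec <- function(kind = c("bifunctional_hk", "complexes",
                                  "turnover", "hk_autodephos",
                                  "hpt_autodephos"),
                         delta = 0, kd = 0,
                         on = c(0, 0, 0), off = c(0, 0, 0),
                         cat = c(0, 0, 0)) {
  kind <- match.arg(kind)
  v <- list(kind = kind)
  if (kind == "turnover") {
    stopifnot(delta >= 0)
    v$delta <- delta
  } else if (kind %in% c("hk_autodephos", "hpt_autodephos")) {
    stopifnot(kd >= 0)
    v$kd <- kd
  } else if (kind == "complexes") {
    stopifnot(length(on) == 3, length(off) == 3, length(cat) == 3,
              all(c(on, off, cat) >= 0))
    v$on <- on; v$off <- off; v$cat <- cat
  }
  structure(v, class = "variant_spec")
}

variant_drains <- function(variant) {
  d <- zero_drains()
  if (is.null(variant)) return(d)
  switch(variant$kind,
         turnover = d + variant$delta,
         hk_autodephos = { d[["d_hk"]] <- variant$kd; d },
         hpt_autodephos = { d[["d_hpt"]] <- variant$kd; d },
         d)
}

variant_rates <- function(variant) {
  switch(variant$kind,
         turnover = c(delta = variant$delta),
         hk_autodephos = c(kd_hk = variant$kd),
         hpt_autodephos = c(kd_hpt = variant$kd),
         complexes = c(on2 = variant$on[1], on3 = variant$on[2],
                       on4 = variant$on[3], off2 = variant$off[1],
                       off3 = variant$off[2], off4 = variant$off[3],
                       cat2 = variant$cat[1], cat3 = variant$cat[2],
                       cat4 = variant$cat[3]),
         numeric(0))
}

variant_extra_state <- function(variant) {
  switch(variant$kind,
         bifunctional_hk = c(C = 0),
         complexes = c(C2 = 0, C3 = 0, C4 = 0),
         numeric(0))
}

#' Assemble a variant state vector
#'
#' Like [relay_state()] but appending the variant's extra species
#' (complexes) at the given values.
#'
#' @param params Parameter vector.
#' @param variant A `"variant_spec"`.
#' @param ... Passed to [relay_state()] plus extra species by name
#'   (`C`, `C2`, `C3`, `C4`).
#' @export
variant_state <- function(params, variant, ...) {
  args <- list(...)
  extra <- variant_extra_state(variant)
  for (nm in intersect(names(args), names(extra))) extra[[nm]] <- args[[nm]]
  base <- do.call(relay_state,
                  c(list(params = params), args[setdiff(names(args),
                                                        names(extra))]))
  c(base, extra)
}

variant_rhs <- function(state, p, ks, variant) {
  base <- relay_rhs_simple(state[species_names()], p, ks)
  switch(variant$kind,
    turnover = {
      delta <- variant$delta
      prod <- c(HK = p[["HK_tot"]], HKp = 0, REC = p[["REC_tot"]], RECp = 0,
                Hpt = p[["Hpt_tot"]], Hptp = 0, RR = p[["RR_tot"]], RRp = 0)
      base + delta * prod - delta * state[species_names()]
    },
    hk_autodephos = {
      flux <- variant$kd * state[["HKp"]]
      base[["HK"]] <- base[["HK"]] + flux
      base[["HKp"]] <- base[["HKp"]] - flux
      base
    },
    hpt_autodephos = {
      flux <- variant$kd * state[["Hptp"]]
      base[["Hpt"]] <- base[["Hpt"]] + flux
      base[["Hptp"]] <- base[["Hptp"]] - flux
      base
    },
    bifunctional_hk = {
      bind <- p[["k5"]] * state[["HK"]] * state[["RECp"]]
      unbind <- p[["k5r"]] * state[["C"]]
      catal <- p[["k6"]] * state[["C"]]
      base[["HK"]] <- base[["HK"]] - bind + unbind + catal
      base[["RECp"]] <- base[["RECp"]] - bind + unbind
      base[["REC"]] <- base[["REC"]] + catal
      c(base, C = bind - unbind - catal)
    },
    complexes = {
      donors <- c("HKp", "RECp", "Hptp")
      accept <- c("REC", "Hpt", "RR")
      dphos <- c("HK", "REC", "Hpt")
      aphos <- c("RECp", "Hptp", "RRp")
      cx <- c("C2", "C3", "C4")
      dC <- numeric(3)
      for (i in 1:3) {
        form <- variant$on[i] * state[[donors[i]]] * state[[accept[i]]]
        diss <- variant$off[i] * state[[cx[i]]]
        tr <- variant$cat[i] * state[[cx[i]]]
        base[[donors[i]]] <- base[[donors[i]]] - form + diss
        base[[accept[i]]] <- base[[accept[i]]] - form + diss
        base[[dphos[i]]] <- base[[dphos[i]]] + tr
        base[[aphos[i]]] <- base[[aphos[i]]] + tr
        dC[i] <- form - diss - tr
      }
      c(base, C2 = dC[1], C3 = dC[2], C4 = dC[3])
    },
    stop("unknown variant kind"))
}

#' Numerical signal-response curve for any model variant
#'
#' Builds the signal-response relation by integrating the variant ODE to
#' steady state on a log-spaced signal grid.  The maximal response `alpha`
#' is taken as the steady-state response in the large-signal limit.  This
#' is the general (slow) path used for variants without a closed
#' elimination; models with one should use [signal_response_curve()].
#'
#' @param object A `"phosphorelay"` (any variant).
#' @param n_points Grid size.
#' @param span Decades covered on each side of the half-maximal signal.
#' @param ks_large Signal used for the large-signal limit.
#' @return A data frame with columns `ks`, `rr` and `fraction`, attribute
#'   `alpha`.
#' @export
variant_steady_curve <- function(object, n_points = 25L, span = 2.5,
                                 ks_large = 1e6) {
  stopifnot(inherits(object, "phosphorelay"))
  p <- object$params
  rr_at <- function(ks) {
    ss <- ode_steady_state(p, ks, object$variant)
    if (!ss$converged) stop("no steady state at ks = ", ks)
    ss$state[["RRp"]]
  }
  scale_ks <- ks_large * max(1, max(p[c("kh1", "kh2", "k6")]))
  alpha <- rr_at(scale_ks)
  ks_half <- stats::uniroot(function(lk) rr_at(exp(lk)) - alpha / 2,
                            lower = log(1e-9), upper = log(scale_ks),
                            tol = 1e-6)$root
  ks <- exp(seq(ks_half - span * log(10), ks_half + span * log(10),
                length.out = n_points))
  rr <- vapply(ks, rr_at, 0)
  structure(data.frame(ks = ks, rr = rr, fraction = rr / p[["RR_tot"]]),
            alpha = alpha, class = c("data.frame"))
}

#' Signal at half-maximal response
#'
#' @param object A responsive `"phosphorelay"` with a closed elimination.
#' @return The signal `f(alpha / 2)`.
#' @export
half_maximal_signal <- function(object) {
  alpha <- maximal_response(object)
  e <- object$f(alpha / 2)
  if (!e$feasible) stop("half-maximal point infeasible")
  e$ks
}

#' Numerical checks of the variants' sigmoidality conditions
#'
#' Seeded randomized verification of the structural claims attached to each
#' variant: existence claims search for a witness instance; necessity
#' claims search for counterexamples across random draws and must find
#' none.
#'
#' \describe{
#'   \item{`hpt_autodephos`}{Sigmoidality can arise with `kh1 = 0` and
#'     `k3r = 0` provided `k4r > k4` (witness search); and every sigmoidal
#'     draw satisfies the simple-model conditions or `k4r > k4`
#'     (necessity).}
#'   \item{`hk_autodephos`}{No sigmoidal draw violates the simple-model
#'     necessary conditions.}
#'   \item{`turnover`}{Sigmoidality can arise with `kh1 = 0`, `k3r = 0`,
#'     `k4r > 0` (witness); no sigmoidal draw has `k3r = 0` and `k4r = 0`
#'     (necessity).}
#'   \item{`bifunctional_hk`}{A topology lacking hydrolysis at REC admits a
#'     sigmoidal instance when HK is bifunctional (witness search).}
#' }
#'
#' @param kind Variant kind.
#' @param seed Integer seed.
#' @param n_draws Draws for necessity claims.
#' @param n_witness Draw budget for witness searches.
#' @param scheme Sampling ranges.
#' @return A list of claim results, each with `description`, `satisfied`
#'   and supporting `witness` / `n_violations`.
#' @export
variant_condition_checks <- function(kind, seed, n_draws = 10000L,
                                     n_witness = 2000L,
                                     scheme = sampling_scheme()) {
  if (missing(seed)) stop("a seed is required")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  switch(kind,
         hpt_autodephos = check_hpt_autodephos(n_draws, n_witness, scheme),
         hk_autodephos = check_hk_autodephos(n_draws, scheme),
         turnover = check_turnover(n_draws, n_witness, scheme),
         bifunctional_hk = check_bifunctional(n_witness, scheme),
         stop("no condition checks defined for kind ", kind))
}

random_draw <- function(topo, scheme) {
  s <- sample.int(2^30, 1L)
  sample_parameter_sets(topo, n = 1L, scheme = scheme, seed = s)[[1]]
}

curvature_or_na <- function(topo, p, variant = NULL) {
  tryCatch(curvature_at_zero(phosphorelay(topo, p, variant)),
           error = function(e) NA_real_)
}

check_hpt_autodephos <- function(n_draws, n_witness, scheme) {
  # witness: topology 3 (rev 001, hyd 01) has kh1 = 0 and k3r = 0
  # structurally; keep draws with k4r > k4 and add a Hpt~P drain
  topo3 <- relay_topology(3)
  witness <- NULL
  for (i in seq_len(n_witness)) {
    p <- random_draw(topo3, scheme)
    if (p[["k4r"]] <= p[["k4"]]) next
    v <- variant_spec("hpt_autodephos", kd = rlogunif(1, scheme$hydrolysis))
    curv <- curvature_or_na(topo3, p, v)
    if (!is.na(curv) && curv > 0) {
      witness <- list(params = p, kd = v$kd, curvature = curv)
      break
    }
  }
  # necessity: sigmoidal draws satisfy simple conditions or k4r > k4
  tab <- relay_topologies()
  resp <- tab$id[tab$responsive]
  viol <- 0L
  for (i in seq_len(n_draws)) {
    topo <- relay_topology(sample(resp, 1L))
    p <- random_draw(topo, scheme)
    v <- variant_spec("hpt_autodephos", kd = rlogunif(1, scheme$hydrolysis))
    curv <- curvature_or_na(topo, p, v)
    if (!is.na(curv) && curv > 0 &&
        !necessary_conditions(p)$sigmoidal_possible &&
        !(p[["k4r"]] > p[["k4"]]))
      viol <- viol + 1L
  }
  list(
    witness_kh1_k3r_zero = list(
      description = "sigmoidal with kh1 = 0, k3r = 0, k4r > k4",
      satisfied = !is.null(witness), witness = witness),
    necessity = list(
      description = "sigmoidal draws satisfy simple conditions or k4r > k4",
      satisfied = viol == 0L, n_violations = viol, n_draws = n_draws))
}

check_hk_autodephos <- function(n_draws, scheme) {
  tab <- relay_topologies()
  resp <- tab$id[tab$responsive]
  viol <- 0L
  for (i in seq_len(n_draws)) {
    topo <- relay_topology(sample(resp, 1L))
    p <- random_draw(topo, scheme)
    v <- variant_spec("hk_autodephos", kd = rlogunif(1, scheme$hydrolysis))
    curv <- curvature_or_na(topo, p, v)
    if (!is.na(curv) && curv > 0 &&
        !necessary_conditions(p)$sigmoidal_possible)
      viol <- viol + 1L
  }
  list(necessity = list(
    description = "sigmoidality still requires the simple-model conditions",
    satisfied = viol == 0L, n_violations = viol, n_draws = n_draws))
}

check_turnover <- function(n_draws, n_witness, scheme) {
  topo3 <- relay_topology(3)   # kh1 = 0, k3r = 0, k4r free
  witness <- NULL
  for (i in seq_len(n_witness)) {
    p <- random_draw(topo3, scheme)
    v <- variant_spec("turnover", delta = rlogunif(1, scheme$hydrolysis))
    curv <- curvature_or_na(topo3, p, v)
    if (!is.na(curv) && curv > 0) {
      witness <- list(params = p, delta = v$delta, curvature = curv)
      break
    }
  }
  # necessity: k3r = 0 and k4r = 0 forbids sigmoidality; topologies with
  # r3 = r4 = 0
  ids <- c(1, 7, 25, 31)
  viol <- 0L
  for (i in seq_len(n_draws)) {
    topo <- relay_topology(sample(ids, 1L))
    p <- random_draw(topo, scheme)
    v <- variant_spec("turnover", delta = rlogunif(1, scheme$hydrolysis))
    curv <- curvature_or_na(topo, p, v)
    if (!is.na(curv) && curv > 0) viol <- viol + 1L
  }
  list(
    witness_kh1_k3r_zero = list(
      description = "sigmoidal with kh1 = 0, k3r = 0, k4r > 0 under turnover",
      satisfied = !is.null(witness), witness = witness),
    necessity = list(
      description = "no sigmoidality when both k3r = 0 and k4r = 0",
      satisfied = viol == 0L, n_violations = viol, n_draws = n_draws))
}

check_bifunctional <- function(n_witness, scheme) {
  # topology 6 (rev 011, hyd 01) lacks hydrolysis at REC; the
  # HK-mediated dephosphorylation must stand in for kh1
  topo6 <- relay_topology(6)
  witness <- NULL
  for (i in seq_len(n_witness)) {
    s <- sample.int(2^30, 1L)
    p <- sample_parameter_sets(topo6, n = 1L, scheme = scheme, seed = s,
                               bifunctional = TRUE)[[1]]
    curv <- curvature_or_na(topo6, p, variant_spec("bifunctional_hk"))
    if (!is.na(curv) && curv > 0) {
      m <- phosphorelay(topo6, p, variant_spec("bifunctional_hk"))
      confirmed <- tryCatch(
        classify(m, method = "sign_change", n_grid = 100L)$label ==
          "sigmoidal", error = function(e) FALSE)
      if (confirmed) {
        witness <- list(params = p, curvature = curv)
        break
      }
    }
  }
  list(witness_no_rec_hydrolysis = list(
    description = "bifunctional HK enables sigmoidality without kh1",
    satisfied = !is.null(witness), witness = witness))
}
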