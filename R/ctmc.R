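#' Stochastic (molecular-count) configuration
#'
#' The relay is mapped to a continuous-time Markov chain on molecule
#' counts: each layer total is represented by `N` molecules, i.e. counts
#' `n = g * concentration` with scaling factor `g = N / total` (the
#' `N_A * V` system-size factor).  Bimolecular stochastic rates are the
#' mass-action rate constants divided by `g`; first-order rates are
#' unchanged.  Equal totals across layers are required so that a single
#' `g` maps every layer to `N` molecules.
#'
#' @param N Molecules per layer total (default 10, giving `(N+1)^4 = 14641`
#'   states).
#' @param max_states Refuse to build generators larger than this.
#' @return A list of class `"stochastic_config"`.
#' @export
stochastic_config <- function(N = 10L, max_states = 5e5) {
  stopifnot(N >= 1L)
  structure(list(N = as.integer(N), max_states = max_states),
            class = "stochastic_config")
}

# Scaled per-channel stochastic rate constants.  Channel order:
# 1 auto-phosphorylation, 2 J2 forward, 3 J2 reverse, 4 J3 forward,
# 5 J3 reverse, 6 J4 forward, 7 J4 reverse, 8 hydrolysis REC~P,
# 9 hydrolysis RR~P.
ctmc_rates <- function(params, config, ks) {
  p <- as_relay_parameters(params)
  totals <- p[c("HK_tot", "REC_tot", "Hpt_tot", "RR_tot")]
  if (diff(range(totals)) > 1e-9 * max(totals))
    stop("the molecular-count mapping requires equal layer totals")
  g <- config$N / totals[[1]]
  list(N = config$N, g = g,
       rates = c(ks,
                 p[["k2"]] / g, p[["k2r"]] / g,
                 p[["k3"]] / g, p[["k3r"]] / g,
                 p[["k4"]] / g, p[["k4r"]] / g,
                 p[["kh1"]], p[["kh2"]]))
}

#' Build the CTMC generator of a relay at one signal level
#'
#' States are 4-tuples of phospho-counts `(HK~P, REC~P, Hpt~P, RR~P)`, each
#' in `0..N` (conservation eliminates the unphosphorylated forms), indexed
#' in mixed-radix order.  The generator `Q` holds the scaled mass-action
#' propensities off-diagonal; row sums are zero.
#'
#' @param object A simple-model `"phosphorelay"` with equal layer totals.
#' @param ks Signal value.
#' @param config A [stochastic_config()].
#' @return A list with the sparse generator `Q` (`dgCMatrix`), the count
#'   vectors `counts` (matrix with one row per state) and `N`.
#' @export
build_generator <- function(object, ks, config = stochastic_config()) {
  stopifnot(inherits(object, "phosphorelay"))
  if (object$kind != "simple")
    stop("the CTMC analysis covers the simple monofunctional model")
  r <- ctmc_rates(object$params, config, ks)
  N <- r$N
  S <- (N + 1)^4
  if (S > config$max_states)
    stop("state space has ", S, " states, above the cap of ",
         config$max_states)
  i0 <- 0:(S - 1)
  a <- i0 %% (N + 1)
  b <- (i0 %/% (N + 1)) %% (N + 1)
  cc <- (i0 %/% (N + 1)^2) %% (N + 1)
  d <- i0 %/% (N + 1)^3
  k <- r$rates
  # propensity and state-index offset per channel
  chan <- list(
    list(w = k[1] * (N - a),        off = +1),               # HK -> HK~P
    list(w = k[2] * a * (N - b),    off = -1 + (N + 1)),     # J2 forward
    list(w = k[3] * (N - a) * b,    off = +1 - (N + 1)),     # J2 reverse
    list(w = k[4] * b * (N - cc),   off = -(N + 1) + (N + 1)^2),
    list(w = k[5] * (N - b) * cc,   off = +(N + 1) - (N + 1)^2),
    list(w = k[6] * cc * (N - d),   off = -(N + 1)^2 + (N + 1)^3),
    list(w = k[7] * d * (N - cc),   off = +(N + 1)^2 - (N + 1)^3),
    list(w = k[8] * b,              off = -(N + 1)),         # REC~P ->
    list(w = k[9] * d,              off = -(N + 1)^3))       # RR~P ->
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (ch in chan) {
    keep <- ch$w > 0
    from <- c(from, i0[keep])
    to <- c(to, i0[keep] + ch$off)
    w <- c(w, ch$w[keep])
  }
  Q <- Matrix::sparseMatrix(i = from + 1L, j = to + 1L, x = w,
                            dims = c(S, S))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  list(Q = Q, counts = cbind(HKp = a, RECp = b, Hptp = cc, RRp = d), N = N)
}

# Indicator of states reachable from the fully-unphosphorylated state.
reachable_states <- function(Q) {
  A <- Matrix::t(Q)
  Matrix::diag(A) <- 0
  reach <- numeric(nrow(A)); reach[1] <- 1
  repeat {
    nxt <- as.numeric((A %*% reach) > 0 | reach > 0)
    if (sum(nxt) == sum(reach)) break
    reach <- nxt
  }
  reach > 0
}

# Stationary distribution on the class reachable from the empty state:
# pi Q = 0, sum(pi) = 1.  Fast path: compiled Gauss-Seidel sweeps of the
# balance equations (the iterative scheme probabilistic model checkers
# use).  Stiff relays -- rates spread over decades, or no hydrolysis at the
# output layer -- mix too slowly for any iterative scheme, so if the sweeps
# do not reach the residual tolerance the solve falls through to an exact
# direct elimination over RR~P levels (the chain is quasi-birth-death in
# the output count); plain sparse LU of the whole 4-D lattice generator is
# not an option (catastrophic fill-in).
stationary_distribution <- function(Q, reach = NULL, tol = 1e-12,
                                    init = NULL, N = NULL,
                                    anchor_high = FALSE) {
  if (is.null(reach)) reach <- reachable_states(Q)
  sub <- which(reach)
  full <- length(sub) == nrow(Q)
  qbd_ok <- full && !is.null(N) && nrow(Q) == (N + 1)^4 &&
    (N + 1)^3 <= 2000
  Qs <- methods::as(Q[sub, sub, drop = FALSE], "CsparseMatrix")
  pi_sub <- stationary_gs(Qs@p, Qs@i, Qs@x, length(sub), tol = tol,
                          max_sweeps = if (qbd_ok) 600L else 20000L,
                          init = if (!is.null(init)) init[sub])
  if (attr(pi_sub, "residual") > tol) {
    if (qbd_ok) {
      # anchor the level elimination at the end expected to carry the mass;
      # redo from the opposite end if the residual disagrees
      maxout <- max(-Matrix::diag(Qs))
      pi_sub <- qbd_stationary(Qs, N, reverse = anchor_high)
      if (max(abs(pi_sub %*% Qs)) / maxout > 1e-11) {
        alt <- qbd_stationary(Qs, N, reverse = !anchor_high)
        if (max(abs(alt %*% Qs)) < max(abs(pi_sub %*% Qs))) pi_sub <- alt
      }
    } else {
      warning("stationary solve converged poorly (residual ",
              format(attr(pi_sub, "residual")), ")")
    }
  }
  pi_sub <- pmax(as.numeric(pi_sub), 0)
  pi_sub <- pi_sub / sum(pi_sub)
  out <- numeric(nrow(Q))
  out[sub] <- pi_sub
  out
}

# Exact stationary solve by block elimination over RR~P levels.  With
# states ordered so the output count d is the outermost coordinate, Q is
# block tridiagonal: level d talks only to d-1 (reverse transfer,
# hydrolysis) and d+1 (forward transfer).  Working with x = pi^T, Schur
# complements are accumulated from the top level down, the bottom-level
# null vector is extracted, and the remaining levels follow by forward
# substitution reusing the stored factorizations.
qbd_stationary <- function(Q, N, reverse = FALSE) {
  mblk <- nrow(Q) / (N + 1)
  rd <- if (reverse) function(d) (N - d) * mblk + 1:mblk
        else function(d) d * mblk + 1:mblk
  # backward pass: Schur complements C_d and propagation matrices
  # Y_{d+1} = C_{d+1}^{-1} U_d^T (reused verbatim by the forward pass)
  C <- as.matrix(Matrix::t(Q[rd(N), rd(N)]))
  Ys <- vector("list", N + 1)
  for (d in (N - 1):0) {
    Ut <- Matrix::t(Q[rd(d), rd(d + 1)])
    Dt <- Matrix::t(Q[rd(d + 1), rd(d)])
    Ys[[d + 2]] <- Y <- solve(C, as.matrix(Ut))
    C <- as.matrix(Matrix::t(Q[rd(d), rd(d)])) - as.matrix(Dt %*% Y)
  }
  A <- C
  A[1, ] <- 1                       # normalization replaces one balance row
  x <- solve(A, c(1, rep(0, mblk - 1)))
  pi <- numeric(nrow(Q))
  pi[rd(0)] <- x
  for (d in 0:(N - 1)) {
    x <- -as.numeric(Ys[[d + 2]] %*% x)
    pi[rd(d + 1)] <- x
  }
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Stationary noise of the phosphorylated-RR fraction
#'
#' Exact stationary analysis of the molecular-count Markov chain: for each
#' signal, the stationary distribution is obtained by a sparse linear solve
#' on the reachable communicating class, and the mean, standard deviation
#' and noise (SD/mean) of the fraction of phosphorylated RR are reported.
#'
#' @param object A responsive simple-model `"phosphorelay"` with equal
#'   layer totals.
#' @param signals Signal grid; default 20 log-spaced points spanning the
#'   dynamic range of the deterministic curve (signals at 5% and 95% of
#'   the maximal response).
#' @param config A [stochastic_config()].
#' @return A data frame of class `"ctmc_noise"` with columns `ks`,
#'   `mean_fraction`, `sd_fraction`, `cv`; attribute `n_states`.
#' @export
stationary_noise <- function(object, signals = NULL,
                             config = stochastic_config()) {
  stopifnot(inherits(object, "phosphorelay"))
  if (is.null(signals)) signals <- default_signal_grid(object)
  # the reachable class is a positivity pattern: identical for every
  # positive signal, so compute it once; warm-start each solve from the
  # previous grid point's distribution
  reach <- NULL; pi_prev <- NULL
  rows <- lapply(signals, function(ks) {
    gen <- build_generator(object, ks, config)
    if (ks > 0 && !is.null(reach)) r <- reach
    else r <- reachable_states(gen$Q)
    if (ks > 0 && is.null(reach)) reach <<- r
    init <- if (ks > 0 && !is.null(pi_prev)) pi_prev
            else if (ks > 0) binomial_seed(object, ks, gen$N)
    det_fr <- if (ks > 0 && !is.null(object$f))
      tryCatch(predict(object, ks) / object$params[["RR_tot"]],
               error = function(e) 0) else 0
    pi <- stationary_distribution(gen$Q, reach = r, init = init,
                                  N = config$N,
                                  anchor_high = det_fr > 0.5)
    if (ks > 0) pi_prev <<- pi
    fr <- gen$counts[, "RRp"] / gen$N
    m <- sum(pi * fr)
    v <- max(sum(pi * fr^2) - m^2, 0)
    data.frame(ks = ks, mean_fraction = m, sd_fraction = sqrt(v),
               cv = if (m > 0) sqrt(v) / m else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_states") <- (config$N + 1)^4
  class(out) <- c("ctmc_noise", "data.frame")
  out
}

# Product-of-binomials seed centered on the deterministic steady state:
# a cheap approximation of the stationary law that warm-starts the
# Gauss-Seidel solve.
binomial_seed <- function(object, ks, N) {
  if (is.null(object$f)) return(NULL)
  rr <- tryCatch(predict(object, ks), error = function(e) NULL)
  if (is.null(rr)) return(NULL)
  det <- object$f(rr)
  p <- object$params
  pb <- function(x, Tot) stats::dbinom(0:N, N, min(1, max(0, x / Tot)))
  as.numeric(outer(outer(pb(det$HKp, p[["HK_tot"]]),
                         pb(det$RECp, p[["REC_tot"]])),
                   outer(pb(det$Hptp, p[["Hpt_tot"]]),
                         pb(rr, p[["RR_tot"]]))))
}

default_signal_grid <- function(object, n = 20L, lo_frac = 0.05,
                                hi_frac = 0.95) {
  alpha <- maximal_response(object)
  ks_lo <- object$f(lo_frac * alpha)$ks
  ks_hi <- object$f(hi_frac * alpha)$ks
  exp(seq(log(ks_lo), log(ks_hi), length.out = n))
}

#' Compare intrinsic noise between hyperbolic and sigmoidal regimes
#'
#' Builds matched regime pairs for one topology (see [regime_pairs()]):
#' both members of a pair share every rate constant and total except the
#' orientation of the forward/reverse rates at the REC-Hpt and Hpt-RR
#' interfaces -- forward-dominant for the hyperbolic member,
#' reverse-dominant for the sigmoidal member (the relay's tuning knob) --
#' and both classifications are verified.  Noise is evaluated at signals
#' producing matched response fractions (10% to 90% of each member's own
#' maximal response), so the two members are compared at equivalent
#' operating points; a grid spaced in raw signal would concentrate the
#' sigmoidal member's points in its compressed, saturated (low-noise) top
#' end.  The pair comparison uses each member's median CV over the
#' fraction grid.
#'
#' @param id Topology id (14 and 30 are the tunable ones).
#' @param n_pairs Number of matched pairs.
#' @param scheme,seed Sampling scheme and seed (see
#'   [sample_parameter_sets()]).
#' @param config A [stochastic_config()].
#' @param fractions Response fractions of the maximal response at which
#'   noise is evaluated.
#' @param max_draws Sampling cap while collecting `n_pairs`.
#' @return A data frame with columns `pair`, `cv_hyperbolic`,
#'   `cv_sigmoidal`; attribute `n_higher` counts pairs with sigmoidal noise
#'   above hyperbolic noise.
#' @export
noise_regime_comparison <- function(id, n_pairs = 10L,
                                    scheme = sampling_scheme(), seed,
                                    config = stochastic_config(),
                                    fractions = seq(0.1, 0.9, by = 0.2),
                                    max_draws = 400L) {
  if (missing(seed)) stop("a seed is required")
  pairs <- regime_pairs(id, n_pairs, scheme, seed, max_draws)
  med_cv <- function(m) {
    grid <- signal_for_response(m, fractions * maximal_response(m))
    stats::median(stationary_noise(m, grid, config)$cv, na.rm = TRUE)
  }
  cv_h <- vapply(pairs, function(pr) med_cv(pr$hyperbolic), 0)
  cv_s <- vapply(pairs, function(pr) med_cv(pr$sigmoidal), 0)
  out <- data.frame(pair = seq_along(pairs), cv_hyperbolic = cv_h,
                    cv_sigmoidal = cv_s)
  attr(out, "n_higher") <- sum(cv_s > cv_h)
  out
}

#' Matched hyperbolic/sigmoidal parameter pairs
#'
#' Draws base parameter sets and derives from each a matched pair: the
#' rate values at the REC-Hpt and Hpt-RR interfaces are reassigned so that
#' the forward rate takes the larger of the drawn (forward, reverse) values
#' in the hyperbolic member and the smaller in the sigmoidal member;
#' everything else is shared.  Pairs are kept only when the two members
#' classify as intended, so each pair isolates the regime change from the
#' overall kinetic scale.
#'
#' @inheritParams noise_regime_comparison
#' @return A list of pairs, each a list with `"hyperbolic"` and
#'   `"sigmoidal"` `"phosphorelay"` models.
#' @export
regime_pairs <- function(id, n_pairs = 10L, scheme = sampling_scheme(),
                         seed, max_draws = 400L) {
  if (missing(seed)) stop("a seed is required")
  topo <- relay_topology(id)
  if (topo$r3 == 0L || topo$r4 == 0L)
    stop("matched regime pairs need reverse transfer at both lower ",
         "interfaces (topologies such as 14 and 30)")
  sets <- sample_parameter_sets(topo, n = max_draws, scheme = scheme,
                                seed = seed + id)
  pairs <- list()
  for (p in sets) {
    ph <- p; ps <- p
    for (iface in list(c("k3", "k3r"), c("k4", "k4r"))) {
      v <- sort(c(p[[iface[1]]], p[[iface[2]]]))
      ph[[iface[1]]] <- v[2]; ph[[iface[2]]] <- v[1]   # forward-dominant
      ps[[iface[1]]] <- v[1]; ps[[iface[2]]] <- v[2]   # reverse-dominant
    }
    mh <- phosphorelay(topo, ph); ms <- phosphorelay(topo, ps)
    lab_h <- tryCatch(classify(mh)$label, error = function(e) NA)
    lab_s <- tryCatch(classify(ms)$label, error = function(e) NA)
    if (identical(lab_h, "hyperbolic") && identical(lab_s, "sigmoidal"))
      pairs[[length(pairs) + 1L]] <- list(hyperbolic = mh, sigmoidal = ms)
    if (length(pairs) >= n_pairs) break
  }
  if (length(pairs) < n_pairs)
    stop("could not assemble ", n_pairs, " matched pairs within ",
         max_draws, " draws")
  pairs
}

# First n models of each classification label, from equal-totals draws.
regime_draws <- function(id, n_each, scheme, seed, max_draws = 400L) {
  topo <- relay_topology(id)
  sets <- sample_parameter_sets(topo, n = max_draws, scheme = scheme,
                                seed = seed + id)
  hyp <- list(); sig <- list()
  for (p in sets) {
    m <- phosphorelay(topo, p)
    lab <- tryCatch(classify(m)$label, error = function(e) NA_character_)
    if (is.na(lab)) next
    if (lab == "hyperbolic" && length(hyp) < n_each) hyp[[length(hyp) + 1]] <- m
    if (lab == "sigmoidal" && length(sig) < n_each) sig[[length(sig) + 1]] <- m
    if (length(hyp) >= n_each && length(sig) >= n_each) break
  }
  if (length(hyp) < n_each || length(sig) < n_each)
    stop("could not collect ", n_each, " draws per regime within ",
         max_draws, " samples")
  list(hyperbolic = hyp, sigmoidal = sig)
}

#' Empirical stationary moments from Gillespie simulation
#'
#' Cross-check of [stationary_noise()]: simulates one long trajectory,
#' discards a burn-in, and estimates the stationary mean and SD of the
#' phospho-RR fraction from equally spaced samples, with a batch-means
#' standard error for the mean.
#'
#' @param object A simple-model `"phosphorelay"` with equal totals.
#' @param ks Signal value.
#' @param config A [stochastic_config()].
#' @param t_burn,t_end Burn-in and total simulated time.
#' @param n_samples Number of post-burn-in samples.
#' @param n_batches Batches for the standard-error estimate.
#' @return A list with `mean`, `sd`, `se_mean`, `n_samples`.
#' @export
ssa_moments <- function(object, ks, config = stochastic_config(),
                        t_burn = 50, t_end = 500, n_samples = 2000L,
                        n_batches = 20L) {
  stopifnot(inherits(object, "phosphorelay"))
  r <- ctmc_rates(object$params, config, ks)
  times <- seq(t_burn, t_end, length.out = n_samples)
  m <- ssa_path(c(0L, 0L, 0L, 0L), r$N, r$rates, times)
  fr <- m[, 4] / r$N
  batches <- split(fr, cut(seq_along(fr), n_batches, labels = FALSE))
  bm <- vapply(batches, mean, 0)
  list(mean = mean(fr), sd = stats::sd(fr),
       se_mean = stats::sd(bm) / sqrt(n_batches), n_samples = n_samples)
}
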