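#' Parameter-space sampling scheme
#'
#' Describes the "biologically permissible" ranges from which relay
#' parameter sets are drawn.  All draws are log-uniform: rate constants of
#' signaling reactions span several decades in vivo and a log-uniform draw
#' weights each decade equally, which also makes ratio-based criteria
#' (forward vs reverse rates) scale-free.  Defaults: bimolecular transfer
#' rates over `[1e-2, 1e2]` with forward and reverse drawn i.i.d.,
#' first-order hydrolysis rates over `[1e-3, 1e1]`, totals over
#' `[1e-1, 1e1]`.
#'
#' @param bimolecular Length-2 range for `k2, k3, k4, k2r, k3r, k4r` (and
#'   the bifunctional binding rate `k5`).
#' @param hydrolysis Length-2 range for `kh1, kh2` (and `k5r`, `k6`).
#' @param totals Length-2 range for the four layer totals.
#' @param totals_mode `"equal"`: one draw shared by all four layers
#'   (the survey default); `"free"`: four independent draws.
#' @return A list of class `"sampling_scheme"`.
#' @export
sampling_scheme <- function(bimolecular = c(1e-2, 1e2),
                            hydrolysis = c(1e-3, 1e1),
                            totals = c(1e-1, 1e1),
                            totals_mode = c("equal", "free")) {
  totals_mode <- match.arg(totals_mode)
  for (rg in list(bimolecular, hydrolysis, totals))
    if (length(rg) != 2L || any(rg <= 0) || rg[1] >= rg[2])
      stop("ranges must be (low, high) with 0 < low < high")
  structure(list(bimolecular = bimolecular, hydrolysis = hydrolysis,
                 totals = totals, totals_mode = totals_mode),
            class = "sampling_scheme")
}

rlogunif <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Sample parameter sets for a topology
#'
#' Draws `n` parameter sets from `scheme`, log-uniformly, with the rate
#' constants of reactions absent from `topology` fixed at zero.
#' Deterministic given `seed`.
#'
#' @param topology A `"relay_topology"` or integer id.
#' @param n Number of sets.
#' @param scheme A [sampling_scheme()].
#' @param seed Integer seed (mandatory, recorded in the result).
#' @param bifunctional Also draw `k5, k5r, k6` (otherwise 0).
#' @return A list of `n` bound `"relay_parameters"` vectors, with
#'   attributes `seed`, `scheme` and `topology_id`.
#' @export
sample_parameter_sets <- function(topology, n = 1000L,
                                  scheme = sampling_scheme(), seed,
                                  bifunctional = FALSE) {
  topology <- as_relay_topology(topology)
  stopifnot(inherits(scheme, "sampling_scheme"), n >= 1L)
  if (missing(seed)) stop("a seed is required for reproducible sampling")
  seed <- as.integer(seed)     # force before the RNG state is captured
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    bi <- rlogunif(6L, scheme$bimolecular)
    hy <- rlogunif(2L, scheme$hydrolysis)
    tt <- if (scheme$totals_mode == "equal")
      rep(rlogunif(1L, scheme$totals), 4L) else rlogunif(4L, scheme$totals)
    bf <- if (bifunctional)
      c(rlogunif(1L, scheme$bimolecular), rlogunif(2L, scheme$hydrolysis))
    else c(0, 0, 0)
    p <- structure(c(bi[1:3],
                     bi[4] * topology$r2, bi[5] * topology$r3,
                     bi[6] * topology$r4,
                     hy[1] * topology$h1, hy[2] * topology$h2,
                     bf, tt),
                   names = param_names(), class = "relay_parameters")
    out[[i]] <- p
  }
  structure(out, seed = seed, scheme = scheme, topology_id = topology$id)
}
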