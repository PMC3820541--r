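#' Survey sigmoidality across the parameter space of relay topologies
#'
#' For each topology: draws `n` parameter sets from `scheme`, builds the
#' relay model for each, classifies its signal-response curve, and reports
#' the percentage classified sigmoidal (the remainder being hyperbolic).
#' Per-set classification failures (degenerate instances) are excluded and
#' counted.
#'
#' @param ids Integer vector of topology ids (default: the 18 responsive
#'   topologies).
#' @param n Parameter sets per topology.
#' @param scheme A [sampling_scheme()].
#' @param method Classifier passed to [classify()]; the survey default is
#'   the curvature-at-zero criterion.
#' @param seed Integer seed; topology `id` uses sub-seed `seed + id` so
#'   per-topology results are independent of the id subset surveyed.
#' @return A data frame of class `"relay_survey"`: topology code columns,
#'   `n`, `n_sigmoidal`, `pct_sigmoidal` (0..100), `n_failed`; attributes
#'   `seed`, `scheme`, `method`.
#' @examples
#' \donttest{
#' survey_topologies(c(14, 30), n = 100, seed = 1)
#' }
#' @export
survey_topologies <- function(ids = NULL, n = 1000L,
                              scheme = sampling_scheme(),
                              method = c("curvature_at_zero", "sign_change"),
                              seed) {
  method <- match.arg(method)
  if (missing(seed)) stop("a seed is required")
  tab <- relay_topologies()
  if (is.null(ids)) ids <- tab$id[tab$responsive]
  rows <- lapply(ids, function(id) {
    topo <- relay_topology(id)
    if (!topo$responsive)
      stop("topology ", id, " is non-responsive; nothing to survey")
    sets <- sample_parameter_sets(topo, n = n, scheme = scheme,
                                  seed = seed + id)
    lab <- vapply(sets, function(p) {
      tryCatch(classify(phosphorelay(topo, p), method = method)$label,
               error = function(e) NA_character_)
    }, "")
    ok <- !is.na(lab)
    data.frame(id = id, r2 = topo$r2, r3 = topo$r3, r4 = topo$r4,
               h1 = topo$h1, h2 = topo$h2, n = sum(ok),
               n_sigmoidal = sum(lab[ok] == "sigmoidal"),
               pct_sigmoidal = 100 * mean(lab[ok] == "sigmoidal"),
               n_failed = sum(!ok))
  })
  structure(do.call(rbind, rows), seed = seed, scheme = scheme,
            method = method, class = c("relay_survey", "data.frame"))
}

#' @export
print.relay_survey <- function(x, ...) {
  cat(sprintf("Parameter-space survey (%d sets/topology, %s, seed %d)\n",
              max(x$n + x$n_failed), attr(x, "method"), attr(x, "seed")))
  y <- as.data.frame(x)
  y$pct_sigmoidal <- sprintf("%.2f", y$pct_sigmoidal)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Forward/reverse rate-ratio summary by response regime
#'
#' For one topology, splits `n` sampled parameter sets by their
#' classification and summarizes the ratios `k3/k3r` and `k4/k4r` (mean,
#' minimum, maximum) within each regime.  A mean ratio below one in the
#' sigmoidal regime is the signature of reverse-transfer dominance.
#'
#' @inheritParams survey_topologies
#' @param id Topology id.
#' @return A data frame with columns `ratio`, `stat`, `hyperbolic`,
#'   `sigmoidal`, plus counts as attribute `n_by_label`.
#' @export
regime_ratio_summary <- function(id, n = 1000L, scheme = sampling_scheme(),
                                 method = c("curvature_at_zero",
                                            "sign_change"), seed) {
  method <- match.arg(method)
  if (missing(seed)) stop("a seed is required")
  topo <- relay_topology(id)
  sets <- sample_parameter_sets(topo, n = n, scheme = scheme,
                                seed = seed + id)
  lab <- vapply(sets, function(p) {
    tryCatch(classify(phosphorelay(topo, p), method = method)$label,
             error = function(e) NA_character_)
  }, "")
  r3 <- vapply(sets, function(p) p[["k3"]] / p[["k3r"]], 0)
  r4 <- vapply(sets, function(p) p[["k4"]] / p[["k4r"]], 0)
  stat_row <- function(v, lab, f) {
    c(hyperbolic = f(v[lab == "hyperbolic" & !is.na(lab)]),
      sigmoidal = f(v[lab == "sigmoidal" & !is.na(lab)]))
  }
  grid <- expand.grid(ratio = c("k3/k3r", "k4/k4r"),
                      stat = c("mean", "min", "max"),
                      stringsAsFactors = FALSE)
  vals <- t(mapply(function(ratio, stat) {
    v <- if (ratio == "k3/k3r") r3 else r4
    f <- switch(stat, mean = mean, min = min, max = max)
    stat_row(v, lab, f)
  }, grid$ratio, grid$stat))
  out <- cbind(grid, as.data.frame(vals))
  attr(out, "n_by_label") <- table(factor(lab,
                                          c("hyperbolic", "sigmoidal")))
  attr(out, "seed") <- seed
  out
}
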