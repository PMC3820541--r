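#' Rate constants and total concentrations for one relay instance
#'
#' Bundles the 11 mass-action rate constants and the 4 per-layer total
#' protein concentrations of a four-layered phosphorelay.  Units are
#' arbitrary but must be coherent: bimolecular rate constants in
#' concentration^-1 time^-1, first-order rates in time^-1, totals in
#' concentration.
#'
#' @param k2,k3,k4 Forward phosphotransfer rate constants (HK~P -> REC,
#'   REC~P -> Hpt, Hpt~P -> RR); must be positive.
#' @param k2r,k3r,k4r Reverse phosphotransfer rate constants; `>= 0`.
#' @param kh1,kh2 Hydrolysis rate constants of REC~P and RR~P; `>= 0`.
#' @param k5,k5r,k6 Bifunctional-HK binding, unbinding and catalytic
#'   dephosphorylation rate constants (only used by the bifunctional
#'   variant); `>= 0`.
#' @param HK_tot,REC_tot,Hpt_tot,RR_tot Total protein concentration of each
#'   layer; must be positive.
#' @return A named numeric vector of class `"relay_parameters"` with the 15
#'   entries in the order `k2, k3, k4, k2r, k3r, k4r, kh1, kh2, k5, k5r, k6,
#'   HK_tot, REC_tot, Hpt_tot, RR_tot`.
#' @examples
#' # a relay with strong reverse transfer at the lower layers
#' relay_parameters(k2 = 5, k3 = 0.1, k4 = 0.01, k3r = 10, k4r = 0.1,
#'                  kh1 = 10, kh2 = 0.001,
#'                  HK_tot = 5, REC_tot = 1, Hpt_tot = 1, RR_tot = 10)
#' @export
relay_parameters <- function(k2, k3, k4, k2r = 0, k3r = 0, k4r = 0,
                             kh1 = 0, kh2 = 0, k5 = 0, k5r = 0, k6 = 0,
                             HK_tot = 1, REC_tot = 1, Hpt_tot = 1,
                             RR_tot = 1) {
  p <- c(k2 = k2, k3 = k3, k4 = k4, k2r = k2r, k3r = k3r, k4r = k4r,
         kh1 = kh1, kh2 = kh2, k5 = k5, k5r = k5r, k6 = k6,
         HK_tot = HK_tot, REC_tot = REC_tot, Hpt_tot = Hpt_tot,
         RR_tot = RR_tot)
  validate_relay_parameters(p)
  structure(p, class = "relay_parameters")
}

param_names <- function() {
  c("k2", "k3", "k4", "k2r", "k3r", "k4r", "kh1", "kh2", "k5", "k5r", "k6",
    "HK_tot", "REC_tot", "Hpt_tot", "RR_tot")
}

validate_relay_parameters <- function(p) {
  if (!is.numeric(p) || !all(param_names() %in% names(p)))
    stop("parameters must be a named numeric vector with entries ",
         paste(param_names(), collapse = ", "))
  if (anyNA(p) || any(p < 0))
    stop("all parameters must be finite and >= 0")
  strict <- c("k2", "k3", "k4", "HK_tot", "REC_tot", "Hpt_tot", "RR_tot")
  if (any(p[strict] <= 0))
    stop("forward rates k2, k3, k4 and all totals must be > 0")
  invisible(p)
}

as_relay_parameters <- function(p) {
  if (inherits(p, "relay_parameters")) return(p)
  p <- unlist(p)
  validate_relay_parameters(p)
  structure(p[param_names()], class = "relay_parameters")
}

#' Bind a parameter set to a topology
#'
#' Returns a copy of `params` with every rate constant whose reaction is
#' absent from `topology` set exactly to zero; all other entries are left
#' unchanged.  Rates required by the topology (the three forward transfers
#' and any flagged reverse/hydrolysis reaction) must be strictly positive,
#' otherwise the instance is degenerate and an error is signalled.
#'
#' @param topology A `"relay_topology"` or integer id.
#' @param params A `"relay_parameters"` vector (or coercible named vector).
#' @return A `"relay_parameters"` vector bound to `topology`.
#' @export
bind_parameters <- function(topology, params) {
  topology <- as_relay_topology(topology)
  p <- as_relay_parameters(params)
  flags <- c(k2r = topology$r2, k3r = topology$r3, k4r = topology$r4,
             kh1 = topology$h1, kh2 = topology$h2)
  for (nm in names(flags)) {
    if (flags[[nm]] == 0L) {
      p[[nm]] <- 0
    } else if (p[[nm]] <= 0) {
      stop("degenerate instance: topology ", topology$id, " requires ", nm,
           " > 0")
    }
  }
  p
}

#' @export
print.relay_parameters <- function(x, ...) {
  cat("Phosphorelay parameter set:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Read parameter sets from a CSV file
#'
#' Each row is one parameter set; columns are the 15 entries in the standard
#' order (`k2, k3, k4, k2r, k3r, k4r, kh1, kh2, k5, k5r, k6, HK_tot,
#' REC_tot, Hpt_tot, RR_tot`), either named in a header or positional.
#'
#' @param path Path to a CSV file.
#' @return A list of `"relay_parameters"` vectors.
#' @export
read_parameter_sets <- function(path) {
  d <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (!all(param_names() %in% names(d))) {
    d <- utils::read.csv(path, header = FALSE)
    if (ncol(d) != 15L)
      stop("CSV must have the 15 standard columns (named or positional)")
    names(d) <- param_names()
  }
  lapply(seq_len(nrow(d)), function(i) as_relay_parameters(d[i, param_names()]))
}

#' Read a single parameter set from a flat key:value config file
#'
#' Accepts YAML (or any `key: value` per line file) whose keys are exactly
#' the parameter names.  Missing optional rates default to 0.
#'
#' @param path Path to the config file.
#' @return A `"relay_parameters"` vector.
#' @export
read_relay_config <- function(path) {
  if (requireNamespace("yaml", quietly = TRUE)) {
    vals <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- strsplit(lines, ":", fixed = TRUE)
    vals <- stats::setNames(lapply(kv, function(x) as.numeric(trimws(x[2]))),
                            vapply(kv, function(x) trimws(x[1]), ""))
  }
  unknown <- setdiff(names(vals), param_names())
  if (length(unknown))
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  full <- stats::setNames(numeric(15L), param_names())
  full[names(vals)] <- unlist(vals)
  as_relay_parameters(full)
}
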