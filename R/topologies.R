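#' Enumerate the 32 four-layered phosphorelay topologies
#'
#' A four-layered phosphorelay HK -> REC -> Hpt -> RR always carries the four
#' forward phosphotransfer steps; topologies differ in which of the three
#' reverse phosphotransfer reactions (HK<->REC, REC<->Hpt, Hpt<->RR) and which
#' of the two hydrolysis reactions (on REC~P and on RR~P) are present.  That
#' gives `2^5 = 32` distinct topologies, identified here by an integer id
#' 1..32 and a 5-bit presence code `(r2, r3, r4, h1, h2)`.
#'
#' The id order groups topologies into four blocks of eight by hydrolysis
#' pattern -- ids 1-8: `(h1,h2) = (0,1)`, 9-16: `(1,0)`, 17-24: `(0,0)`,
#' 25-32: `(1,1)` -- with a fixed within-block order of the reverse-transfer
#' codes: (100), (010), (001), (101), (110), (011), (000), (111).
#'
#' @return A data frame with 32 rows and columns `id`, `r2`, `r3`, `r4`
#'   (reverse-transfer flags, 0/1), `h1`, `h2` (hydrolysis flags, 0/1) and
#'   `responsive` (logical, see [is_responsive()]).
#' @seealso [relay_topology()], [is_responsive()]
#' @examples
#' tab <- relay_topologies()
#' sum(!tab$responsive)  # 14 non-responsive structures
#' @export
relay_topologies <- function() {
  rev_order <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L), c(1L, 0L, 1L),
                    c(1L, 1L, 0L), c(0L, 1L, 1L), c(0L, 0L, 0L), c(1L, 1L, 1L))
  hyd_order <- list(c(0L, 1L), c(1L, 0L), c(0L, 0L), c(1L, 1L))
  rev <- do.call(rbind, rev_order)[rep(seq_len(8L), times = 4L), ]
  hyd <- do.call(rbind, hyd_order)[rep(seq_len(4L), each = 8L), ]
  out <- data.frame(id = 1:32,
                    r2 = rev[, 1L], r3 = rev[, 2L], r4 = rev[, 3L],
                    h1 = hyd[, 1L], h2 = hyd[, 2L])
  out$responsive <- out$h2 == 1L | (out$h1 == 1L & out$r3 == 1L & out$r4 == 1L)
  out
}

#' Look up a single relay topology
#'
#' @param id Integer topology id in 1..32, or `NULL` when `rev`/`hyd` are given.
#' @param rev Length-3 0/1 vector `(r2, r3, r4)` of reverse-transfer flags.
#' @param hyd Length-2 0/1 vector `(h1, h2)` of hydrolysis flags.
#' @return An object of class `"relay_topology"`: a list with elements `id`,
#'   `r2`, `r3`, `r4`, `h1`, `h2` and `responsive`.
#' @examples
#' relay_topology(30)                 # rev (0,1,1), hyd (1,1)
#' relay_topology(rev = c(0, 1, 1), hyd = c(1, 0))  # id 14
#' @export
relay_topology <- function(id = NULL, rev = NULL, hyd = NULL) {
  tab <- relay_topologies()
  if (!is.null(id)) {
    id <- as.integer(id)
    if (length(id) != 1L || is.na(id) || id < 1L || id > 32L)
      stop("topology id must be a single integer in 1..32")
    row <- tab[tab$id == id, ]
  } else {
    if (is.null(rev) || is.null(hyd) || length(rev) != 3L || length(hyd) != 2L)
      stop("supply either `id`, or `rev` (length 3) and `hyd` (length 2)")
    hit <- tab$r2 == rev[1L] & tab$r3 == rev[2L] & tab$r4 == rev[3L] &
      tab$h1 == hyd[1L] & tab$h2 == hyd[2L]
    row <- tab[hit, ]
  }
  structure(as.list(row), class = "relay_topology")
}

#' @export
print.relay_topology <- function(x, ...) {
  cat(sprintf("Phosphorelay topology %d: rev (%d %d %d), hyd (%d %d) -- %s\n",
              x$id, x$r2, x$r3, x$r4, x$h1, x$h2,
              if (x$responsive) "responsive" else "non-responsive"))
  invisible(x)
}

#' Structural responsiveness of a relay topology
#'
#' A topology is non-responsive when its steady-state output (phosphorylated
#' RR) jumps to its maximal level for any positive signal, so the relay
#' cannot grade its response.  This happens exactly when hydrolysis on RR is
#' absent (`h2 = 0`) and, in addition, hydrolysis on REC is absent (`h1 = 0`)
#' or one of the reverse transfers REC<->Hpt (`r3`) or Hpt<->RR (`r4`) is
#' absent.  14 of the 32 topologies are non-responsive under this rule.
#'
#' @param topology A `"relay_topology"` object or an integer id.
#' @return Logical scalar.
#' @seealso [responsiveness_screen()] for the numerical counterpart.
#' @export
is_responsive <- function(topology) {
  topology <- as_relay_topology(topology)
  isTRUE(topology$responsive)
}

as_relay_topology <- function(topology) {
  if (inherits(topology, "relay_topology")) return(topology)
  if (is.numeric(topology) && length(topology) == 1L)
    return(relay_topology(topology))
  stop("expected a relay_topology or an integer id")
}

# Self-check of the id<->code map against every pairing printed in the
# source tables (ran at load; cheap, guards accidental reordering).
check_topology_table <- function() {
  tab <- relay_topologies()
  printed <- rbind(
    c(1, 1, 0, 0, 0, 1), c(2, 0, 1, 0, 0, 1), c(3, 0, 0, 1, 0, 1),
    c(4, 1, 0, 1, 0, 1), c(5, 1, 1, 0, 0, 1), c(6, 0, 1, 1, 0, 1),
    c(7, 0, 0, 0, 0, 1), c(8, 1, 1, 1, 0, 1), c(14, 0, 1, 1, 1, 0),
    c(16, 1, 1, 1, 1, 0), c(25, 1, 0, 0, 1, 1), c(26, 0, 1, 0, 1, 1),
    c(27, 0, 0, 1, 1, 1), c(28, 1, 0, 1, 1, 1), c(29, 1, 1, 0, 1, 1),
    c(30, 0, 1, 1, 1, 1), c(31, 0, 0, 0, 1, 1), c(32, 1, 1, 1, 1, 1))
  got <- as.matrix(tab[match(printed[, 1], tab$id),
                       c("id", "r2", "r3", "r4", "h1", "h2")])
  stopifnot(all(got == printed))
  invisible(TRUE)
}

.onLoad <- function(libname, pkgname) {
  check_topology_table()
}
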