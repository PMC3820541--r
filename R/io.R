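#' Export a signal-response curve
#'
#' Writes the curve as CSV (columns `rr`, `fraction`, `ks`) and, optionally,
#' as JSON with a provenance block (package version, topology id, bound
#' parameters, maximal response).
#'
#' @param curve A `"signal_response_curve"`.
#' @param csv_path Output CSV path (or `NULL` to skip).
#' @param json_path Output JSON path (or `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_curve <- function(curve, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(curve, "signal_response_curve"))
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(curve)[, c("rr", "fraction", "ks")],
                     csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- list(
      provenance = list(
        package = "phosphorelay",
        version = as.character(utils::packageVersion("phosphorelay")),
        topology_id = attr(curve, "topology_id"),
        parameters = as.list(unclass(attr(curve, "parameters"))),
        alpha = attr(curve, "alpha")),
      curve = as.data.frame(curve))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csv_path, json = json_path))
}

#' Export a parameter-space survey
#'
#' Writes the survey table as CSV with a provenance JSON (seed, scheme,
#' classification method) beside it if requested.  Percentages keep full
#' precision in the CSV; the print method rounds to two decimals.
#'
#' @param survey A `"relay_survey"`.
#' @param csv_path Output CSV path.
#' @param json_path Optional provenance JSON path.
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(survey, csv_path, json_path = NULL) {
  stopifnot(inherits(survey, "relay_survey"))
  utils::write.csv(as.data.frame(survey), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    sch <- attr(survey, "scheme")
    jsonlite::write_json(
      list(package = "phosphorelay",
           version = as.character(utils::packageVersion("phosphorelay")),
           seed = attr(survey, "seed"), method = attr(survey, "method"),
           scheme = unclass(sch)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csv_path, json = json_path))
}
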