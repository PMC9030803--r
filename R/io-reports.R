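# JSON reports: evaluation records, selection traces, pipeline manifests.

#' Write a report object to JSON
#'
#' Serializes evaluation records, selection states, mRMR rankings or any
#' list-like report to JSON with full numeric precision so that
#' write-then-read round-trips losslessly.
#'
#' @param record List-like report object.
#' @param path Output path.
#' @export
write_report <- function(record, path) {
  # jsonlite drops names of atomic vectors; promote them to objects so
  # the read-back equals the written record
  promote <- function(x) {
    if (is.data.frame(x)) {
      x
    } else if (is.list(x)) {
      lapply(x, promote)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  jsonlite::write_json(promote(record), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path Path to a JSON report.
#' @return The deserialized report (lists and vectors).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
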