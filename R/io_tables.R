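# Tab-separated channel/event tables (BIDS-iEEG style dialects) and result
# writers (TSV for tabular results, JSON for nested ones).

#' Read a channels.tsv metadata table
#'
#' Expects header columns `name`, `shaft`, `index`, `region`, `hemisphere`,
#' `x`, `y`, `z`. Unrecognised region strings become `"other"` with a
#' warning; duplicate (shaft, index) pairs are an integrity error.
#'
#' @param path TSV file.
#' @return validated channel table (see [channel_table()]).
#' @export
read_channels <- function(path) {
  if (!file.exists(path)) stop_argument("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "shaft", "index", "region", "hemisphere")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_integrity("channels.tsv missing columns: ", paste(missing, collapse = ", "))
  }
  channel_table(label = tab$name, shaft = tab$shaft, index_on_shaft = tab$index,
                region = tab$region, hemisphere = tab$hemisphere,
                x = if (is.null(tab$x)) NA_real_ else tab$x,
                y = if (is.null(tab$y)) NA_real_ else tab$y,
                z = if (is.null(tab$z)) NA_real_ else tab$z)
}

#' Read an events.tsv table
#'
#' Expects columns `onset`, `duration`, `condition`, `phase`; rows are
#' returned sorted by onset and validated (strictly increasing onsets,
#' non-negative durations). An empty table with a header is valid.
#'
#' @param path TSV file.
#' @return [event_table()] data frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_argument("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(onset = "character"))
  need <- c("onset", "duration", "condition", "phase")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_integrity("events.tsv missing columns: ", paste(missing, collapse = ", "))
  }
  onset <- suppressWarnings(as.numeric(tab$onset))
  if (nrow(tab) > 0 && any(is.na(onset))) {
    stop_argument("events.tsv onset column is not numeric")
  }
  if (nrow(tab) == 0) {
    return(validate_events(data.frame(onset = numeric(0), duration = numeric(0),
                                      condition = character(0), phase = character(0))))
  }
  event_table(onset, tab$duration, tab$condition, tab$phase)
}

#' Write analysis results to disk
#'
#' Site labels and response-onset summaries are written as TSV; classifier
#' reports and cluster details as JSON. Files re-read losslessly for the
#' fields written.
#'
#' @param results a `site_labels` data frame, `rol_result`,
#'   `classifier_report` or `cluster_result` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) UseMethod("write_results")

#' @export
write_results.site_labels <- function(results, path) {
  out <- as.data.frame(results)
  out$responsive_spans <- vapply(out$responsive_spans, spans_to_json, "")
  out$specific_spans <- vapply(out$specific_spans, spans_to_json, "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.rol_result <- function(results, path) {
  utils::write.table(results$regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  trial_path <- sub("(\\.[^.]+)?$", "_trials\\1", path)
  utils::write.table(results$trials, trial_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
write_results.classifier_report <- function(results, path) {
  jsonlite::write_json(unclass(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
write_results.cluster_result <- function(results, path) {
  jsonlite::write_json(unclass(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

spans_to_json <- function(spans) {
  if (is.null(spans) || nrow(spans) == 0) return("[]")
  as.character(jsonlite::toJSON(unname(apply(spans, 1, function(r)
    list(start = unname(r[1]), end = unname(r[2])))), auto_unbox = TRUE,
    digits = NA))
}

#' Read back a site-label TSV written by [write_results()]
#' @param path TSV file.
#' @return data frame with span columns decoded to matrices.
#' @export
read_site_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  decode <- function(s) {
    v <- jsonlite::fromJSON(s)
    if (length(v) == 0) {
      matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
    } else {
      m <- as.matrix(v[, c("start", "end")])
      dimnames(m) <- list(NULL, c("start", "end"))
      m
    }
  }
  tab$responsive_spans <- lapply(tab$responsive_spans, decode)
  tab$specific_spans <- lapply(tab$specific_spans, decode)
  class(tab) <- c("site_labels", "data.frame")
  tab
}
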