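#' Continuous multichannel SEEG recording
#'
#' The central raw-data container: a channels-by-samples voltage matrix (in
#' microvolts) with its sampling rate and a channel metadata table. Channel
#' metadata drive the flanking-Laplacian re-reference (shaft membership and
#' contact order) and all region-level summaries.
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channels data frame with columns `label`, `shaft`,
#'   `index_on_shaft`, `region`, `hemisphere` and optional `x`, `y`, `z`
#'   (MNI mm). One row per signal row, same order.
#' @param start_time recording start offset in seconds (event onsets are
#'   absolute, i.e. relative to time 0 of this clock).
#' @return object of class `seeg_recording`.
#' @seealso [channel_table()], [read_recording()]
#' @export
seeg_recording <- function(signal, fs, channels, start_time = 0) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop_argument("signal must be a numeric channels x samples matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_argument("fs must be a single positive number")
  }
  if (any(!is.finite(signal))) stop_argument("signal contains non-finite values")
  channels <- validate_channels(channels)
  if (nrow(channels) != nrow(signal)) {
    stop_integrity("channel table has ", nrow(channels),
                   " rows but signal has ", nrow(signal), " channels")
  }
  structure(list(signal = signal, fs = fs, channels = channels,
                 start_time = start_time),
            class = "seeg_recording")
}

#' Channel metadata regions recognised by the pipeline
#' @export
fc_regions <- function() {
  c("frontal_operculum", "anterior_insula", "posterior_insula",
    "visual", "premotor", "other")
}

#' Build a channel metadata table
#'
#' @param label channel labels (unique).
#' @param shaft electrode shaft identity (groups contacts for the Laplacian).
#' @param index_on_shaft 1-based contact position along the shaft.
#' @param region anatomical region, one of [fc_regions()]; unrecognised
#'   values are mapped to `"other"` with a warning.
#' @param hemisphere `"L"` or `"R"`.
#' @param x,y,z optional MNI coordinates (mm).
#' @return validated data frame.
#' @export
channel_table <- function(label, shaft, index_on_shaft, region = "other",
                          hemisphere = "L", x = NA_real_, y = NA_real_,
                          z = NA_real_) {
  validate_channels(data.frame(label = label, shaft = shaft,
                               index_on_shaft = as.integer(index_on_shaft),
                               region = region, hemisphere = hemisphere,
                               x = x, y = y, z = z,
                               stringsAsFactors = FALSE))
}

validate_channels <- function(channels) {
  required <- c("label", "shaft", "index_on_shaft", "region", "hemisphere")
  missing <- setdiff(required, names(channels))
  if (length(missing)) {
    stop_integrity("channel table missing columns: ", paste(missing, collapse = ", "))
  }
  channels$label <- as.character(channels$label)
  channels$shaft <- as.character(channels$shaft)
  channels$index_on_shaft <- as.integer(channels$index_on_shaft)
  if (anyDuplicated(channels$label)) stop_integrity("duplicate channel labels")
  key <- paste(channels$shaft, channels$index_on_shaft)
  if (anyDuplicated(key)) {
    stop_integrity("duplicate (shaft, index_on_shaft) pair: ",
                   key[duplicated(key)][1])
  }
  unknown <- !(channels$region %in% fc_regions())
  if (any(unknown)) {
    warning("unrecognised region(s) ",
            paste(unique(channels$region[unknown]), collapse = ", "),
            " mapped to 'other'", call. = FALSE)
    channels$region[unknown] <- "other"
  }
  if (!all(channels$hemisphere %in% c("L", "R"))) {
    stop_integrity("hemisphere must be 'L' or 'R'")
  }
  for (col in c("x", "y", "z")) {
    if (is.null(channels[[col]])) channels[[col]] <- NA_real_
  }
  rownames(channels) <- NULL
  channels
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("<seeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat("  shafts:", paste(unique(x$channels$shaft), collapse = ", "), "\n")
  cat("  regions:", paste(unique(x$channels$region), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.seeg_recording <- function(x) dim(x$signal)

n_samples <- function(rec) ncol(rec$signal)
rec_duration <- function(rec) ncol(rec$signal) / rec$fs

channel_index <- function(rec, channel) {
  if (is.numeric(channel)) return(as.integer(channel))
  idx <- match(channel, rec$channels$label)
  if (any(is.na(idx))) {
    stop_integrity("unknown channel(s): ", paste(channel[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Event table constructor / validator
#'
#' @param onset event onsets in seconds (strictly increasing).
#' @param duration event durations in seconds (non-negative).
#' @param condition condition label per event.
#' @param phase one of `"cue"`, `"receipt"`, `"bite"`.
#' @return data frame of class `fc_events`, sorted by onset.
#' @export
event_table <- function(onset, duration, condition, phase) {
  ev <- data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
                   condition = as.character(condition),
                   phase = as.character(phase), stringsAsFactors = FALSE)
  validate_events(ev)
}

validate_events <- function(ev) {
  required <- c("onset", "duration", "condition", "phase")
  missing <- setdiff(required, names(ev))
  if (length(missing)) {
    stop_integrity("event table missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(is.na(ev$onset))) stop_argument("event onsets contain NA (parse failure?)")
  ev <- ev[order(ev$onset), , drop = FALSE]
  if (nrow(ev) > 1 && any(diff(ev$onset) <= 0)) {
    stop_integrity("event onsets must be strictly increasing")
  }
  if (any(ev$duration < 0)) stop_integrity("event durations must be >= 0")
  if (!all(ev$phase %in% c("cue", "receipt", "bite"))) {
    stop_integrity("event phase must be cue, receipt or bite")
  }
  rownames(ev) <- NULL
  class(ev) <- c("fc_events", "data.frame")
  ev
}
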