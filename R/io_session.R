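# HDF5 session container: one file holds the signal, sampling rate, channel
# table and (optionally) the event table, lossless in double precision.

#' Write a recording (and optionally events) to an HDF5 session file
#'
#' @param rec [seeg_recording()].
#' @param path output `.h5` file (overwritten if present).
#' @param events optional [event_table()] stored alongside the signal.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, events = NULL) {
  stopifnot(inherits(rec, "seeg_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$signal, path, "signal")
  rhdf5::h5write(rec$fs, path, "fs")
  rhdf5::h5write(rec$start_time, path, "start_time")
  ch <- rec$channels
  ch$x <- as.numeric(ch$x); ch$y <- as.numeric(ch$y); ch$z <- as.numeric(ch$z)
  rhdf5::h5write(ch, path, "channels")
  if (!is.null(events)) {
    rhdf5::h5write(as.data.frame(unclass(events)), path, "events")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

read_session_h5 <- function(path) {
  if (!file.exists(path)) stop_argument("file not found: ", path)
  contents <- tryCatch(rhdf5::h5ls(path, recursive = FALSE)$name,
                       error = function(e) stop_argument("not a readable HDF5 file: ", path))
  need <- c("signal", "fs", "channels")
  if (!all(need %in% contents)) {
    stop_argument("HDF5 session file missing datasets: ",
                  paste(setdiff(need, contents), collapse = ", "))
  }
  signal <- rhdf5::h5read(path, "signal")
  fs <- as.numeric(rhdf5::h5read(path, "fs"))
  start_time <- if ("start_time" %in% contents)
    as.numeric(rhdf5::h5read(path, "start_time")) else 0
  drop_dims <- function(df) {
    as.data.frame(lapply(df, function(col) as.vector(col)),
                  stringsAsFactors = FALSE)
  }
  channels <- drop_dims(as.data.frame(rhdf5::h5read(path, "channels")))
  events <- if ("events" %in% contents)
    validate_events(drop_dims(as.data.frame(rhdf5::h5read(path, "events")))) else NULL
  rhdf5::h5closeAll()
  rec <- seeg_recording(signal, fs, channels, start_time)
  attr(rec, "events") <- events
  rec
}

#' Read a recording from EDF or an HDF5 session file
#'
#' @param path input file.
#' @param format `"hdf5"` or `"edf"`.
#' @param channels optional channel metadata table replacing what the file
#'   carries; its row count must match the stored channel count.
#' @return [seeg_recording()]; for HDF5 sessions a stored event table is
#'   attached as `attr(rec, "events")`.
#' @export
read_recording <- function(path, format = c("hdf5", "edf"), channels = NULL) {
  format <- match.arg(format)
  rec <- switch(format, hdf5 = read_session_h5(path), edf = read_edf(path))
  if (!is.null(channels)) {
    channels <- validate_channels(channels)
    if (nrow(channels) != nrow(rec$signal)) {
      stop_integrity("recording has ", nrow(rec$signal),
                     " channels but supplied table lists ", nrow(channels))
    }
    rec$channels <- channels
  }
  rec
}
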