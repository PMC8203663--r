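# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores 16-bit samples with a per-signal linear physical calibration.
# The writer emits a single data record spanning the whole recording, which
# every conforming reader (including this one) accepts; amplitudes are
# quantised to the 16-bit digital range, so round trips are exact only to
# (physical range)/65535.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- trimws(formatC(x, format = "g", digits = 7))
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' @param rec [seeg_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "seeg_recording"))
  ns <- nrow(rec$signal)
  nsamp <- ncol(rec$signal)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("foodcue", 80), edf_pad("synthetic", 80),
    edf_pad("01.01.20", 8), edf_pad("00.00.00", 8),
    edf_num(hdr_bytes, 8), edf_pad("", 44),
    edf_num(1, 8), edf_num(nsamp / rec$fs, 8), edf_num(ns, 4)
  ), con, eos = NULL)
  pmin_ <- apply(rec$signal, 1, min)
  pmax_ <- apply(rec$signal, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  field <- function(f, w) paste(vapply(f, edf_pad, "", width = w), collapse = "")
  writeChar(paste0(
    field(rec$channels$label, 16), field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    paste(vapply(pmin_, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax_, edf_num, "", width = 8), collapse = ""),
    field(rep("-32768", ns), 8), field(rep("32767", ns), 8),
    field(rep("", ns), 80), field(rep(nsamp, ns), 8), field(rep("", ns), 32)
  ), con, eos = NULL)
  for (i in seq_len(ns)) {
    scale <- (pmax_[i] - pmin_[i]) / 65535
    dig <- as.integer(round((rec$signal[i, ] - pmin_[i]) / scale) - 32768)
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Channel metadata beyond the label are not stored in EDF; shaft and contact
#' index are inferred from labels of the form `<shaft><number>` when possible,
#' otherwise each channel becomes its own shaft.
#'
#' @param path EDF file.
#' @return [seeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_argument("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(n) {
    v <- suppressWarnings(as.numeric(trimws(rd(n))))
    if (is.na(v)) stop_argument("not a valid EDF file: ", path)
    v
  }
  version <- trimws(rd(8))
  if (version != "0") stop_argument("not a valid EDF file: ", path)
  rd(80 + 80 + 8 + 8)
  num(8)                      # header bytes
  rd(44)
  n_rec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  spr <- as.numeric(fld(8)); fld(32)
  signal <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2,
                     endian = "little", signed = TRUE)
      phys <- pmin_[i] + (dig - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      signal[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  fs <- spr[1] / (rec_dur / 1)
  m <- regmatches(labels, regexec("^([A-Za-z]+)([0-9]+)$", labels))
  shaft <- vapply(seq_along(m), function(i)
    if (length(m[[i]]) == 3) m[[i]][2] else labels[i], "")
  idx <- vapply(seq_along(m), function(i)
    if (length(m[[i]]) == 3) as.integer(m[[i]][3]) else 1L, 1L)
  seeg_recording(signal, fs, channel_table(labels, shaft, idx))
}
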