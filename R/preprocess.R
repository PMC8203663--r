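# Signal chain: notch, flanking-Laplacian re-reference, Hilbert band power,
# Hann spectrogram, epoching with pooled-baseline z-scoring.
#
# All zero-phase filtering goes through pad_filtfilt(): 1 s odd-reflection
# padding at both ends before signal::filtfilt, which keeps IIR start-up
# transients out of the retained samples.

pad_filtfilt <- function(filt, x, fs, pad = 1) {
  n <- length(x)
  np <- min(as.integer(round(pad * fs)), n - 1L)
  xp <- c(2 * x[1] - rev(x[2:(np + 1)]), x,
          2 * x[n] - rev(x[(n - np):(n - 1)]))
  signal::filtfilt(filt, xp)[(np + 1):(np + n)]
}

#' Attenuate mains noise with zero-phase notch filters
#'
#' Cascaded 2nd-order Butterworth band-stop filters (two-pass, so 4th-order
#' magnitude response) centred at each frequency, width `f0 / q`.
#'
#' @param rec [seeg_recording()].
#' @param freqs notch centre frequencies in Hz (default 60 Hz and its first
#'   two harmonics); must be below Nyquist.
#' @param q notch quality factor (centre / width).
#' @return filtered [seeg_recording()].
#' @export
notch_filter <- function(rec, freqs = c(60, 120, 180), q = 35) {
  stopifnot(inherits(rec, "seeg_recording"))
  if (any(freqs >= rec$fs / 2)) {
    stop_argument("notch frequency at or above Nyquist (", rec$fs / 2, " Hz)")
  }
  for (f0 in freqs) {
    bw <- f0 / q
    filt <- signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / (rec$fs / 2),
                           type = "stop")
    for (ch in seq_len(nrow(rec$signal))) {
      rec$signal[ch, ] <- pad_filtfilt(filt, rec$signal[ch, ], rec$fs)
    }
  }
  rec
}

#' Flanking-contact Laplacian re-reference
#'
#' Each interior contact has the mean of its two shaft neighbours
#' subtracted; shaft-end contacts subtract their single neighbour; shafts of
#' one contact are left unchanged with a warning. Suppresses far-field
#' volume-conducted components while keeping local field differences.
#'
#' @param rec [seeg_recording()] whose channel table carries `shaft` and
#'   `index_on_shaft`.
#' @return re-referenced [seeg_recording()].
#' @export
laplacian_rereference <- function(rec) {
  stopifnot(inherits(rec, "seeg_recording"))
  ch <- rec$channels
  if (any(is.na(ch$shaft)) || any(is.na(ch$index_on_shaft))) {
    stop_integrity("shaft metadata required for Laplacian re-referencing")
  }
  out <- rec$signal
  for (shaft in unique(ch$shaft)) {
    rows <- which(ch$shaft == shaft)
    rows <- rows[order(ch$index_on_shaft[rows])]
    m <- length(rows)
    if (m == 1) {
      warning("shaft ", shaft, " has a single contact; left unreferenced",
              call. = FALSE)
      next
    }
    for (j in seq_len(m)) {
      i <- rows[j]
      if (j == 1) {
        out[i, ] <- rec$signal[i, ] - rec$signal[rows[2], ]
      } else if (j == m) {
        out[i, ] <- rec$signal[i, ] - rec$signal[rows[m - 1], ]
      } else {
        out[i, ] <- rec$signal[i, ] -
          (rec$signal[rows[j - 1], ] + rec$signal[rows[j + 1], ]) / 2
      }
    }
  }
  rec$signal <- out
  rec
}

# FFT analytic signal; x is real, returns complex vector of same length.
analytic_signal <- function(x) {
  n <- length(x)
  n2 <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(n2 - n)))
  h <- numeric(n2)
  h[1] <- 1
  if (n2 %% 2 == 0) {
    h[n2 / 2 + 1] <- 1
    h[2:(n2 / 2)] <- 2
  } else {
    h[2:((n2 + 1) / 2)] <- 2
  }
  (stats::fft(X * h, inverse = TRUE) / n2)[seq_len(n)]
}

#' Continuous band-power (Hilbert envelope) extraction
#'
#' Zero-phase Butterworth band-pass of the band's stated order, magnitude of
#' the analytic signal (Hilbert envelope), then a centred boxcar moving
#' average. Computed on the full continuous recording before any epoching so
#' filter and Hilbert edge effects stay at the recording ends.
#'
#' @param rec [seeg_recording()].
#' @param band a [band_definition()] or a band name from the config.
#' @param smooth boxcar width in seconds (default 200 ms).
#' @param config [fc_config()] used to resolve band names.
#' @return object of class `cont_power`: list with `power`
#'   (channels x samples envelope matrix), `fs`, `channels`, `band`.
#' @export
band_power <- function(rec, band = "hfb", smooth = 0.2, config = fc_config()) {
  stopifnot(inherits(rec, "seeg_recording"))
  band <- resolve_band(band, config)
  if (band$hi >= rec$fs / 2) stop_argument("band upper edge at or above Nyquist")
  w <- as.integer(round(smooth * rec$fs))
  n <- n_samples(rec)
  if (w > n) stop_argument("smoothing window longer than the recording")
  filt <- signal::butter(band$order / 2, c(band$lo, band$hi) / (rec$fs / 2),
                         type = "pass")
  np <- min(as.integer(rec$fs), n - 1L)
  power <- matrix(0, nrow(rec$signal), n)
  for (ch in seq_len(nrow(rec$signal))) {
    x <- rec$signal[ch, ]
    xp <- c(2 * x[1] - rev(x[2:(np + 1)]), x, 2 * x[n] - rev(x[(n - np):(n - 1)]))
    env <- Mod(analytic_signal(signal::filtfilt(filt, xp)))
    if (w > 1) env <- boxcar_smooth(env, w)
    power[ch, ] <- env[(np + 1):(np + n)]
  }
  structure(list(power = power, fs = rec$fs, channels = rec$channels,
                 band = band, smooth = smooth),
            class = "cont_power")
}

boxcar_smooth <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  half_lo <- (w - 1) %/% 2
  half_hi <- w %/% 2
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
print.cont_power <- function(x, ...) {
  cat(sprintf("<cont_power> band %s (%g-%g Hz), %d channels x %d samples @ %g Hz\n",
              x$band$name, x$band$lo, x$band$hi, nrow(x$power), ncol(x$power), x$fs))
  invisible(x)
}

#' Event-locked Hann-taper spectrogram
#'
#' Sliding Hann-windowed Fourier power per trial and channel, expressed in
#' dB relative to the mean over the pre-event baseline window at each
#' frequency.
#'
#' @param rec [seeg_recording()].
#' @param events [event_table()]; rows with `phase == lock_phase` define the
#'   trials.
#' @param window taper length in seconds.
#' @param step hop between window centres in seconds (must be <= window).
#' @param epoch_window c(start, end) seconds around each event.
#' @param baseline c(start, end) seconds of the per-frequency dB reference.
#' @param lock_phase event phase to lock to.
#' @param freq_range optional c(lo, hi) Hz to retain.
#' @return list with `power` (trials x channels x freq x time, dB), `freqs`,
#'   `times` (window centres, s), class `fc_spectrogram`.
#' @export
spectrogram <- function(rec, events, window = 0.5, step = 0.05,
                        epoch_window = c(-2, 6), baseline = c(-0.6, -0.1),
                        lock_phase = "cue", freq_range = NULL) {
  stopifnot(inherits(rec, "seeg_recording"))
  if (step > window) stop_argument("step must not exceed window")
  fs <- rec$fs
  nw <- as.integer(round(window * fs))
  hop <- max(1L, as.integer(round(step * fs)))
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  ev <- events[events$phase == lock_phase, , drop = FALSE]
  n_ep <- as.integer(round(diff(epoch_window) * fs))
  centers <- seq(1 + nw %/% 2, n_ep - (nw - nw %/% 2), by = hop)
  times <- epoch_window[1] + (centers - 1) / fs
  freqs <- (0:(nw %/% 2)) * fs / nw
  keep_f <- if (is.null(freq_range)) seq_along(freqs) else
    which(freqs >= freq_range[1] & freqs <= freq_range[2])
  out <- array(0, c(nrow(ev), nrow(rec$signal), length(keep_f), length(centers)))
  for (tr in seq_len(nrow(ev))) {
    i0 <- sample_at(ev$onset[tr] + epoch_window[1], fs)
    if (i0 < 1 || i0 + n_ep - 1 > n_samples(rec)) {
      stop_argument("epoch for event at ", ev$onset[tr], " s exceeds recording bounds")
    }
    for (ch in seq_len(nrow(rec$signal))) {
      seg <- rec$signal[ch, i0:(i0 + n_ep - 1)]
      for (kt in seq_along(centers)) {
        c0 <- centers[kt]
        win <- seg[(c0 - nw %/% 2):(c0 - nw %/% 2 + nw - 1)] * taper
        P <- Mod(stats::fft(win))^2
        out[tr, ch, , kt] <- P[keep_f]
      }
    }
  }
  base_idx <- which(times >= baseline[1] & times <= baseline[2])
  for (ch in seq_len(dim(out)[2])) {
    for (fi in seq_len(dim(out)[3])) {
      ref <- mean(out[, ch, fi, base_idx])
      out[, ch, fi, ] <- 10 * log10(out[, ch, fi, ] / ref)
    }
  }
  structure(list(power = out, freqs = freqs[keep_f], times = times,
                 channels = rec$channels, window = window, step = step),
            class = "fc_spectrogram")
}

#' Epoch continuous band power and z-score against a pooled baseline
#'
#' Cuts `window` (half-open, `round(diff(window) * fs)` samples) around each
#' locking event and z-transforms each channel against the mean and SD of
#' its pooled baseline samples across all retained trials. Trials extending
#' past the recording bounds are dropped with a message.
#'
#' @param power [band_power()] output.
#' @param events [event_table()].
#' @param window c(start, end) seconds relative to the locking event.
#' @param baseline c(start, end) seconds; must lie inside `window`.
#' @param lock_phase event phase to lock to (`"cue"` or `"bite"`).
#' @return object of class `band_epochs`: list with `data`
#'   (trials x channels x time z-scores), `times`, `condition`, `phase`,
#'   `band`, `channels`, `baseline`.
#' @export
epoch_and_zscore <- function(power, events, window = c(-2, 6),
                             baseline = c(-0.6, -0.1), lock_phase = "cue") {
  stopifnot(inherits(power, "cont_power"))
  if (baseline[1] < window[1] || baseline[2] > window[2]) {
    stop_argument("baseline window must lie inside the epoch window")
  }
  fs <- power$fs
  ev <- events[events$phase == lock_phase, , drop = FALSE]
  if (nrow(ev) == 0) stop_argument("no events with phase '", lock_phase, "'")
  n_t <- as.integer(round(diff(window) * fs))
  starts <- vapply(ev$onset, function(o) sample_at(o + window[1], fs), 1L)
  ok <- starts >= 1 & starts + n_t - 1 <= ncol(power$power)
  if (any(!ok)) {
    message(sum(!ok), " trial(s) dropped: epoch exceeds recording bounds")
  }
  ev <- ev[ok, , drop = FALSE]
  starts <- starts[ok]
  n_trials <- nrow(ev)
  n_ch <- nrow(power$power)
  data <- array(0, c(n_trials, n_ch, n_t))
  for (tr in seq_len(n_trials)) {
    data[tr, , ] <- power$power[, starts[tr]:(starts[tr] + n_t - 1)]
  }
  times <- window[1] + (seq_len(n_t) - 1) / fs
  b_idx <- which(times >= baseline[1] & times < baseline[2])
  for (ch in seq_len(n_ch)) {
    b <- as.vector(data[, ch, b_idx])
    mu <- mean(b)
    sg <- stats::sd(b)
    if (!is.finite(sg) || sg == 0) {
      stop_argument("degenerate baseline (zero variance) on channel ",
                    power$channels$label[ch])
    }
    data[, ch, ] <- (data[, ch, ] - mu) / sg
  }
  structure(list(data = data, times = times, condition = ev$condition,
                 phase = lock_phase, band = power$band,
                 channels = power$channels, baseline = baseline,
                 window = window, fs = fs),
            class = "band_epochs")
}

#' Construct an epoched band-power object from an array
#'
#' Low-level constructor used when epochs come from a source other than
#' [epoch_and_zscore()] (simulation studies, external pipelines).
#'
#' @param data trials x channels x time array of z-scored power.
#' @param times time axis in seconds relative to the locking event.
#' @param condition per-trial condition labels.
#' @param channels channel table (defaults to generic labels).
#' @param phase locking phase label.
#' @param baseline baseline window (seconds).
#' @param band band definition.
#' @return `band_epochs` object.
#' @export
band_epochs <- function(data, times, condition,
                        channels = NULL, phase = "cue",
                        baseline = c(-0.6, -0.1),
                        band = band_definition("hfb", 70, 170, 8)) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times),
            dim(data)[1] == length(condition))
  if (any(diff(times) <= 0)) stop_argument("times must be strictly increasing")
  if (is.null(channels)) channels <- default_channels(dim(data)[2])
  fs <- 1 / stats::median(diff(times))
  structure(list(data = data, times = times, condition = condition,
                 phase = phase, band = band, channels = channels,
                 baseline = baseline, window = range(times), fs = fs),
            class = "band_epochs")
}

#' @export
print.band_epochs <- function(x, ...) {
  cat(sprintf("<band_epochs> %d trials x %d channels x %d samples, band %s, lock %s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$band$name, x$phase))
  cat("  conditions:", paste(sprintf("%s (%d)", names(table(x$condition)),
                                     table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}

# trials x time matrix for one channel, optionally one condition
epoch_matrix <- function(epochs, channel, condition = NULL) {
  ch <- if (is.numeric(channel)) as.integer(channel) else
    match(channel, epochs$channels$label)
  if (is.na(ch)) stop_integrity("unknown channel: ", channel)
  keep <- if (is.null(condition)) seq_along(epochs$condition) else
    which(epochs$condition == condition)
  epochs$data[keep, ch, , drop = FALSE][, 1, , drop = TRUE]
}
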