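# Inter-ictal spike detection and spectrum-matched interpolation, used to
# clean ad libitum meal recordings before bite-locked epoching.

#' Detect inter-ictal spikes
#'
#' Band-passes every channel to 20-50 Hz, averages across channels, and
#' flags samples whose absolute value exceeds `threshold` robust standard
#' deviations (scaled median absolute deviation, so the artifacts cannot
#' inflate their own detection threshold) of that average trace. Flags
#' closer than `merge` seconds are merged into one spike whose time is the
#' sample of maximum absolute deflection.
#'
#' @param rec [seeg_recording()].
#' @param threshold SD multiples (> 0); default 5.
#' @param band c(lo, hi) Hz of the detection band-pass.
#' @param merge merge window in seconds.
#' @return object of class `spike_set`: data frame `spikes` (`time`,
#'   `peak`), `threshold`, `intervals` (replacement windows, start/end s).
#' @export
detect_spikes <- function(rec, threshold = 5, band = c(20, 50), merge = 0.1) {
  stopifnot(inherits(rec, "seeg_recording"))
  if (threshold <= 0) stop_argument("threshold must be > 0")
  fs <- rec$fs
  filt <- signal::butter(2, band / (fs / 2), type = "pass")
  avg <- rep(0, n_samples(rec))
  for (ch in seq_len(nrow(rec$signal))) {
    avg <- avg + pad_filtfilt(filt, rec$signal[ch, ], fs)
  }
  avg <- avg / nrow(rec$signal)
  # robust SD (scaled MAD) so the artifacts being detected cannot inflate
  # their own detection threshold
  sd_avg <- stats::mad(avg)
  flags <- which(abs(avg) > threshold * sd_avg)
  times <- numeric(0)
  peaks <- numeric(0)
  if (length(flags)) {
    gap <- as.integer(round(merge * fs))
    grp <- cumsum(c(1, diff(flags) > gap))
    for (g in unique(grp)) {
      idx <- flags[grp == g]
      peak_i <- idx[which.max(abs(avg[idx]))]
      times <- c(times, (peak_i - 1) / fs)
      peaks <- c(peaks, avg[peak_i])
    }
  }
  half <- 0.05
  intervals <- if (length(times))
    merge_spans(cbind(pmax(times - half, 0),
                      pmin(times + half, rec_duration(rec))))
  else matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  structure(list(spikes = data.frame(time = times, peak = peaks),
                 threshold = threshold, band = band, intervals = intervals),
            class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  cat(sprintf("<spike_set> %d spikes at threshold %g SD (%g-%g Hz)\n",
              nrow(x$spikes), x$threshold, x$band[1], x$band[2]))
  invisible(x)
}

#' Replace spike windows with spectrum-matched stationary surrogate
#'
#' Each ~100 ms replacement window is rebuilt per channel from surrogate
#' noise whose amplitude spectrum equals the average spectrum of the
#' flanking second of background (excluding other spike windows), with
#' random phases and a 10 ms linear crossfade into the surrounding signal.
#' Samples outside the windows are bit-identical to the input.
#'
#' @param rec [seeg_recording()].
#' @param spikes [detect_spikes()] output (or a `spike_set` built from
#'   known times).
#' @param crossfade crossfade length in seconds.
#' @param seed RNG seed for the surrogate phases.
#' @return cleaned [seeg_recording()].
#' @export
interpolate_spikes <- function(rec, spikes, crossfade = 0.01, seed = NULL) {
  stopifnot(inherits(rec, "seeg_recording"), inherits(spikes, "spike_set"))
  if (nrow(spikes$intervals) == 0) return(rec)
  fs <- rec$fs
  n <- n_samples(rec)
  nf <- as.integer(round(crossfade * fs))
  with_seed(seed, {
    for (w in seq_len(nrow(spikes$intervals))) {
      i0 <- max(sample_at(spikes$intervals[w, 1], fs), 1L)
      i1 <- min(sample_at(spikes$intervals[w, 2], fs), n)
      if (i1 - i0 + 1 < 4) {
        warning("replacement window at recording edge shorter than 4 samples; skipped",
                call. = FALSE)
        next
      }
      len <- i1 - i0 + 1L
      flank_idx <- flanking_indices(i0, i1, n, fs, spikes$intervals)
      for (ch in seq_len(nrow(rec$signal))) {
        target <- mean_amplitude_spectrum(rec$signal[ch, ], flank_idx, len)
        sur <- phase_randomized(target, len)
        sur <- sur - mean(sur) + mean(rec$signal[ch, flank_idx])
        seg <- sur
        if (nf > 0 && len > 2 * nf) {
          wgt <- seq(0, 1, length.out = nf)
          seg[seq_len(nf)] <- (1 - wgt) * rec$signal[ch, i0:(i0 + nf - 1)] +
            wgt * sur[seq_len(nf)]
          seg[(len - nf + 1):len] <- rev(wgt) * sur[(len - nf + 1):len] +
            (1 - rev(wgt)) * rec$signal[ch, (i1 - nf + 1):i1]
        }
        rec$signal[ch, i0:i1] <- seg
      }
    }
    rec
  })
}

# up to 0.5 s on each side of [i0, i1], excluding any spike window
flanking_indices <- function(i0, i1, n, fs, intervals) {
  half <- as.integer(round(0.5 * fs))
  cand <- c(max(1, i0 - half):(i0 - 1), (i1 + 1):min(n, i1 + half))
  cand <- cand[cand >= 1 & cand <= n]
  t <- (cand - 1) / fs
  in_spike <- rep(FALSE, length(cand))
  for (w in seq_len(nrow(intervals))) {
    in_spike <- in_spike | (t >= intervals[w, 1] & t <= intervals[w, 2])
  }
  cand[!in_spike]
}

# average |FFT| over length-len chunks of the flanking samples
mean_amplitude_spectrum <- function(x, flank_idx, len) {
  chunks <- split(flank_idx, ceiling(seq_along(flank_idx) / len))
  chunks <- chunks[vapply(chunks, length, 1L) == len]
  if (length(chunks) == 0) {
    seg <- x[flank_idx[seq_len(min(len, length(flank_idx)))]]
    seg <- c(seg, rep(mean(seg), len - length(seg)))
    return(Mod(stats::fft(seg)))
  }
  amp <- rep(0, len)
  for (cc in chunks) amp <- amp + Mod(stats::fft(x[cc]))
  amp / length(chunks)
}

# real surrogate with the given amplitude spectrum and random phases
phase_randomized <- function(amp, len) {
  half <- len %/% 2
  ph <- stats::runif(len, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  spec[1] <- complex(real = amp[1], imaginary = 0)
  if (len %% 2 == 0) spec[half + 1] <- complex(real = amp[half + 1], imaginary = 0)
  for (k in 2:len) {                 # enforce Hermitian symmetry
    km <- len - k + 2
    if (km < k) spec[k] <- Conj(spec[km])
  }
  Re(stats::fft(spec, inverse = TRUE)) / len
}
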