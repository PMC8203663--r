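# Synthetic SEEG generator with planted ground truth.
#
# Sessions are built from three additive parts: 1/f^beta background noise
# (spectrally shaped white noise) with 60 Hz mains contamination and its
# harmonics, event-locked high-frequency-broadband responses (amplitude-
# modulated 70-170 Hz band-limited noise, so Hilbert envelopes behave like
# real high gamma), and optional biphasic inter-ictal spikes shared across
# channels. Every component is deterministic under its seed and the planted
# parameters are returned as ground truth.

#' Generate 1/f background with mains contamination
#'
#' Each channel is independent spectrally shaped Gaussian noise with power
#' spectral density proportional to `1/f^one_over_f_exponent`, scaled to
#' `sd` microvolts RMS, plus a 60 Hz sinusoid of amplitude `line_amp` with
#' 120/180 Hz harmonics at half and quarter amplitude.
#'
#' @param n_channels number of channels (ignored if `channels` given).
#' @param duration recording length in seconds.
#' @param fs sampling rate (Hz).
#' @param one_over_f_exponent spectral exponent beta (1 is typical LFP).
#' @param line_amp mains amplitude in microvolts (0 disables).
#' @param sd background RMS amplitude per channel (microvolts).
#' @param channels optional channel table; default builds shafts of up to 8
#'   contacts labelled `A1..A8, B1..`.
#' @param seed RNG seed for reproducibility.
#' @return [seeg_recording()].
#' @examples
#' rec <- generate_background(2, 4, seed = 1)
#' @export
generate_background <- function(n_channels, duration, fs = 1024,
                                one_over_f_exponent = 1, line_amp = 5,
                                sd = 20, channels = NULL, seed = NULL) {
  if (duration <= 0 || fs <= 0) stop_argument("duration and fs must be positive")
  n <- as.integer(round(duration * fs))
  if (n < 2048) stop_argument("recording must contain at least 2048 samples")
  if (!is.null(channels)) {
    channels <- validate_channels(channels)
    n_channels <- nrow(channels)
  } else {
    channels <- default_channels(n_channels)
  }
  signal <- with_seed(seed, {
    out <- matrix(0, n_channels, n)
    t <- (seq_len(n) - 1) / fs
    for (ch in seq_len(n_channels)) {
      x <- shape_one_over_f(stats::rnorm(n), one_over_f_exponent)
      x <- x / stats::sd(x) * sd
      if (line_amp > 0) {
        ph <- stats::runif(3, 0, 2 * pi)
        x <- x + line_amp * sin(2 * pi * 60 * t + ph[1]) +
          line_amp / 2 * sin(2 * pi * 120 * t + ph[2]) +
          line_amp / 4 * sin(2 * pi * 180 * t + ph[3])
      }
      out[ch, ] <- x
    }
    out
  })
  seeg_recording(signal, fs, channels)
}

# Multiply the spectrum of white noise by f^(-beta/2) (power ~ 1/f^beta).
shape_one_over_f <- function(w, beta) {
  n <- length(w)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)            # two-sided frequency index, DC at 0
  amp <- c(0, f[-1]^(-beta / 2)) # kill DC
  Re(stats::fft(W * amp, inverse = TRUE)) / n
}

default_channels <- function(n_channels, shaft_size = 8) {
  shaft_id <- LETTERS[((seq_len(n_channels) - 1) %/% shaft_size) + 1]
  idx <- ((seq_len(n_channels) - 1) %% shaft_size) + 1L
  channel_table(label = paste0(shaft_id, idx), shaft = shaft_id,
                index_on_shaft = idx)
}

#' Response specification table
#'
#' One row per (channel, phase, condition): planted HFB response gain (in
#' multiples of the channel's background SD), onset latency after the locking
#' event, total supra-baseline duration and linear rise time.
#'
#' @param channel channel label.
#' @param condition condition the response is locked to.
#' @param gain envelope plateau in background-SD multiples (>= 0).
#' @param onset_latency seconds after the locking event onset.
#' @param duration total response duration in seconds (> 0).
#' @param rise_time linear ramp length in seconds (<= duration / 2).
#' @param phase event phase the response locks to (`"cue"`, `"receipt"`,
#'   `"bite"`).
#' @return data frame of class `response_specs`.
#' @export
response_spec <- function(channel, condition, gain, onset_latency = 0.3,
                          duration = 1, rise_time = 0.1, phase = "cue") {
  df <- data.frame(channel = channel, condition = condition, gain = gain,
                   onset_latency = onset_latency, duration = duration,
                   rise_time = rise_time, phase = phase,
                   stringsAsFactors = FALSE)
  if (any(df$gain < 0)) stop_argument("gain must be >= 0")
  if (any(df$duration <= 0)) stop_argument("duration must be > 0")
  if (any(df$rise_time > df$duration)) stop_argument("rise_time must be <= duration")
  class(df) <- c("response_specs", "data.frame")
  df
}

#' Add event-locked HFB responses to a recording
#'
#' For each event matching a spec's (condition, phase), adds 70-170 Hz
#' band-limited noise whose envelope ramps linearly from 0 to
#' `gain * sd(channel)` over `rise_time` starting at
#' `onset + onset_latency`, holds, and decays over `rise_time` so the total
#' supra-baseline extent equals `duration`. The input signal is otherwise
#' untouched (output minus input is exactly the planted component).
#'
#' @param rec [seeg_recording()].
#' @param events [event_table()].
#' @param specs [response_spec()] table.
#' @param seed RNG seed (carrier noise).
#' @return modified [seeg_recording()].
#' @export
inject_responses <- function(rec, events, specs, seed = NULL) {
  stopifnot(inherits(rec, "seeg_recording"))
  if (is.null(specs) || nrow(specs) == 0) return(rec)
  missing <- setdiff(specs$channel, rec$channels$label)
  if (length(missing)) {
    stop_integrity("response spec references absent channel(s): ",
                   paste(unique(missing), collapse = ", "))
  }
  fs <- rec$fs
  n <- n_samples(rec)
  bp <- signal::butter(2, c(70, 170) / (fs / 2), type = "pass")
  # gains are multiples of the *input* background SD, fixed before any
  # injection so that spec order cannot bias amplitudes
  sigma_bg <- apply(rec$signal, 1, stats::sd)
  with_seed(seed, {
    for (s in seq_len(nrow(specs))) {
      sp <- specs[s, ]
      if (sp$gain == 0) next
      ch <- channel_index(rec, sp$channel)
      sigma <- sigma_bg[ch]
      ev <- events[events$condition == sp$condition & events$phase == sp$phase, ]
      env <- response_envelope(sp$duration, sp$rise_time, fs)
      len <- length(env)
      for (e in seq_len(nrow(ev))) {
        i0 <- sample_at(ev$onset[e] + sp$onset_latency, fs)
        if (i0 < 1 || i0 + len - 1 > n) next
        carrier <- signal::filtfilt(bp, stats::rnorm(len + 2048))
        carrier <- carrier[1025:(1024 + len)]
        carrier <- carrier / stats::sd(carrier)
        rec$signal[ch, i0:(i0 + len - 1)] <-
          rec$signal[ch, i0:(i0 + len - 1)] + sp$gain * sigma * env * carrier
      }
    }
    rec
  })
}

response_envelope <- function(duration, rise_time, fs) {
  n <- max(2L, as.integer(round(duration * fs)))
  nr <- as.integer(round(rise_time * fs))
  env <- rep(1, n)
  if (nr > 0) {
    ramp <- seq(0, 1, length.out = nr + 1)[-1]
    env[seq_len(nr)] <- ramp
    env[(n - nr + 1):n] <- rev(ramp)
  }
  env
}

#' Superimpose inter-ictal spikes on all channels
#'
#' Biphasic transients (a sharp ~40 ms deflection followed by a slower
#' opposite-polarity wave) are added simultaneously to every channel at
#' homogeneous-Poisson times, scaled per channel to `amplitude` multiples of
#' that channel's SD.
#'
#' @param rec [seeg_recording()].
#' @param rate spikes per minute (>= 0).
#' @param amplitude peak amplitude in background-SD multiples.
#' @param width sharp-component width in seconds (20-70 ms is typical).
#' @param n_spikes optionally plant exactly this many spikes instead of a
#'   Poisson draw.
#' @param times optionally plant spikes at exactly these times (seconds),
#'   overriding `rate`/`n_spikes`.
#' @param seed RNG seed.
#' @return list with elements `rec` (modified recording) and `times`
#'   (planted spike times, seconds).
#' @export
inject_spikes <- function(rec, rate, amplitude = 8, width = 0.04,
                          n_spikes = NULL, times = NULL, seed = NULL) {
  stopifnot(inherits(rec, "seeg_recording"))
  if (rate < 0) stop_argument("rate must be >= 0")
  dur <- rec_duration(rec)
  fs <- rec$fs
  with_seed(seed, {
    if (is.null(times)) {
      k <- if (!is.null(n_spikes)) n_spikes else stats::rpois(1, rate * dur / 60)
      times <- numeric(0)
      if (k > 0) {
        # discrete events: enforce 0.5 s separation so transients do not
        # overlap (thinned resampling keeps times uniform otherwise)
        for (try in 1:1000) {
          times <- sort(stats::runif(k, 0.5, dur - 0.5))
          if (k < 2 || min(diff(times)) >= 0.5) break
        }
      }
    }
    if (length(times) == 0) return(list(rec = rec, times = numeric(0)))
    shape_t <- seq(-0.1, 0.3, by = 1 / fs)
    # sharp biphasic deflection: derivative of a Gaussian (spectral peak
    # near 1/(2*pi*sigma) ~ 20 Hz), followed by a slower opposite wave
    sig_sharp <- width / 5
    sharp <- -shape_t * exp(-(shape_t / sig_sharp)^2 / 2)
    sharp <- sharp / max(abs(sharp))
    shape <- sharp - 0.35 * exp(-((shape_t - 0.12) / 0.05)^2 / 2)
    sds <- apply(rec$signal, 1, stats::sd)
    for (tt in times) {
      i0 <- sample_at(tt + shape_t[1], fs)
      idx <- i0:(i0 + length(shape) - 1)
      keep <- idx >= 1 & idx <= n_samples(rec)
      rec$signal[, idx[keep]] <- rec$signal[, idx[keep]] +
        outer(amplitude * sds, shape[keep])
    }
    list(rec = rec, times = times)
  })
}

#' Derive the true site category from planted response specs
#'
#' A channel/phase is `inactive` when all its planted gains are zero (or it
#' has no spec), `responsive` when its gains are positive and equal across
#' conditions, and `specific` when the condition gains differ.
#'
#' @param specs [response_spec()] table.
#' @param channels channel table (all channels get a category).
#' @param phase event phase to derive categories for.
#' @param conditions the two condition labels to compare.
#' @return data frame with `channel`, `category`.
#' @export
true_categories <- function(specs, channels, phase = "cue",
                            conditions = c("palatable", "neutral")) {
  cat_of <- function(lab) {
    rows <- specs[specs$channel == lab & specs$phase == phase &
                    specs$condition %in% conditions, , drop = FALSE]
    gains <- stats::setNames(rep(0, 2), conditions)
    if (nrow(rows)) gains[rows$condition] <- rows$gain
    if (all(gains == 0)) "inactive"
    else if (gains[1] == gains[2]) "responsive"
    else "specific"
  }
  data.frame(channel = channels$label,
             category = vapply(channels$label, cat_of, ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic task session
#'
#' Builds background, a randomized evenly split palatable/neutral trial
#' sequence (1 s cue at trial onset, receipt at +3 s for 3 s), injects the
#' planted responses and returns the recording, event table and ground
#' truth.
#'
#' @param specs [response_spec()] table (phases `"cue"`/`"receipt"`).
#' @param n_trials total trial count, split evenly (must be even).
#' @param channels channel table; defaults to the union of spec channels
#'   plus any supplied here.
#' @param config [fc_config()].
#' @param seed RNG seed.
#' @return list `rec`, `events`, `truth` (specs, per-phase categories, seed).
#' @export
generate_task_session <- function(specs, n_trials = 80, channels = NULL,
                                  config = fc_config(), seed = NULL) {
  if (n_trials %% 2 != 0) stop_argument("n_trials must be even (balanced split)")
  tk <- config$task
  if (is.null(channels)) {
    labs <- unique(specs$channel)
    channels <- default_channels(max(length(labs), 1))
    channels$label[seq_along(labs)] <- labs
    channels <- validate_channels(channels)
  }
  conditions <- with_seed(child_seed(seed, 1),
                          sample(rep(tk$conditions, n_trials / 2)))
  cue_onsets <- 10 + (seq_len(n_trials) - 1) * tk$trial_spacing
  events <- validate_events(rbind(
    data.frame(onset = cue_onsets, duration = tk$cue_duration,
               condition = conditions, phase = "cue"),
    data.frame(onset = cue_onsets + tk$receipt_onset,
               duration = tk$receipt_duration, condition = conditions,
               phase = "receipt")))
  duration <- max(cue_onsets) + 10
  rec <- generate_background(nrow(channels), duration, fs = config$fs,
                             channels = channels, seed = child_seed(seed, 2))
  rec <- inject_responses(rec, events, specs, seed = child_seed(seed, 3))
  truth <- list(
    specs = specs,
    categories = list(
      anticipation = true_categories(specs, channels, "cue", tk$conditions),
      receipt = true_categories(specs, channels, "receipt", tk$conditions)),
    spike_times = numeric(0),
    seed = seed)
  list(rec = rec, events = events, truth = truth)
}

#' Generate a synthetic ad libitum meal session
#'
#' Bite events of two food types in randomized order with inter-bite spacing
#' wide enough that -5..+5 s epochs never overlap, planted bite-locked
#' responses, and optional inter-ictal spikes.
#'
#' @param specs [response_spec()] table with `phase = "bite"`.
#' @param n_bites length-2 vector: bites of entree and non-entree food.
#' @param spike_rate planted spikes per minute (0 disables).
#' @param spike_amplitude spike amplitude in background-SD multiples.
#' @param channels optional channel table.
#' @param config [fc_config()].
#' @param seed RNG seed.
#' @return list `rec`, `events`, `truth`.
#' @export
generate_meal_session <- function(specs, n_bites = c(26, 18), spike_rate = 0,
                                  spike_amplitude = 8, channels = NULL,
                                  config = fc_config(), seed = NULL) {
  ml <- config$meal
  if (ml$bite_spacing < 10) stop_argument("bite spacing must be >= 10 s so epochs do not overlap")
  if (is.null(channels)) {
    labs <- unique(specs$channel)
    channels <- default_channels(max(length(labs), 1))
    channels$label[seq_along(labs)] <- labs
    channels <- validate_channels(channels)
  }
  foods <- with_seed(child_seed(seed, 1),
                     sample(rep(ml$conditions, times = n_bites)))
  onsets <- 10 + (seq_along(foods) - 1) * ml$bite_spacing
  events <- event_table(onsets, 0, foods, "bite")
  duration <- max(onsets) + 10
  rec <- generate_background(nrow(channels), duration, fs = config$fs,
                             channels = channels, seed = child_seed(seed, 2))
  rec <- inject_responses(rec, events, specs, seed = child_seed(seed, 3))
  spike_times <- numeric(0)
  if (spike_rate > 0) {
    sp <- inject_spikes(rec, spike_rate, amplitude = spike_amplitude,
                        seed = child_seed(seed, 4))
    rec <- sp$rec
    spike_times <- sp$times
  }
  truth <- list(
    specs = specs,
    categories = list(
      meal = true_categories(specs, channels, "bite", ml$conditions)),
    spike_times = spike_times,
    seed = seed)
  list(rec = rec, events = events, truth = truth)
}
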