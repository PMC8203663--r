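# Signal chain: notch, Laplacian, Hilbert band power, spectrogram,
# epoching/z-scoring, effect sizes.

tone_recording <- function(freq, amp = 1, duration = 30, fs = 1024,
                           n_channels = 1) {
  t <- (0:(duration * fs - 1)) / fs
  sig <- matrix(rep(amp * sin(2 * pi * freq * t), n_channels),
                n_channels, byrow = TRUE)
  seeg_recording(sig, fs, foodcue:::default_channels(n_channels))
}

test_that("notch filter removes mains and leaves the passband alone", {
  tone60 <- tone_recording(60)
  out <- notch_filter(tone60)
  expect_lt(sd(out$signal[1, ]) / sd(tone60$signal[1, ]), 0.03)

  tone10 <- tone_recording(10)
  out10 <- notch_filter(tone10)
  expect_lt(abs(sd(out10$signal[1, ]) / sd(tone10$signal[1, ]) - 1), 0.01)

  zero <- seeg_recording(matrix(0, 1, 4096), 1024,
                         foodcue:::default_channels(1))
  expect_equal(max(abs(notch_filter(zero)$signal)), 0)
  expect_error(notch_filter(tone10, freqs = 600), "Nyquist")
})

test_that("Laplacian matches the flanking-contact formula", {
  # three equal channels on one shaft: middle becomes zero
  x <- matrix(rnorm(3000), 1)
  eq <- seeg_recording(rbind(x, x, x), 1024,
                       channel_table(c("S1", "S2", "S3"), "S", 1:3))
  lap <- laplacian_rereference(eq)
  expect_equal(max(abs(lap$signal[2, ])), 0)

  # constant traces (0, 1, 0): middle output is constant 1
  const <- seeg_recording(rbind(matrix(0, 1, 100), matrix(1, 1, 100),
                                matrix(0, 1, 100)), 1024,
                          channel_table(c("S1", "S2", "S3"), "S", 1:3))
  expect_equal(unique(laplacian_rereference(const)$signal[2, ]), 1)

  # 5-contact shaft vs per-sample brute force
  sig <- matrix(rnorm(5 * 1000), 5)
  rec <- seeg_recording(sig, 1024, channel_table(paste0("S", 1:5), "S", 1:5))
  lap5 <- laplacian_rereference(rec)$signal
  brute <- sig
  brute[1, ] <- sig[1, ] - sig[2, ]
  brute[5, ] <- sig[5, ] - sig[4, ]
  for (i in 2:4) brute[i, ] <- sig[i, ] - (sig[i - 1, ] + sig[i + 1, ]) / 2
  expect_identical(lap5, brute)

  single <- seeg_recording(matrix(rnorm(100), 1), 1024,
                           channel_table("Z1", "Z", 1))
  expect_warning(laplacian_rereference(single), "single contact")
})

test_that("Hilbert envelope recovers tone amplitude and rejects stopband", {
  A <- 2.5
  rec <- tone_recording(100, amp = A, duration = 10)
  env <- band_power(rec, "hfb", smooth = 0.2)$power[1, ]
  interior <- seq(round(0.1 * length(env)), round(0.9 * length(env)))
  expect_lt(max(abs(env[interior] - A)) / A, 0.05)

  rec10 <- tone_recording(10, amp = A, duration = 10)
  env10 <- band_power(rec10, "hfb", smooth = 0.2)$power[1, ]
  expect_lt(mean(env10), 0.05 * A)
})

test_that("boxcar smoothing spreads an amplitude step over ~200 ms", {
  fs <- 1024
  t <- (0:(8 * fs - 1)) / fs
  carrier <- sin(2 * pi * 120 * t)
  amp <- ifelse(t >= 4, 1, 0)
  rec <- seeg_recording(matrix(carrier * amp, 1), fs,
                        foodcue:::default_channels(1))
  env <- band_power(rec, "hfb", smooth = 0.2)$power[1, ]
  t25 <- t[min(which(env >= 0.25))]
  t75 <- t[min(which(env >= 0.75))]
  # boxcar of 200 ms: quartile crossing separation ~ 100 ms
  expect_lt(abs((t75 - t25) - 0.1), 0.03)
})

test_that("spectrogram is self-normalising and localises bursts", {
  fs <- 1024
  rec <- generate_background(1, 80, line_amp = 0, seed = 31)
  ev <- event_table(seq(10, 70, by = 10), 1, "palatable", "cue")
  sg <- spectrogram(rec, ev, window = 0.5, step = 0.1,
                    epoch_window = c(-2, 2), baseline = c(-1.5, -0.5),
                    freq_range = c(2, 200))
  # stationary noise: the trial-averaged linear-power map sits at ~0 dB
  avg_db <- 10 * log10(apply(10^(sg$power / 10), c(3, 4), mean))
  expect_lt(abs(mean(avg_db)), 1)

  # 100 Hz burst at 0..1 s after each event
  burst <- rec
  t <- (0:(ncol(rec$signal) - 1)) / fs
  for (o in ev$onset) {
    idx <- t >= o & t < o + 1
    burst$signal[1, idx] <- burst$signal[1, idx] +
      3 * sd(rec$signal) * sin(2 * pi * 100 * t[idx])
  }
  sgb <- spectrogram(burst, ev, window = 0.5, step = 0.1,
                     epoch_window = c(-2, 2), baseline = c(-1.5, -0.5),
                     freq_range = c(2, 200))
  avg <- apply(sgb$power, c(3, 4), mean)
  peak <- which(avg == max(avg), arr.ind = TRUE)
  expect_true(sgb$freqs[peak[1]] >= 70 && sgb$freqs[peak[1]] <= 170)
  expect_true(sgb$times[peak[2]] >= 0 && sgb$times[peak[2]] <= 1)

  # doubling the burst amplitude adds ~6 dB at the peak tile
  burst2 <- rec
  for (o in ev$onset) {
    idx <- t >= o & t < o + 1
    burst2$signal[1, idx] <- burst2$signal[1, idx] +
      6 * sd(rec$signal) * sin(2 * pi * 100 * t[idx])
  }
  sgb2 <- spectrogram(burst2, ev, window = 0.5, step = 0.1,
                      epoch_window = c(-2, 2), baseline = c(-1.5, -0.5),
                      freq_range = c(2, 200))
  avg2 <- apply(sgb2$power, c(3, 4), mean)
  expect_lt(abs((avg2[peak[1], peak[2]] - avg[peak[1], peak[2]]) - 6), 1)
  expect_error(spectrogram(rec, ev, window = 0.2, step = 0.5), "step")
})

test_that("pooled-baseline z-scoring is exact by construction", {
  sim <- small_task_session()
  ep <- sim$epochs
  b_idx <- which(ep$times >= -0.6 & ep$times < -0.1)
  for (ch in 1:3) {
    b <- as.vector(ep$data[, ch, b_idx])
    expect_lt(abs(mean(b)), 1e-9)
    expect_lt(abs(sd(b) - 1), 1e-9)
  }
  # epoch tensor: 40 trials x 3 channels x 8192 samples (half-open window)
  expect_equal(dim(ep$data), c(40, 3, 8192))
})

test_that("constant recordings are rejected as degenerate", {
  const <- seeg_recording(matrix(1, 1, 40960), 1024,
                          foodcue:::default_channels(1))
  pw <- structure(list(power = const$signal, fs = 1024,
                       channels = const$channels,
                       band = band_definition("hfb", 70, 170, 8),
                       smooth = 0.2), class = "cont_power")
  ev <- event_table(c(10, 20), 1, c("palatable", "neutral"), "cue")
  expect_error(epoch_and_zscore(pw, ev, c(-2, 6)), "degenerate|A1")
})

test_that("window effect sizes carry the palatable-minus-neutral sign", {
  sim <- small_task_session()
  eff <- mean_window_effect(sim$epochs, c(0, 1))
  expect_lt(abs(eff$d[1]), 0.8)          # inactive channel: small effect
  expect_lt(eff$d[3], -1)                # neutral-dominant: negative d
  # pooled-SD degenerate path
  dat <- array(1, c(8, 1, 100))
  dat[, 1, 1:20] <- 0                    # baseline variation, flat test window
  ep0 <- band_epochs(dat + array(rnorm(800, sd = 1e-12), dim(dat)),
                     seq(-0.5, 0.49, by = 0.01),
                     rep(c("palatable", "neutral"), 4))
  ep0$data[, 1, ] <- 1                   # identical trials
  expect_error(mean_window_effect(ep0, c(0, 0.4)), "pooled SD")
})

test_that("group band effects behave like a one-sample t", {
  z <- group_band_effects(rep(0, 10))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)

  jit <- group_band_effects(1 + rnorm(10, sd = 1e-3))
  expect_gt(jit$t, 100)
  expect_lt(jit$p, 0.01)

  # sampling distribution: d ~ N(0.25, 1), n = 168 -> E[t] ~ sqrt(168)/4
  set.seed(41)
  ts <- replicate(40, group_band_effects(rnorm(168, 0.25, 1))$t)
  expect_lt(abs(mean(ts) - sqrt(168) * 0.25), 2 * sd(ts) / sqrt(40) + 0.2)
  expect_error(group_band_effects(c(0, 1)), "3 channels")
})
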