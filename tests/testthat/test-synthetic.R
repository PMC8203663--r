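# Synthetic SEEG generator: spectral shape, determinism, additivity of the
# planted components, session structure, ground-truth derivation.

test_that("background spectrum follows the requested 1/f slope", {
  rec <- generate_background(1, 60, one_over_f_exponent = 1, line_amp = 0,
                             seed = 11)
  x <- rec$signal[1, ]
  # Welch-style averaged periodogram over 4 s segments
  fs <- rec$fs
  seg_len <- 4 * fs
  n_seg <- floor(length(x) / seg_len)
  pxx <- 0
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * seg_len + 1):(s * seg_len)]
    pxx <- pxx + Mod(fft(seg * (0.5 - 0.5 * cos(2 * pi * seq_along(seg) / seg_len))))^2
  }
  freqs <- (seq_len(seg_len) - 1) * fs / seg_len
  keep <- freqs >= 1 & freqs <= 100
  fit <- lm(log10(pxx[keep]) ~ log10(freqs[keep]))
  expect_lt(abs(unname(fit$coefficients[2]) - (-1)), 0.15)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_background(2, 3, seed = 12)
  b <- generate_background(2, 3, seed = 12)
  expect_identical(a$signal, b$signal)
  c <- generate_background(2, 3, seed = 13)
  expect_false(identical(a$signal, c$signal))
})

test_that("mains contamination creates a dominant 60 Hz line", {
  rec <- generate_background(1, 8, line_amp = 5, seed = 14)
  x <- rec$signal[1, ]
  P <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) * rec$fs / length(x)
  i60 <- which.min(abs(freqs - 60))
  neighbours <- c(i60 - 20, i60 - 15, i60 + 15, i60 + 20)
  expect_gt(P[i60], 10 * max(P[neighbours]))
})

test_that("response injection is additive, band-limited and null at gain 0", {
  rec <- generate_background(2, 40, seed = 15)
  ev <- event_table(c(10, 25), 1, "palatable", "cue")
  null_spec <- response_spec("A1", "palatable", 0)
  expect_identical(inject_responses(rec, ev, null_spec, seed = 1)$signal,
                   rec$signal)

  spec <- response_spec("A1", "palatable", 3, 0.3, 1, 0.1)
  out <- inject_responses(rec, ev, spec, seed = 2)
  diff <- out$signal[1, ] - rec$signal[1, ]
  expect_identical(out$signal[2, ], rec$signal[2, ])   # untouched channel
  # planted component confined to the event windows (one-sample slack for
  # the rounded window start)
  t <- (seq_along(diff) - 1) / rec$fs
  inside <- (t >= 10.299 & t <= 11.301) | (t >= 25.299 & t <= 26.301)
  expect_true(all(diff[!inside] == 0))
  expect_gt(sd(diff[inside]), 0)
  # spectral confinement: power outside 60-180 Hz < 5% of the total added
  P <- Mod(fft(diff))^2
  freqs <- (seq_along(diff) - 1) * rec$fs / length(diff)
  fold <- pmin(freqs, rec$fs - freqs)
  expect_lt(sum(P[fold < 60 | fold > 180]) / sum(P), 0.05)

  expect_error(inject_responses(rec, ev, response_spec("ZZ9", "palatable", 1)),
               "absent channel")
})

test_that("injected responses raise measured HFB z-scores post-event", {
  sim <- small_task_session()
  ep <- sim$epochs
  post <- which(ep$times >= 0.5 & ep$times <= 1.3)
  pre <- which(ep$times >= -0.6 & ep$times <= -0.1)
  X <- ep$data[, 2, ]                      # B1: planted gain 3 both conditions
  frac <- mean(rowMeans(X[, post]) > rowMeans(X[, pre]))
  expect_gte(frac, 0.95)
})

test_that("spike injection matches the requested rate and amplitude", {
  rec <- generate_background(3, 600, seed = 16)
  same <- inject_spikes(rec, rate = 0, seed = 1)
  expect_identical(same$rec$signal, rec$signal)
  expect_length(same$times, 0)

  sp <- inject_spikes(rec, rate = 6, amplitude = 8, seed = 17)
  # Poisson 99% interval for mean 60
  expect_gte(length(sp$times), qpois(0.005, 60))
  expect_lte(length(sp$times), qpois(0.995, 60))

  avg_in <- colMeans(sp$rec$signal)
  avg_sd <- sd(colMeans(rec$signal))
  peaks <- vapply(sp$times, function(tt) {
    i <- round(tt * rec$fs) + 1
    max(abs(avg_in[max(1, i - 20):min(length(avg_in), i + 20)]))
  }, 1.0)
  expect_gte(mean(peaks >= 5 * avg_sd), 0.95)
})

test_that("task sessions have balanced randomized trials and receipt rows", {
  specs <- response_spec("A1", "palatable", 1)
  sim <- generate_task_session(specs, n_trials = 40, seed = 18)
  cue <- sim$events[sim$events$phase == "cue", ]
  receipt <- sim$events[sim$events$phase == "receipt", ]
  expect_equal(nrow(cue), 40)
  expect_equal(nrow(receipt), 40)
  expect_equal(as.integer(table(cue$condition)), c(20L, 20L))
  expect_equal(receipt$onset, cue$onset + 3)
  expect_error(generate_task_session(specs, n_trials = 39), "even")
  # randomized order: across seeds both conditions appear early
  both_early <- vapply(1:20, function(s) {
    ev <- generate_task_session(specs, n_trials = 40, seed = s)$events
    length(unique(ev$condition[ev$phase == "cue"][1:10])) == 2
  }, TRUE)
  expect_gte(mean(both_early), 0.99)
})

test_that("meal sessions count bites and keep epochs disjoint", {
  specs <- response_spec("A1", "entree", 2, phase = "bite")
  sim <- generate_meal_session(specs, n_bites = c(26, 18), seed = 19)
  expect_equal(nrow(sim$events), 44)
  expect_equal(sum(sim$events$condition == "entree"), 26)
  expect_equal(sum(sim$events$condition == "non_entree"), 18)
  # -5..+5 s epochs never overlap
  expect_true(all(diff(sim$events$onset) >= 10))
})

test_that("ground-truth categories are a pure function of the planted gains", {
  ch <- channel_table(paste0("X", 1:3), "X", 1:3)
  for (seed in 1:20) {
    set.seed(seed)
    g <- matrix(sample(0:4, 6, replace = TRUE), 3, 2)
    specs <- do.call(rbind, lapply(1:3, function(i) rbind(
      response_spec(paste0("X", i), "palatable", g[i, 1]),
      response_spec(paste0("X", i), "neutral", g[i, 2]))))
    truth <- true_categories(specs, ch, "cue")
    want <- ifelse(g[, 1] == 0 & g[, 2] == 0, "inactive",
                   ifelse(g[, 1] == g[, 2], "responsive", "specific"))
    expect_equal(truth$category, want)
  }
})
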