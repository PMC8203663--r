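# Shared fixtures, built in code. Expensive sessions are memoised per test
# run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# three-channel task session: A1 inactive, B1 responsive (3/3),
# C1 neutral-dominant specific (palatable 1, neutral 4), onset 0.3 s
small_task_session <- function() {
  cached("small_task", function() {
    specs <- rbind(
      response_spec("B1", "palatable", 3, 0.3, 1, 0.1, "cue"),
      response_spec("B1", "neutral", 3, 0.3, 1, 0.1, "cue"),
      response_spec("C1", "palatable", 1, 0.3, 1, 0.1, "cue"),
      response_spec("C1", "neutral", 4, 0.3, 1, 0.1, "cue"))
    ch <- channel_table(c("A1", "B1", "C1"), c("A", "B", "C"), c(1, 1, 1),
                        region = c("frontal_operculum", "anterior_insula",
                                   "posterior_insula"))
    sim <- generate_task_session(specs, n_trials = 40, channels = ch, seed = 71)
    hfb <- band_power(sim$rec, "hfb")
    sim$epochs <- epoch_and_zscore(hfb, sim$events)
    sim
  })
}

# white-noise z-score epochs for null calibration
noise_epochs <- function(n_trials = 30, n_channels = 1, fs = 256,
                         t_range = c(-0.7, 0.6), seed = 1) {
  set.seed(seed)
  times <- seq(t_range[1], t_range[2], by = 1 / fs)
  dat <- array(rnorm(n_trials * n_channels * length(times)),
               c(n_trials, n_channels, length(times)))
  band_epochs(dat, times, rep_len(c("palatable", "neutral"), n_trials))
}

# Gaussian feature matrix with class separation delta planted in one window
gaussian_features <- function(delta, feature = 2, n_per_class = 100, seed = 1) {
  set.seed(seed)
  lab <- rep(c("neutral", "palatable"), each = n_per_class)
  X <- matrix(rnorm(2 * n_per_class * 4), 2 * n_per_class, 4)
  X[lab == "neutral", feature] <- X[lab == "neutral", feature] + delta
  df <- data.frame(subject = "S1", channel = "C1",
                   trial = seq_len(2 * n_per_class),
                   f1 = X[, 1], f2 = X[, 2], f3 = X[, 3], f4 = X[, 4],
                   label = lab, stringsAsFactors = FALSE)
  class(df) <- c("feature_matrix", "data.frame")
  df
}

expect_spans_equal <- function(a, b, tol = 1e-9) {
  expect_equal(dim(a), dim(b))
  if (nrow(a)) expect_true(max(abs(a - b)) < tol)
}
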