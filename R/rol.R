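# Single-trial response onset latency (ROL) by segment regression.

#' Single-trial response onset latency
#'
#' On a baseline-z-scored power trace: find the first run of at least
#' `min_supra` seconds with z above `threshold` inside `search_window`;
#' take a `window`-long stretch from the first supra-threshold sample;
#' slide `min_supra`-long segments through it at 10 ms steps (90% overlap);
#' fit an ordinary least-squares line to each; among the five
#' largest-slope segments pick the one with the smallest mean squared
#' residual; the onset is that segment's first time point.
#'
#' @param trace numeric vector of z-scored power for one trial.
#' @param times time axis in seconds (same length as `trace`).
#' @param search_window c(start, end) seconds to search for the onset.
#' @param threshold z threshold (baseline SD units).
#' @param min_supra minimum supra-threshold run and segment length (s).
#' @param window extraction window length (s).
#' @return onset latency in seconds, or `NA` if no qualifying run.
#' @export
single_trial_rol <- function(trace, times, search_window = c(0, 3),
                             threshold = 2, min_supra = 0.1, window = 0.2) {
  if (length(trace) != length(times)) stop_argument("trace and times differ in length")
  fs <- 1 / stats::median(diff(times))
  if (length(trace) < as.integer(round(window * fs))) {
    stop_argument("trace shorter than the extraction window")
  }
  idx <- which(times >= search_window[1] & times < search_window[2])
  if (!length(idx)) stop_argument("search window outside the time axis")
  supra <- trace[idx] > threshold
  runs <- runs_of(supra)
  min_len <- as.integer(round(min_supra * fs))
  runs <- runs[runs[, 2] - runs[, 1] + 1 >= min_len, , drop = FALSE]
  if (nrow(runs) == 0) return(NA_real_)
  i0 <- idx[runs[1, 1]]
  nwin <- as.integer(round(window * fs))
  i1 <- min(i0 + nwin - 1, length(trace))
  seg_len <- min_len
  step <- max(1L, as.integer(round(0.01 * fs)))
  starts <- seq(i0, i1 - seg_len + 1, by = step)
  if (!length(starts)) return(times[i0])
  fits <- vapply(starts, function(s) {
    y <- trace[s:(s + seg_len - 1)]
    x <- seq_along(y)
    fit <- stats::lm.fit(cbind(1, x), y)
    c(slope = fit$coefficients[2], mse = mean(fit$residuals^2))
  }, c(slope = 0, mse = 0))
  top <- order(fits["slope", ], decreasing = TRUE)[seq_len(min(5, length(starts)))]
  best <- top[which.min(fits["mse", top])]
  times[starts[best]]
}

#' Response onset latencies for all trials and channels
#'
#' @param epochs [epoch_and_zscore()] output.
#' @param search_window c(start, end) seconds (anticipation `(0, 3)`,
#'   receipt `(3, 6)`).
#' @param config [fc_config()] (ROL parameters).
#' @return data frame with `channel`, `region`, `trial`, `condition`,
#'   `rol` (seconds; `NA` when no onset qualifies).
#' @export
rol_by_trial <- function(epochs, search_window = c(0, 3), config = fc_config()) {
  stopifnot(inherits(epochs, "band_epochs"))
  p <- config$rol
  out <- list()
  for (ch in seq_len(dim(epochs$data)[2])) {
    lat <- vapply(seq_len(dim(epochs$data)[1]), function(tr)
      single_trial_rol(epochs$data[tr, ch, ], epochs$times, search_window,
                       p$threshold, p$min_supra, p$window), 1.0)
    out[[ch]] <- data.frame(channel = epochs$channels$label[ch],
                            region = epochs$channels$region[ch],
                            trial = seq_along(lat),
                            condition = epochs$condition,
                            rol = lat, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Median onset latency with bootstrap confidence interval
#'
#' @param latencies numeric vector of single-trial latencies (seconds or
#'   ms); `NA`s (trials without onset) are dropped.
#' @param n_boot bootstrap resamples for the percentile CI of the median.
#' @param min_n minimum latency count.
#' @param seed bootstrap seed.
#' @return list with `median`, `ci` (length 2), `n`.
#' @export
region_rol <- function(latencies, n_boot = 1000, min_n = 10, seed = NULL) {
  latencies <- latencies[!is.na(latencies)]
  n <- length(latencies)
  if (n < min_n) {
    stop_argument("need at least ", min_n, " latencies (got ", n, ")")
  }
  med <- stats::median(latencies)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    stats::median(sample(latencies, n, replace = TRUE)), 1.0))
  list(median = med,
       ci = unname(stats::quantile(boots, c(0.025, 0.975))),
       n = n)
}

#' Per-region onset latency summaries
#'
#' Pools single-trial latencies across channels and conditions within each
#' region, then summarises with [region_rol()].
#'
#' @param trials output of [rol_by_trial()].
#' @param config [fc_config()].
#' @param seed bootstrap seed.
#' @return object of class `rol_result`: list with `trials` and `regions`
#'   (data frame `region`, `median_ms`, `ci_lo_ms`, `ci_hi_ms`, `n_trials`).
#' @export
rol_summary <- function(trials, config = fc_config(), seed = NULL) {
  p <- config$rol
  regions <- unique(trials$region)
  rows <- list()
  for (rg in regions) {
    lat <- trials$rol[trials$region == rg]
    lat <- lat[!is.na(lat)]
    if (length(lat) < p$min_n) next
    s <- region_rol(lat, n_boot = p$n_boot, min_n = p$min_n,
                    seed = child_seed(seed, match(rg, regions)))
    rows[[rg]] <- data.frame(region = rg, median_ms = s$median * 1000,
                             ci_lo_ms = s$ci[1] * 1000,
                             ci_hi_ms = s$ci[2] * 1000, n_trials = s$n,
                             stringsAsFactors = FALSE)
  }
  structure(list(trials = trials, regions = do.call(rbind, rows)),
            class = "rol_result")
}

#' @export
print.rol_result <- function(x, ...) {
  cat("<rol_result> region medians (ms):\n")
  print(x$regions, row.names = FALSE)
  invisible(x)
}
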