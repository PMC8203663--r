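# Condition effect sizes on epoched band power.

cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (!is.finite(sp) || sp == 0) {
    stop_argument("pooled SD is zero; effect size undefined")
  }
  (mean(a) - mean(b)) / sp
}

#' Per-channel condition effect size over a time window
#'
#' Averages each trial's z-scored power over `window`, then computes
#' Cohen's d between the two conditions with the pooled SD. The sign
#' convention is first condition minus second (positive d = greater
#' activity for `conditions[1]`, by default palatable).
#'
#' @param epochs [epoch_and_zscore()] output.
#' @param window c(start, end) seconds; the cue period uses (0, 1), the
#'   receipt period (3, 4).
#' @param conditions length-2 character: minuend and subtrahend condition.
#' @return data frame with `channel`, `d`, `n1`, `n2`.
#' @export
mean_window_effect <- function(epochs, window = c(0, 1),
                               conditions = c("palatable", "neutral")) {
  stopifnot(inherits(epochs, "band_epochs"))
  i1 <- which(epochs$condition == conditions[1])
  i2 <- which(epochs$condition == conditions[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stop_argument("each condition needs at least 2 trials")
  }
  t_idx <- which(epochs$times >= window[1] & epochs$times < window[2])
  d <- vapply(seq_len(dim(epochs$data)[2]), function(ch) {
    m <- rowMeans(epochs$data[, ch, t_idx, drop = FALSE][, 1, , drop = TRUE])
    cohens_d(m[i1], m[i2])
  }, 1.0)
  data.frame(channel = epochs$channels$label, d = d,
             n1 = length(i1), n2 = length(i2), stringsAsFactors = FALSE)
}

#' Group-level test of per-channel effect sizes
#'
#' Classical one-sample t-test of the channel-wise Cohen's d values against
#' zero, asking whether a band shows a systematic condition preference
#' across the recorded population.
#'
#' @param d numeric vector of per-channel effect sizes (>= 3 values).
#' @return list with `t`, `df`, `p`, `mean_d`, `n`.
#' @export
group_band_effects <- function(d) {
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) stop_argument("need at least 3 channels")
  if (stats::sd(d) == 0) {
    # degenerate: no spread; centred data carry no evidence against 0
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = n - 1, p = if (t == 0) 1 else 0,
                mean_d = mean(d), n = n))
  }
  tt <- stats::t.test(d, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_d = mean(d), n = n)
}
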