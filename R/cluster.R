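# Cluster-based non-parametric permutation tests on epoched band power.
#
# Two flavours share the same machinery: activity vs pre-event baseline
# (one-tailed, null built by swapping each trial's test segment with its
# time-averaged baseline value) and condition vs condition (two-tailed,
# null built by shuffling condition labels). Cluster statistic is the
# summed pointwise t over a temporally contiguous supra-threshold run
# (maxsum), compared against the permutation distribution of the maximum
# cluster mass.

new_cluster_result <- function(clusters, alpha, n_perm, tail, threshold,
                               times, null_max) {
  structure(list(clusters = clusters, alpha = alpha, n_perm = n_perm,
                 tail = tail, threshold = threshold,
                 times = range(times), null_max = null_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, %d permutations, alpha %g\n",
              x$tail, x$n_perm, x$alpha))
  if (nrow(x$clusters) == 0) cat("  no supra-threshold clusters\n")
  else print(x$clusters)
  invisible(x)
}

# contiguous runs where keep is TRUE -> (start_idx, end_idx) matrix
runs_of <- function(keep) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# pooled-variance two-sample t between rows of value matrices (vectorised
# over permutations x time); m/v are means and variances, n group sizes
pooled_t <- function(m1, v1, n1, m2, v2, n2) {
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# cluster masses of one t-trace; sign-separated runs above threshold.
# Returns matrix (start, end, mass) in sample indices.
t_clusters <- function(tvec, tcrit, tail) {
  if (tail == "greater") {
    runs <- runs_of(tvec > tcrit)
    if (nrow(runs) == 0) return(cbind(runs, numeric(0)))
    mass <- vapply(seq_len(nrow(runs)), function(i)
      sum(tvec[runs[i, 1]:runs[i, 2]]), 1.0)
    return(cbind(runs, mass))
  }
  keep <- abs(tvec) > tcrit
  if (!any(keep)) return(matrix(numeric(0), ncol = 3))
  sgn <- sign(tvec) * keep
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values != 0
  runs <- cbind(starts[sel], ends[sel])
  mass <- vapply(seq_len(nrow(runs)), function(i)
    sum(tvec[runs[i, 1]:runs[i, 2]]), 1.0)
  cbind(runs, mass)
}

max_cluster_stat <- function(tvec, tcrit, tail) {
  cl <- t_clusters(tvec, tcrit, tail)
  if (nrow(cl) == 0) return(0)
  if (tail == "greater") max(cl[, 3]) else max(abs(cl[, 3]))
}

#' Cluster permutation test of activity against baseline
#'
#' At every time point of the test window, a pooled two-sample t compares
#' the per-trial values at that time against the per-trial time-averaged
#' baseline values. Contiguous runs with t above the one-sided critical
#' value at `alpha` form clusters with mass = sum of t. The null swaps, per
#' permutation and per trial with probability 1/2, the trial's test-segment
#' values with its baseline value, and records the maximum cluster mass.
#'
#' @param epochs [epoch_and_zscore()] output.
#' @param channel channel label or index.
#' @param test_window c(start, end) seconds (half-open).
#' @param baseline_window c(start, end) seconds; must not overlap the test
#'   window.
#' @param condition restrict to one condition label (NULL = all trials).
#' @param n_perm permutation count.
#' @param alpha cluster-forming alpha.
#' @param seed permutation RNG seed.
#' @return `cluster_result` with one row per observed cluster: `start`,
#'   `end` (s), `mass`, `p`.
#' @export
cluster_perm_vs_baseline <- function(epochs, channel, test_window,
                                     baseline_window = c(-0.6, -0.1),
                                     condition = NULL, n_perm = 1000,
                                     alpha = 0.05, seed = NULL) {
  stopifnot(inherits(epochs, "band_epochs"))
  if (test_window[1] < baseline_window[2] && baseline_window[1] < test_window[2]) {
    stop_argument("test and baseline windows must not overlap")
  }
  X_all <- epoch_matrix(epochs, channel, condition)
  if (nrow(X_all) < 3) stop_argument("need at least 3 trials")
  t_idx <- which(epochs$times >= test_window[1] & epochs$times < test_window[2])
  b_idx <- which(epochs$times >= baseline_window[1] & epochs$times < baseline_window[2])
  if (!length(t_idx) || !length(b_idx)) stop_argument("window outside the epoch time axis")
  X <- X_all[, t_idx, drop = FALSE]
  b <- rowMeans(X_all[, b_idx, drop = FALSE])
  n <- nrow(X)
  df <- 2 * n - 2
  tcrit <- stats::qt(1 - alpha, df)
  xbar <- rowMeans(X)
  X2 <- X^2
  b2 <- b^2
  xbar2 <- xbar^2

  t_of <- function(s) {
    # s: 0/1 flip vector; flipped trials contribute baseline to group1
    keep <- 1 - s
    m1 <- (crossprod(keep, X)[1, ] + sum(s * b)) / n
    q1 <- (crossprod(keep, X2)[1, ] + sum(s * b2)) / n
    v1 <- (q1 - m1^2) * n / (n - 1)
    g2 <- keep * b + s * xbar
    m2 <- mean(g2)
    v2 <- stats::var(g2)
    pooled_t(m1, v1, n, m2, v2, n)
  }
  t_obs <- t_of(rep(0, n))
  null_max <- with_seed(seed, {
    S <- matrix(stats::rbinom(n_perm * n, 1, 0.5), n_perm, n)
    vapply(seq_len(n_perm), function(p)
      max_cluster_stat(t_of(S[p, ]), tcrit, "greater"), 1.0)
  })
  cl <- t_clusters(t_obs, tcrit, "greater")
  clusters <- cluster_df(cl, null_max, epochs$times[t_idx], epochs$fs, "greater")
  new_cluster_result(clusters, alpha, n_perm, "greater", tcrit,
                     epochs$times[t_idx], null_max)
}

#' Cluster permutation test between two conditions
#'
#' Pointwise pooled two-sample t (first minus second condition) over the
#' window; two-sided cluster forming at `alpha` with sign-separated
#' clusters; null from shuffling condition labels, statistic = maximum
#' absolute cluster mass.
#'
#' @param epochs [epoch_and_zscore()] output containing both conditions (or
#'   `epochs_b` given separately).
#' @param channel channel label or index.
#' @param window c(start, end) seconds.
#' @param conditions length-2 character giving group order (A - B).
#' @param epochs_b optional second `band_epochs` on the same channel/time
#'   axis; then `epochs` supplies group A and `epochs_b` group B.
#' @param n_perm,alpha,seed as in [cluster_perm_vs_baseline()].
#' @return `cluster_result`; cluster masses are signed.
#' @export
cluster_perm_between <- function(epochs, channel, window,
                                 conditions = c("palatable", "neutral"),
                                 epochs_b = NULL, n_perm = 1000,
                                 alpha = 0.05, seed = NULL) {
  stopifnot(inherits(epochs, "band_epochs"))
  if (!is.null(epochs_b)) {
    if (!isTRUE(all.equal(epochs$times, epochs_b$times))) {
      stop_integrity("the two epoch sets have mismatched time axes")
    }
    A <- epoch_matrix(epochs, channel)
    B <- epoch_matrix(epochs_b, channel)
  } else {
    A <- epoch_matrix(epochs, channel, conditions[1])
    B <- epoch_matrix(epochs, channel, conditions[2])
  }
  if (nrow(A) < 3 || nrow(B) < 3) stop_argument("need at least 3 trials per condition")
  t_idx <- which(epochs$times >= window[1] & epochs$times < window[2])
  if (!length(t_idx)) stop_argument("window outside the epoch time axis")
  A <- A[, t_idx, drop = FALSE]
  B <- B[, t_idx, drop = FALSE]
  nA <- nrow(A); nB <- nrow(B); N <- nA + nB
  df <- N - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  Z <- rbind(A, B)
  Z2 <- Z^2
  colsum <- colSums(Z)
  colsum2 <- colSums(Z2)

  t_of_sel <- function(selA) {
    s1 <- crossprod(selA, Z)[1, ]
    q1 <- crossprod(selA, Z2)[1, ]
    m1 <- s1 / nA
    v1 <- (q1 - nA * m1^2) / (nA - 1)
    m2 <- (colsum - s1) / nB
    v2 <- (colsum2 - q1 - nB * m2^2) / (nB - 1)
    pooled_t(m1, v1, nA, m2, v2, nB)
  }
  t_obs <- t_of_sel(c(rep(1, nA), rep(0, nB)))
  # Null draws use a canonical (data-sorted) ordering of the pooled trials,
  # so that with a fixed seed the null distribution depends only on the
  # pooled trial set, not on which group was passed first.
  ord <- do.call(order, lapply(seq_len(min(5L, ncol(Z))), function(j) Z[, j]))
  Zs <- Z[ord, , drop = FALSE]
  Zs2 <- Zs^2
  t_of_sorted <- function(selA) {
    s1 <- crossprod(selA, Zs)[1, ]
    q1 <- crossprod(selA, Zs2)[1, ]
    m1 <- s1 / nA
    v1 <- (q1 - nA * m1^2) / (nA - 1)
    m2 <- (colsum - s1) / nB
    v2 <- (colsum2 - q1 - nB * m2^2) / (nB - 1)
    pooled_t(m1, v1, nA, m2, v2, nB)
  }
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      sel <- numeric(N)
      sel[sample.int(N, nA)] <- 1
      max_cluster_stat(t_of_sorted(sel), tcrit, "two_sided")
    }, 1.0)
  })
  cl <- t_clusters(t_obs, tcrit, "two_sided")
  clusters <- cluster_df(cl, null_max, epochs$times[t_idx], epochs$fs, "two_sided")
  new_cluster_result(clusters, alpha, n_perm, "two_sided", tcrit,
                     epochs$times[t_idx], null_max)
}

cluster_df <- function(cl, null_max, times, fs, tail) {
  if (nrow(cl) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      mass = numeric(0), p = numeric(0)))
  }
  n_perm <- length(null_max)
  stat <- if (tail == "greater") cl[, 3] else abs(cl[, 3])
  p <- vapply(stat, function(m) (1 + sum(null_max >= m)) / (1 + n_perm), 1.0)
  out <- data.frame(start = times[cl[, 1]],
                    end = times[cl[, 2]] + 1 / fs,
                    mass = cl[, 3], p = p)
  out[order(out$start), , drop = FALSE]
}
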