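# Cluster permutation engines: power, degeneracy, determinism, symmetry,
# and agreement with full enumeration on a small instance.

test_that("a strong planted response yields a covering significant cluster", {
  hits <- vapply(1:15, function(s) {
    set.seed(s)
    times <- seq(-0.7, 1.2, by = 1 / 256)
    dat <- array(rnorm(20 * length(times)), c(20, 1, length(times)))
    on <- times >= 0.2 & times < 1.0
    dat[, 1, on] <- dat[, 1, on] + 2.5
    ep <- band_epochs(dat, times, rep(c("palatable", "neutral"), 10))
    r <- cluster_perm_vs_baseline(ep, 1, c(0, 1.2), n_perm = 300,
                                  seed = 900 + s)
    sig <- r$clusters[r$clusters$p < 0.05, , drop = FALSE]
    any(sig$start < 1.0 & sig$end > 0.2)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("test values identical to the baseline produce no clusters", {
  times <- seq(-0.7, 0.6, by = 1 / 256)
  dat <- array(0, c(12, 1, length(times)))
  b_idx <- times >= -0.6 & times < -0.1
  set.seed(3)
  for (tr in 1:12) {
    b <- rnorm(1)
    dat[tr, 1, ] <- b                    # every sample equals the baseline mean
  }
  ep <- band_epochs(dat + array(rnorm(length(dat), sd = 1e-9), dim(dat)),
                    times, rep(c("palatable", "neutral"), 6))
  ep$data[ , 1, ] <- dat[, 1, ] * 0 + dat[, 1, 1]
  r <- cluster_perm_vs_baseline(ep, 1, c(0, 0.5), n_perm = 100, seed = 4)
  expect_equal(nrow(r$clusters), 0)
})

test_that("results are deterministic under a fixed permutation seed", {
  ep <- noise_epochs(seed = 61)
  r1 <- cluster_perm_vs_baseline(ep, 1, c(0, 0.5), n_perm = 200, seed = 9)
  r2 <- cluster_perm_vs_baseline(ep, 1, c(0, 0.5), n_perm = 200, seed = 9)
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(r1$clusters, r2$clusters)
  b1 <- cluster_perm_between(ep, 1, c(0, 0.5), n_perm = 200, seed = 9)
  b2 <- cluster_perm_between(ep, 1, c(0, 0.5), n_perm = 200, seed = 9)
  expect_identical(b1$null_max, b2$null_max)
})

test_that("swapping the two conditions flips cluster signs but not p-values", {
  set.seed(62)
  times <- seq(-0.7, 1, by = 1 / 256)
  dat <- array(rnorm(24 * length(times)), c(24, 1, length(times)))
  on <- times >= 0.3 & times < 0.8
  dat[1:12, 1, on] <- dat[1:12, 1, on] + 2
  lab <- rep(c("palatable", "neutral"), each = 12)
  epA <- band_epochs(dat, times, lab)
  epB <- band_epochs(dat, times, rev(lab))
  rA <- cluster_perm_between(epA, 1, c(0, 1), n_perm = 300, seed = 7)
  rB <- cluster_perm_between(epB, 1, c(0, 1), n_perm = 300, seed = 7)
  expect_equal(rA$clusters$mass, -rB$clusters$mass)
  expect_equal(rA$clusters$p, rB$clusters$p)
  sig <- rA$clusters[rA$clusters$p < 0.05, ]
  expect_true(any(sig$mass > 0 & sig$start < 0.8 & sig$end > 0.3))
  expect_error(cluster_perm_vs_baseline(epA, 1, c(-0.3, 0.5)), "overlap")
})

test_that("permutation null matches full enumeration on a 6-trial toy", {
  # 3 vs 3 trials, 20 samples: all C(6,3) = 20 balanced assignments
  set.seed(63)
  n_time <- 20
  times <- seq(0.01, 0.2, by = 0.01)
  A <- matrix(rnorm(3 * n_time), 3)
  B <- matrix(rnorm(3 * n_time), 3)
  full <- array(0, c(6, 1, n_time))
  full[, 1, ] <- rbind(A, B)
  ep <- band_epochs(full, times, rep(c("palatable", "neutral"), each = 3),
                    baseline = c(0, 0))
  r <- cluster_perm_between(ep, 1, c(0, 0.21), n_perm = 1000, seed = 8)

  # independent enumeration oracle: per assignment, pointwise Welch-free
  # pooled t via t.test, threshold at qt(0.975, 4), maxsum of |mass|
  Z <- rbind(A, B)
  tcrit <- qt(0.975, 4)
  combos <- utils::combn(6, 3)
  enum <- apply(combos, 2, function(g1) {
    tv <- vapply(seq_len(n_time), function(j)
      unname(stats::t.test(Z[g1, j], Z[-g1, j], var.equal = TRUE)$statistic),
      1.0)
    keep <- abs(tv) > tcrit
    if (!any(keep)) return(0)
    r <- rle(sign(tv) * keep)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    max(abs(vapply(which(r$values != 0), function(k)
      sum(tv[starts[k]:ends[k]]), 1.0)))
  })
  # round so that identical atoms computed by the two formulas coincide
  ks <- suppressWarnings(stats::ks.test(round(r$null_max, 6),
                                        round(enum, 6))$statistic)
  expect_lt(unname(ks), 0.1)
})
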