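# Layered site classification, span bookkeeping, topology chi-square tests
# and the task/meal association.

test_that("span bookkeeping implements the overlap rules", {
  m <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  merged <- foodcue:::merge_spans(m(0, 0.3, 0.2, 0.5, 0.9, 1.0))
  expect_equal(nrow(merged), 2)
  expect_equal(merged[1, ], c(start = 0, end = 0.5))
  expect_equal(foodcue:::span_intersection_length(m(0, 0.3), m(0.2, 0.5)), 0.1,
               tolerance = 1e-12)
  expect_equal(foodcue:::span_intersection_length(m(0, 0.1), m(0.5, 0.6)), 0)
  expect_equal(foodcue:::span_total_length(merged), 0.6, tolerance = 1e-12)
})

test_that("planted categories are recovered with correct effect-size sign", {
  sim <- small_task_session()
  cfg <- fc_config(n_perm = 500)
  inactive <- classify_task_site(sim$epochs, "A1", "anticipation", cfg, seed = 1)
  responsive <- classify_task_site(sim$epochs, "B1", "anticipation", cfg, seed = 2)
  specific <- classify_task_site(sim$epochs, "C1", "anticipation", cfg, seed = 3)
  expect_equal(inactive$category, "inactive")
  expect_equal(responsive$category, "responsive")
  expect_gt(nrow(responsive$responsive_spans[[1]]), 0)
  expect_equal(specific$category, "specific")
  expect_lt(specific$d, 0)               # neutral-dominant, Fig-style sign
  # responsive spans cover the planted response (0.3 - 1.3 s)
  spans <- specific$responsive_spans[[1]]
  expect_gte(foodcue:::span_intersection_length(
    spans, matrix(c(0.3, 1.3), 1)), 0.3)
  expect_error(classify_task_site(sim$epochs, "A1", "anticipation",
                                  fc_config(site_windows = 20)), "past the epoch")
})

test_that("receipt-phase windows start at solution delivery", {
  sim <- small_task_session()
  cfg <- fc_config(n_perm = 300)
  # no receipt-phase responses were planted: receipt phase stays inactive
  rec_lab <- classify_task_site(sim$epochs, "C1", "receipt", cfg, seed = 4)
  expect_equal(rec_lab$category, "inactive")
})

test_that("meal classification needs 10 bites and finds planted specificity", {
  times <- seq(-5, 5 - 1 / 256, by = 1 / 256)
  set.seed(65)
  dat <- array(rnorm(30 * length(times)), c(30, 1, length(times)))
  on <- times >= -0.3 & times < 0.7
  lab <- rep(c("entree", "non_entree"), each = 15)
  dat[lab == "entree", 1, on] <- dat[lab == "entree", 1, on] + 2.5
  ep <- band_epochs(dat, times, lab, phase = "bite", baseline = c(-5, -4.5))
  out <- classify_meal_site(ep, 1, fc_config(n_perm = 400), seed = 5)
  expect_equal(out$category, "specific")
  expect_gt(out$d, 0)                    # entree-dominant

  few <- band_epochs(dat[c(1:9, 16:30), , , drop = FALSE],
                     times, lab[c(1:9, 16:30)], phase = "bite")
  expect_error(classify_meal_site(few, 1), "at least 10 repetitions")
})

test_that("region proportion chi-square matches the closed form", {
  # [[10, 0], [0, 10]] -> chi-square 20, df 1
  labels <- do.call(rbind, c(
    lapply(sprintf("P%02d", 1:10), foodcue:::site_label_row,
           phase = "anticipation", category = "specific"),
    lapply(sprintf("Q%02d", 1:10), foodcue:::site_label_row,
           phase = "anticipation", category = "inactive")))
  class(labels) <- c("site_labels", "data.frame")
  channels <- channel_table(labels$channel, labels$channel, 1,
                            region = rep(c("anterior_insula",
                                           "posterior_insula"), each = 10))
  res <- region_proportions_test(labels, channels, "L",
                                 regions = c("anterior_insula",
                                             "posterior_insula"))
  expect_equal(res$statistic, 20, tolerance = 1e-9)
  expect_equal(res$df, 1)
  expect_lt(res$p, 1e-4)

  # identical rows -> statistic 0, p 1
  labels2 <- labels
  labels2$category <- rep(c("specific", "inactive"), 10)
  res2 <- region_proportions_test(labels2, channels, "L",
                                  regions = c("anterior_insula",
                                              "posterior_insula"))
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)

  # random 3 x 3 table equals sum((O - E)^2 / E) to 1e-8
  set.seed(66)
  cats <- c("inactive", "responsive", "specific")
  regions <- c("frontal_operculum", "anterior_insula", "posterior_insula")
  n <- 60
  labels3 <- do.call(rbind, lapply(seq_len(n), function(i)
    foodcue:::site_label_row(sprintf("R%02d", i), "anticipation",
                             sample(cats, 1))))
  class(labels3) <- c("site_labels", "data.frame")
  channels3 <- channel_table(labels3$channel, labels3$channel, 1,
                             region = sample(regions, n, replace = TRUE))
  res3 <- region_proportions_test(labels3, channels3, "L")
  O <- unclass(res3$table)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_lt(abs(res3$statistic - sum((O - E)^2 / E)), 1e-8)
})

test_that("task/meal association chi-square and degenerate margins", {
  mk_labels <- function(labs, cats, phase) {
    out <- do.call(rbind, Map(foodcue:::site_label_row, labs, phase, cats))
    class(out) <- c("site_labels", "data.frame")
    out
  }
  labs <- sprintf("C%02d", 1:16)
  task <- mk_labels(labs, rep(c("specific", "inactive"), each = 8), "anticipation")
  meal <- mk_labels(labs, rep(c("specific", "inactive"), each = 8), "meal")
  res <- task_meal_association(task, meal)
  expect_equal(res$statistic, 16, tolerance = 1e-9)
  expect_equal(res$df, 1)

  all_food <- mk_labels(labs, rep("specific", 16), "meal")
  expect_warning(res_deg <- task_meal_association(task, all_food), "degenerate")
  expect_true(is.na(res_deg$p))

  other <- mk_labels(sprintf("D%02d", 1:16), rep("inactive", 16), "meal")
  expect_error(task_meal_association(task, other), "different channels")
})
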