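# Layered site classification: inactive / responsive / specific per channel
# and phase, plus topology proportion tests and the task<->meal association.

site_label_row <- function(channel, phase, category, d = NA_real_,
                           responsive_spans = NULL, specific_spans = NULL) {
  empty <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  df <- data.frame(channel = channel, phase = phase, category = category,
                   d = d, stringsAsFactors = FALSE)
  df$responsive_spans <- list(if (is.null(responsive_spans)) empty else responsive_spans)
  df$specific_spans <- list(if (is.null(specific_spans)) empty else specific_spans)
  class(df) <- c("site_labels", "data.frame")
  df
}

phase_windows <- function(phase, config) {
  origin <- switch(phase, anticipation = 0, receipt = config$task$receipt_onset,
                   stop_argument("phase must be 'anticipation' or 'receipt'"))
  w <- config$site_window_width
  lapply(seq_len(config$site_windows) - 1, function(k)
    c(origin + k * w, origin + (k + 1) * w))
}

#' Classify one channel as inactive, responsive or specific (task)
#'
#' Three layered steps on cue-locked epochs:
#' \enumerate{
#'   \item Responsive: for each condition separately,
#'     [cluster_perm_vs_baseline()] in five consecutive non-overlapping
#'     500 ms windows tiling the first 2.5 s of the phase; the channel is
#'     responsive if any significant cluster (p < alpha) spans at least
#'     200 ms.
#'   \item Specific: within the windows that contained a significant step-1
#'     response, [cluster_perm_between()] (palatable vs neutral) at a
#'     Bonferroni-adjusted threshold alpha / (number of windows tested);
#'     the channel is specific if a significant between-condition cluster
#'     overlaps the step-1 responsive spans by at least 100 ms in total.
#'   \item Effect size: for specific channels, Cohen's d of per-trial mean
#'     z over the union of specific spans (palatable minus neutral).
#' }
#' Category precedence is specific > responsive > inactive.
#'
#' @param epochs cue-locked [epoch_and_zscore()] output with both
#'   conditions.
#' @param channel channel label or index.
#' @param phase `"anticipation"` (windows from 0 s) or `"receipt"`
#'   (windows from 3 s).
#' @param config [fc_config()].
#' @param seed permutation seed.
#' @return one-row `site_labels` data frame.
#' @export
classify_task_site <- function(epochs, channel, phase = c("anticipation", "receipt"),
                               config = fc_config(), seed = NULL) {
  phase <- match.arg(phase)
  windows <- phase_windows(phase, config)
  if (windows[[length(windows)]][2] > max(epochs$times) + 1 / epochs$fs) {
    stop_argument("phase windows extend past the epoch time axis")
  }
  conditions <- config$task$conditions
  alpha <- config$cluster_alpha

  resp_spans <- NULL
  windows_hit <- logical(length(windows))
  responsive <- FALSE
  for (wi in seq_along(windows)) {
    for (cond in conditions) {
      res <- cluster_perm_vs_baseline(
        epochs, channel, windows[[wi]], config$task_baseline,
        condition = cond, n_perm = config$n_perm, alpha = alpha,
        seed = child_seed(seed, wi * 7 + match(cond, conditions)))
      sig <- res$clusters[res$clusters$p < alpha, , drop = FALSE]
      if (nrow(sig)) {
        windows_hit[wi] <- TRUE
        resp_spans <- rbind(resp_spans, as.matrix(sig[, c("start", "end")]))
        if (any(sig$end - sig$start >= config$min_response)) responsive <- TRUE
      }
    }
  }
  resp_spans <- merge_spans(resp_spans)
  if (!responsive) {
    return(site_label_row(site_channel_label(epochs, channel), phase, "inactive"))
  }

  n_tested <- sum(windows_hit)
  alpha_spec <- alpha / n_tested
  spec_spans <- NULL
  for (wi in which(windows_hit)) {
    res <- cluster_perm_between(
      epochs, channel, windows[[wi]], conditions = conditions,
      n_perm = config$n_perm, alpha = alpha,
      seed = child_seed(seed, 100 + wi))
    sig <- res$clusters[res$clusters$p < alpha_spec, , drop = FALSE]
    if (nrow(sig)) spec_spans <- rbind(spec_spans, as.matrix(sig[, c("start", "end")]))
  }
  spec_spans <- merge_spans(spec_spans)
  specific <- span_intersection_length(spec_spans, resp_spans) >= config$min_overlap
  if (!specific) {
    return(site_label_row(site_channel_label(epochs, channel), phase,
                          "responsive", responsive_spans = resp_spans))
  }
  d <- spans_effect_size(epochs, channel, spec_spans, conditions)
  site_label_row(site_channel_label(epochs, channel), phase, "specific",
                 d = d, responsive_spans = resp_spans,
                 specific_spans = spec_spans)
}

site_channel_label <- function(epochs, channel) {
  if (is.numeric(channel)) epochs$channels$label[channel] else channel
}

# Cohen's d of per-trial mean z over a union of spans (cond1 - cond2)
spans_effect_size <- function(epochs, channel, spans, conditions) {
  idx <- unlist(lapply(seq_len(nrow(spans)), function(i)
    which(epochs$times >= spans[i, 1] & epochs$times < spans[i, 2])))
  idx <- sort(unique(idx))
  X <- epoch_matrix(epochs, channel)
  m <- rowMeans(X[, idx, drop = FALSE])
  cohens_d(m[epochs$condition == conditions[1]],
           m[epochs$condition == conditions[2]])
}

#' Classify every channel of an epoch set
#'
#' @inheritParams classify_task_site
#' @return `site_labels` data frame, one row per channel.
#' @export
classify_all_sites <- function(epochs, phase = "anticipation",
                               config = fc_config(), seed = NULL) {
  out <- do.call(rbind, lapply(seq_len(dim(epochs$data)[2]), function(ch)
    classify_task_site(epochs, ch, phase, config,
                       seed = child_seed(seed, ch * 1000))))
  class(out) <- c("site_labels", "data.frame")
  out
}

#' Classify a channel as food-specific during a meal
#'
#' [cluster_perm_between()] of entree vs non-entree bite-locked epochs over
#' -1 to 1 s around food intake; the channel is food-specific if any
#' cluster is significant at `alpha`. Requires at least 10 bites per food
#' type (trial-averaging inclusion criterion).
#'
#' @param epochs bite-locked [epoch_and_zscore()] output.
#' @param channel channel label or index.
#' @param config [fc_config()].
#' @param seed permutation seed.
#' @return one-row `site_labels` data frame with phase `"meal"` and
#'   category `"specific"` (food-specific) or `"inactive"`.
#' @export
classify_meal_site <- function(epochs, channel, config = fc_config(),
                               seed = NULL) {
  conditions <- config$meal$conditions
  n1 <- sum(epochs$condition == conditions[1])
  n2 <- sum(epochs$condition == conditions[2])
  if (min(n1, n2) < config$min_bites) {
    stop_argument("inclusion criterion: at least ", config$min_bites,
                  " repetitions per food type required (got ", n1, " and ", n2, ")")
  }
  res <- cluster_perm_between(epochs, channel, config$meal_test_window,
                              conditions = conditions, n_perm = config$n_perm,
                              alpha = config$cluster_alpha, seed = seed)
  sig <- res$clusters[res$clusters$p < config$cluster_alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(site_label_row(site_channel_label(epochs, channel), "meal", "inactive"))
  }
  spans <- merge_spans(as.matrix(sig[, c("start", "end")]))
  d <- spans_effect_size(epochs, channel, spans, conditions)
  site_label_row(site_channel_label(epochs, channel), "meal", "specific",
                 d = d, specific_spans = spans)
}

#' Chi-square test of category proportions across regions
#'
#' Pearson chi-square (no continuity correction) on the region x category
#' contingency table of channel counts within one hemisphere. Regions with
#' no channels are dropped with a warning.
#'
#' @param labels `site_labels` data frame.
#' @param channels channel metadata table.
#' @param side hemisphere, `"L"` or `"R"`.
#' @param regions regions to tabulate.
#' @return list with `statistic`, `df`, `p`, `table`.
#' @export
region_proportions_test <- function(labels, channels, side = "L",
                                    regions = c("frontal_operculum",
                                                "anterior_insula",
                                                "posterior_insula")) {
  ch <- channels[channels$hemisphere == side & channels$region %in% regions, ]
  cat_by_channel <- stats::setNames(labels$category, labels$channel)
  categories <- factor(cat_by_channel[ch$label],
                       levels = c("inactive", "responsive", "specific"))
  tab <- table(factor(ch$region, levels = regions), categories)
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("dropping region(s) with no channels: ",
            paste(rownames(tab)[empty], collapse = ", "), call. = FALSE)
    tab <- tab[!empty, , drop = FALSE]
  }
  # categories absent everywhere carry no information for the test
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2) stop_argument("need at least 2 regions with channels")
  if (ncol(tab) < 2) stop_argument("all channels share one category")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, table = tab)
}

#' Association between task response and food-specific meal response
#'
#' 2x2 Pearson chi-square (df 1, no continuity correction) between holding
#' the given task category and being food-specific during the meal, over a
#' common channel set.
#'
#' @param task_labels `site_labels` from [classify_all_sites()].
#' @param meal_labels `site_labels` from meal classification.
#' @param task_category task category defining the first margin
#'   (`"specific"` or `"responsive"`).
#' @return list with `statistic`, `df`, `p`, `table`; degenerate margins
#'   give a warning and `NA` statistics.
#' @export
task_meal_association <- function(task_labels, meal_labels,
                                  task_category = "specific") {
  if (!setequal(task_labels$channel, meal_labels$channel)) {
    stop_integrity("task and meal label sets cover different channels")
  }
  m <- match(task_labels$channel, meal_labels$channel)
  task_yes <- factor(task_labels$category == task_category, levels = c(FALSE, TRUE))
  food_yes <- factor(meal_labels$category[m] == "specific", levels = c(FALSE, TRUE))
  tab <- table(task = task_yes, food = food_yes)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate contingency margin; association undefined", call. = FALSE)
    return(list(statistic = NA_real_, df = 1, p = NA_real_, table = tab))
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, table = tab)
}
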