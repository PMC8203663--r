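# Single-trial decoding of the anticipated condition from HFB window
# features: standardize -> PCA (95% variance) -> weighted KNN (squared
# inverse distance, Euclidean, k = 10) under stratified k-fold
# cross-validation, plus permutation feature importance.

#' Extract window-mean HFB features for single-trial decoding
#'
#' One observation per (channel, trial) pair: the mean z-scored power over
#' each of the four anticipation windows 0-0.5, 0.5-1, 1-2 and 2-3 s,
#' labelled with the trial's condition.
#'
#' @param epochs cue-locked [epoch_and_zscore()] output.
#' @param channels channel labels (or indices) to draw observations from;
#'   typically the condition-specific sites found by
#'   [classify_all_sites()].
#' @param windows list of c(start, end) feature windows in seconds.
#' @param subject subject identifier stored as provenance.
#' @return data frame of class `feature_matrix` with columns `subject`,
#'   `channel`, `trial`, `f1..f4`, `label`.
#' @export
extract_features <- function(epochs, channels,
                             windows = list(c(0, 0.5), c(0.5, 1),
                                            c(1, 2), c(2, 3)),
                             subject = "S1") {
  stopifnot(inherits(epochs, "band_epochs"))
  if (length(channels) == 0) stop_argument("channel subset is empty")
  if (is.numeric(channels)) channels <- epochs$channels$label[channels]
  idx_list <- lapply(windows, function(w)
    which(epochs$times >= w[1] & epochs$times < w[2]))
  rows <- list()
  for (lab in channels) {
    X <- epoch_matrix(epochs, lab)
    feats <- vapply(idx_list, function(ix)
      rowMeans(X[, ix, drop = FALSE]), numeric(nrow(X)))
    rows[[lab]] <- data.frame(subject = subject, channel = lab,
                              trial = seq_len(nrow(X)), feats,
                              label = epochs$condition,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[4:(3 + length(windows))] <- paste0("f", seq_along(windows))
  rownames(out) <- NULL
  class(out) <- c("feature_matrix", "data.frame")
  out
}

feature_cols <- function(features) grep("^f[0-9]+$", names(features), value = TRUE)

# stratified fold assignment: within each class, random order, folds cycled
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# weighted KNN vote scores for the positive class; ties in distance broken
# by observation index (stable order from the sort)
knn_scores <- function(train, test, train_labels, positive, k) {
  k <- min(k, nrow(train))
  pos <- train_labels == positive
  apply(test, 1, function(x) {
    d2 <- colSums((t(train) - x)^2)
    nn <- sort.int(d2, index.return = TRUE, method = "radix")$ix[seq_len(k)]
    w <- 1 / pmax(d2[nn], 1e-12)
    sum(w[pos[nn]]) / sum(w)
  })
}

#' Train and evaluate the weighted KNN decoder with cross-validation
#'
#' Per fold: features are standardized with training-fold statistics, PCA
#' is fitted on the training fold keeping the smallest number of
#' components reaching `var_explained`, and a weighted KNN (Euclidean
#' distance, squared-inverse-distance weights, `k` neighbours) votes on
#' the test fold. Positive-class vote shares provide ROC/AUC.
#'
#' @param features [extract_features()] output.
#' @param n_folds cross-validation folds.
#' @param k neighbour count.
#' @param var_explained PCA variance fraction to retain.
#' @param positive positive class label (class 1 of the ROC).
#' @param compute_auc set FALSE to skip ROC/AUC (used by the permutation
#'   test, which only needs TPR/FPR).
#' @param seed fold-assignment seed.
#' @return object of class `classifier_report`: per-fold and mean TPR,
#'   FPR (macro across the two classes), AUC, kept PCA components and
#'   explained variance shares.
#' @export
train_eval_knn <- function(features, n_folds = 5, k = 10,
                           var_explained = 0.95, positive = "neutral",
                           compute_auc = TRUE, seed = NULL) {
  cols <- feature_cols(features)
  X <- as.matrix(features[, cols])
  y <- features$label
  classes <- sort(unique(y))
  if (length(classes) != 2) stop_argument("need exactly two classes")
  if (any(table(y) < k)) stop_argument("each class needs at least k observations")
  negative <- setdiff(classes, positive)
  fold <- with_seed(seed, stratified_folds(y, n_folds))
  per_fold <- list()
  scores_all <- numeric(nrow(X))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    pca <- stats::prcomp(Ztr, center = FALSE, scale. = FALSE)
    evar <- pca$sdev^2 / sum(pca$sdev^2)
    m <- which(cumsum(evar) >= var_explained)[1]
    Ptr <- pca$x[, seq_len(m), drop = FALSE]
    Pte <- Zte %*% pca$rotation[, seq_len(m), drop = FALSE]
    sc <- knn_scores(Ptr, Pte, y[tr], positive, k)
    scores_all[!tr] <- sc
    pred <- ifelse(sc > 0.5, positive, negative)
    truth <- y[!tr]
    tpr_pos <- mean(pred[truth == positive] == positive)
    tpr_neg <- mean(pred[truth == negative] == negative)
    auc <- NA_real_
    if (compute_auc && length(unique(truth)) == 2) {
      auc <- as.numeric(pROC::auc(pROC::roc(
        response = truth, predictor = sc, levels = c(negative, positive),
        direction = "<", quiet = TRUE)))
    }
    per_fold[[f]] <- data.frame(
      fold = f, n_test = sum(!tr), pca_components = m,
      tpr = mean(c(tpr_pos, tpr_neg)), fpr = 1 - mean(c(tpr_pos, tpr_neg)),
      auc = auc, explained_variance = sum(evar[seq_len(m)]))
  }
  folds_df <- do.call(rbind, per_fold)
  pooled_auc <- NA_real_
  if (compute_auc) {
    pooled_auc <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = scores_all, levels = c(negative, positive),
      direction = "<", quiet = TRUE)))
  }
  structure(list(per_fold = folds_df,
                 mean_tpr = mean(folds_df$tpr), mean_fpr = mean(folds_df$fpr),
                 mean_auc = if (compute_auc) mean(folds_df$auc) else NA_real_,
                 pooled_auc = pooled_auc,
                 positive = positive, k = k, n_folds = n_folds,
                 n_obs = nrow(X)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d obs, %d-fold CV, weighted KNN (k = %d)\n",
              x$n_obs, x$n_folds, x$k))
  cat(sprintf("  mean TPR %.3f, FPR %.3f, AUC %s (pooled %s)\n",
              x$mean_tpr, x$mean_fpr,
              formatC(x$mean_auc, digits = 3, format = "f"),
              formatC(x$pooled_auc, digits = 3, format = "f")))
  invisible(x)
}

#' Permutation feature importance for the KNN decoder
#'
#' For each feature, the decoder is fully retrained `n_perm` times on data
#' with that feature's values randomly reassigned across observations; the
#' importance p-value is the (+1-corrected) fraction of shuffled runs
#' whose mean TPR is at least the observed one (and, for FPR, at most the
#' observed one).
#'
#' @param features [extract_features()] output.
#' @param n_perm shuffles per feature (values below 20 warn).
#' @param ... passed to [train_eval_knn()].
#' @param seed RNG seed.
#' @return list with `observed` (report), and a data frame `importance`
#'   with `feature`, `mean_shuffled_tpr`, `mean_shuffled_fpr`, `p_tpr`,
#'   `p_fpr`, `tpr_drop`.
#' @export
feature_permutation_test <- function(features, n_perm = 100, seed = NULL, ...) {
  if (n_perm < 20) warning("fewer than 20 permutations gives unstable p-values",
                           call. = FALSE)
  cols <- feature_cols(features)
  observed <- train_eval_knn(features, compute_auc = FALSE,
                             seed = child_seed(seed, 0), ...)
  rows <- list()
  for (j in seq_along(cols)) {
    tprs <- numeric(n_perm)
    fprs <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      shuf <- features
      perm_seed <- child_seed(seed, j * 10000 + p)
      shuf[[cols[j]]] <- with_seed(perm_seed, sample(shuf[[cols[j]]]))
      rep_p <- train_eval_knn(shuf, compute_auc = FALSE,
                              seed = child_seed(seed, 0), ...)
      tprs[p] <- rep_p$mean_tpr
      fprs[p] <- rep_p$mean_fpr
    }
    rows[[j]] <- data.frame(
      feature = cols[j],
      mean_shuffled_tpr = mean(tprs), mean_shuffled_fpr = mean(fprs),
      p_tpr = (1 + sum(tprs >= observed$mean_tpr)) / (1 + n_perm),
      p_fpr = (1 + sum(fprs <= observed$mean_fpr)) / (1 + n_perm),
      tpr_drop = observed$mean_tpr - mean(tprs))
  }
  list(observed = observed, importance = do.call(rbind, rows))
}
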