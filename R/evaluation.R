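# Evaluation: confusion counts, sensitivity, ROC/AUC, per-subject and cohort
# aggregation, and the train/test feature-distribution drift report.

#' Confusion counts at a probability threshold
#'
#' Prediction is positive when \code{score >= threshold} (ties predicted
#' positive).
#'
#' @param scores numeric scores/probabilities.
#' @param labels binary ground truth.
#' @param threshold decision threshold (default 0.5).
#' @return named vector (tp, fp, tn, fn), summing to \code{length(scores)}.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (!length(scores)) stopf("empty input")
  stopifnot(length(scores) == length(labels))
  pred <- scores >= threshold
  c(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
    tn = sum(!pred & labels == 0), fn = sum(!pred & labels == 1))
}

#' Sensitivity (true positive rate)
#'
#' \code{TP / (TP + FN)}.
#' @param tp,fn true-positive and false-negative counts.
#' @return scalar in [0, 1].
#' @export
sensitivity <- function(tp, fn) {
  if (tp + fn <= 0) stopf("sensitivity undefined: no positive examples")
  tp / (tp + fn)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties grouped), trapezoid-rule
#' area; this tie handling makes the AUC exactly the midrank Mann-Whitney
#' pair statistic (ties counted one half).
#'
#' @param scores numeric scores.
#' @param labels binary ground truth; both classes must be present.
#' @return list with \code{roc} (data.frame threshold/fpr/tpr, including the
#'   (0,0) and (1,1) endpoints) and \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stopf("roc_auc needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative counts at each distinct threshold (all examples with score >=
  # that threshold are predicted positive); `keep` marks the last member of
  # each tie group
  cum_tp <- cumsum(l == 1)
  cum_fp <- cumsum(l == 0)
  keep <- c(diff(s) != 0, TRUE)
  tpr <- c(0, cum_tp[keep] / npos)
  fpr <- c(0, cum_fp[keep] / nneg)
  thr <- c(Inf, s[keep])
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Aggregate fold results into subject and cohort summaries
#'
#' Per subject: mean and SD of fold sensitivities and AUCs (sample SD; 0 for
#' a single fold). Cohort row \code{"AVG"}: mean and SD across subject means.
#'
#' @param results data.frame with one row per fold: columns \code{subject},
#'   \code{fold}, \code{sensitivity}, \code{auc}.
#' @return data.frame with columns \code{subject}, \code{n_folds},
#'   \code{sensitivity_mean}, \code{sensitivity_sd}, \code{auc_mean},
#'   \code{auc_sd}; the last row is the cohort average.
#' @export
aggregate_results <- function(results) {
  stopifnot(nrow(results) >= 1L,
            all(c("subject", "sensitivity", "auc") %in% names(results)))
  subjects <- unique(results$subject)
  rows <- lapply(subjects, function(s) {
    r <- results[results$subject == s, , drop = FALSE]
    data.frame(subject = s, n_folds = nrow(r),
               sensitivity_mean = mean(r$sensitivity),
               sensitivity_sd = sd0(r$sensitivity),
               auc_mean = mean(r$auc), auc_sd = sd0(r$auc))
  })
  tab <- do.call(rbind, rows)
  cohort <- data.frame(subject = "AVG", n_folds = sum(tab$n_folds),
                       sensitivity_mean = mean(tab$sensitivity_mean),
                       sensitivity_sd = sd0(tab$sensitivity_mean),
                       auc_mean = mean(tab$auc_mean),
                       auc_sd = sd0(tab$auc_mean))
  rbind(tab, cohort)
}

#' Train/test feature-distribution overlap report
#'
#' For every feature column, bins the pooled values into equal-width bins and
#' reports the histogram intersection of the normalized train and test
#' distributions: 1 for identical binned distributions, 0 for disjoint
#' supports. A compact view of the covariate drift that degrades fold
#' performance on non-stationary EEG.
#'
#' @param train_feats,test_feats numeric matrices with the same columns.
#' @param bins number of histogram bins.
#' @return data.frame with columns \code{feature}, \code{overlap}, plus the
#'   binned densities as attribute \code{"plot_data"}.
#' @export
feature_distribution_report <- function(train_feats, test_feats, bins = 30L) {
  train_feats <- as.matrix(train_feats); test_feats <- as.matrix(test_feats)
  if (ncol(train_feats) != ncol(test_feats)) stopf("feature dimensionality differs")
  nms <- colnames(train_feats) %||% paste0("f", seq_len(ncol(train_feats)))
  plot_data <- list()
  overlap <- numeric(ncol(train_feats))
  for (j in seq_len(ncol(train_feats))) {
    lo <- min(train_feats[, j], test_feats[, j])
    hi <- max(train_feats[, j], test_feats[, j])
    if (hi <= lo) { overlap[j] <- 1; next }
    brk <- seq(lo, hi, length.out = bins + 1L)
    h_tr <- hist(train_feats[, j], breaks = brk, plot = FALSE)$counts
    h_te <- hist(test_feats[, j], breaks = brk, plot = FALSE)$counts
    p_tr <- h_tr / sum(h_tr); p_te <- h_te / sum(h_te)
    overlap[j] <- sum(pmin(p_tr, p_te))
    plot_data[[nms[j]]] <- data.frame(mid = (brk[-1L] + brk[-length(brk)]) / 2,
                                      train = p_tr, test = p_te)
  }
  out <- data.frame(feature = nms, overlap = overlap)
  attr(out, "plot_data") <- plot_data
  out
}
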