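# Classifier evaluation under LOO / LOSO cross-validation.

feature_cols <- function(tbl) grep("^t\\d{2}$", names(tbl), value = TRUE)

#' Min-max normalization fitted on the training set only
#'
#' Per-feature minima and maxima are computed on the training rows alone;
#' both sets are mapped by `(x - min) / (max - min)` and test values are
#' clipped to `[0, 1]`, so no information flows from test to train. A
#' constant training feature is mapped to 0 (with a warning).
#'
#' @param train,test Feature tibbles sharing the `t01`-`t33` columns
#'   (`test` may be `NULL`).
#' @return A list with normalized `train`, `test`, and the fitted `ranges`.
#' @export
minmax_normalize <- function(train, test = NULL) {
  cols <- feature_cols(train)
  if (length(cols) == 0) {
    abort("no feature columns (t01-t33) found", class = "bcghf_invalid_argument")
  }
  lo <- vapply(train[cols], min, numeric(1))
  hi <- vapply(train[cols], max, numeric(1))
  flat <- hi - lo == 0
  if (any(flat)) {
    warn(sprintf("constant training feature(s) mapped to 0: %s",
                 paste(cols[flat], collapse = ", ")))
  }
  scale_tbl <- function(tbl, clip) {
    for (j in seq_along(cols)) {
      v <- tbl[[cols[j]]]
      v <- if (flat[j]) rep(0, length(v)) else (v - lo[j]) / (hi[j] - lo[j])
      if (clip) v <- pmin(pmax(v, 0), 1)
      tbl[[cols[j]]] <- v
    }
    tbl
  }
  list(train = scale_tbl(train, FALSE),
       test = if (!is.null(test)) scale_tbl(test, TRUE),
       ranges = tibble(feature = cols, min = lo, max = hi))
}

#' Cross-validation fold construction
#'
#' `loo_split()` leaves one epoch out per fold; `loso_split()` leaves all
#' epochs of one subject out per fold, so no subject ever appears on both
#' sides of a fold.
#'
#' @param tbl A feature tibble (`loso_split()` requires `subject_id`).
#' @return A list of integer vectors of test-row indices.
#' @export
loo_split <- function(tbl) {
  if (nrow(tbl) < 2) {
    abort("need at least 2 epochs", class = "bcghf_invalid_argument")
  }
  as.list(seq_len(nrow(tbl)))
}

#' @rdname loo_split
#' @export
loso_split <- function(tbl) {
  subjects <- unique(tbl$subject_id)
  if (length(subjects) < 2) {
    abort("need at least 2 subjects", class = "bcghf_invalid_argument")
  }
  lapply(subjects, function(s) which(tbl$subject_id == s))
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity, specificity and F1 from the confusion counts,
#' each in percent: `Acc = (TP + TN) / total`, `Sen = TP / (TP + FN)`,
#' `Spe = TN / (TN + FP)`, `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' @param tp,tn,fp,fn Confusion counts, or a single named vector/list as
#'   `tp`.
#' @return A tibble with `acc`, `sen`, `spe`, `f1` (percent).
#' @examples
#' compute_metrics(90, 85, 15, 10)
#' @export
compute_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && length(tp) == 4) {
    cc <- as.list(tp)
    tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  }
  total <- tp + tn + fp + fn
  if (total <= 0) abort("empty confusion matrix", class = "bcghf_invalid_argument")
  tibble(acc = 100 * (tp + tn) / total,
         sen = 100 * tp / (tp + fn),
         spe = 100 * tn / (tn + fp),
         f1 = 100 * 2 * tp / (2 * tp + fp + fn))
}

#' ROC curve and AUC from pooled scores
#'
#' The AUC is the Mann-Whitney probability that a positive scores above a
#' negative (ties counted half), equivalently the trapezoidal area under
#' the ROC curve over all score thresholds.
#'
#' @param scores Continuous classifier scores.
#' @param labels Binary labels (1 = positive).
#' @return A list with `auc` (percent) and `roc` (tibble of `fpr`, `tpr`,
#'   `threshold`).
#' @export
compute_roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both classes required for a ROC curve",
          class = "bcghf_invalid_argument")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  # one ROC point per distinct threshold
  last <- !duplicated(scores[ord], fromLast = TRUE)
  roc <- tibble(threshold = scores[ord][last],
                tpr = tp[last] / n1, fpr = fp[last] / n0)
  roc <- dplyr::bind_rows(tibble(threshold = Inf, tpr = 0, fpr = 0), roc)
  list(auc = 100 * auc, roc = roc)
}

#' Nonparametric per-feature group test
#'
#' Two-sided Wilcoxon rank-sum test of HF versus non-HF values of one
#' feature; being rank-based, the p-value is invariant to monotone
#' transforms of the feature.
#'
#' @param features A feature tibble with a binary `label` column.
#' @param feature Feature column name (e.g. `"t28"`).
#' @return The two-sided p-value.
#' @export
feature_group_test <- function(features, feature) {
  x <- features[[feature]][features$label == 1]
  y <- features[[feature]][features$label == 0]
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups required", class = "bcghf_invalid_argument")
  }
  suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
}

#' @rdname feature_group_test
#' @return `feature_group_tests()`: a tibble with one row per feature:
#'   group medians, effect direction and p-value.
#' @export
feature_group_tests <- function(features) {
  cols <- feature_cols(features)
  dplyr::bind_rows(purrr::map(cols, function(f) {
    mh <- median(features[[f]][features$label == 1])
    mn <- median(features[[f]][features$label == 0])
    tibble(feature = f, median_hf = mh, median_nonhf = mn,
           direction = ifelse(mh > mn, "hf_higher", "hf_lower"),
           p_value = feature_group_test(features, f))
  }))
}

#' Mean split-count feature importance across folds
#'
#' Averages the gradient-boosted model's split-count (weight) importance
#' over all cross-validation folds and normalizes the result to sum to 1.
#' When results from two protocols are supplied, the attribute `top_common`
#' holds the intersection of their top-k sets.
#'
#' @param cv A `hf_cv` result containing a gradient-boosted classifier.
#' @param cv2 Optional second `hf_cv` (e.g. the other protocol).
#' @param top_k Size of the top set (default 10).
#' @return A tibble of `feature`, `importance`, `rank` (for `cv`), with
#'   attributes `top` and, if `cv2` is given, `top_common`.
#' @export
rank_importance <- function(cv, cv2 = NULL, top_k = 10) {
  imp_of <- function(x) {
    row <- x$results[!purrr::map_lgl(x$results$importance, is.null), ]
    if (nrow(row) == 0) {
      abort("no gradient-boosted importance available in this result",
            class = "bcghf_invalid_argument")
    }
    row$importance[[1]]
  }
  imp <- imp_of(cv)
  out <- tibble(feature = names(imp), importance = as.numeric(imp))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  attr(out, "top") <- head(out$feature, top_k)
  if (!is.null(cv2)) {
    imp2 <- imp_of(cv2)
    top2 <- names(sort(imp2, decreasing = TRUE))[seq_len(top_k)]
    attr(out, "top_common") <- intersect(attr(out, "top"), top2)
  }
  out
}
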