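# broom-style tidiers and plotting for evaluation results.

#' Tidy a cross-validation result
#'
#' @param x A `hf_cv` object.
#' @param ... Unused.
#' @return One row per classifier with protocol and the five metrics
#'   (percent).
#' @exportS3Method generics::tidy
#' @export
tidy.hf_cv <- function(x, ...) {
  dplyr::select(x$results, "classifier", "protocol",
                "acc", "sen", "spe", "f1", "auc")
}

#' @rdname tidy.hf_cv
#' @return `glance()`: a one-row summary of the best classifier by accuracy.
#' @exportS3Method generics::glance
#' @export
glance.hf_cv <- function(x, ...) {
  best <- x$results[which.max(x$results$acc), ]
  tibble(protocol = x$protocol, n_epochs = x$n_epochs,
         n_subjects = x$n_subjects, best_classifier = best$classifier,
         acc = best$acc, auc = best$auc)
}

#' Plot ROC curves of a cross-validation result
#'
#' @param object A `hf_cv` object.
#' @param ... Unused.
#' @return A ggplot of pooled out-of-fold ROC curves, one per classifier.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.hf_cv <- function(object, ...) {
  roc <- tidyr::unnest(
    dplyr::select(object$results, "classifier", "roc"), "roc")
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr,
                                    colour = .data$classifier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL,
                  title = sprintf("Pooled %s ROC", toupper(object$protocol))) +
    ggplot2::theme_minimal()
}

#' Plot per-feature class contrasts
#'
#' Boxplots of selected features split by class, the standard companion to
#' the per-feature rank-sum tests.
#'
#' @param features A feature table with a `label` column.
#' @param which Feature columns to show (default: the cardiopulmonary set).
#' @return A ggplot object.
#' @export
plot_feature_contrast <- function(features, which = c("t01", "t27", "t28", "t33")) {
  long <- tidyr::pivot_longer(
    dplyr::select(features, "label", dplyr::all_of(which)),
    -"label", names_to = "feature")
  long$class <- ifelse(long$label == 1, "HF", "non-HF")
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$value,
                                     fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot feature importance
#'
#' @param importance A tibble from [rank_importance()].
#' @param top_n Number of leading features to show.
#' @return A ggplot bar chart of mean normalized importance.
#' @export
plot_importance <- function(importance, top_n = 15) {
  d <- head(importance, top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(.data$importance, .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean split-count importance (normalized)", y = NULL) +
    ggplot2::theme_minimal()
}
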