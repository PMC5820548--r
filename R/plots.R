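#' Plot a ROC curve
#'
#' @param x An `eval_report` from [cross_validate()].
#' @param ... Ignored.
#' @return A ggplot object: sensitivity against 1 - specificity with the
#'   chance diagonal, AUC in the subtitle.
#' @export
autoplot.eval_report <- function(x, ...) {
  ggplot2::ggplot(x$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC, %s (%d-fold CV)", x$config$classifier, x$config$folds),
      subtitle = sprintf("AUC = %.3f", x$pooled$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the forward-selection accuracy curve
#'
#' @param x An `sfs_trace` from [sfs_select()].
#' @param ... Ignored.
#' @return A ggplot of cross-validated accuracy against the number of
#'   features added, with the selected prefix marked.
#' @export
autoplot.sfs_trace <- function(x, ...) {
  sel <- attr(x, "selected_size")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$step, y = .data$cv_accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = sel, linetype = "dotted", colour = "red") +
    ggplot2::annotate(
      "text", x = sel, y = min(x$cv_accuracy), hjust = -0.1, vjust = 0,
      label = sprintf("selected: %d features", sel), colour = "red", size = 3
    ) +
    ggplot2::labs(
      x = "Number of features", y = "Cross-validated accuracy",
      title = "Sequential forward selection"
    ) +
    ggplot2::theme_minimal()
}

#' Plot ReliefF scores
#'
#' @param x A `relief_ranking` from [relief_scores()].
#' @param top Show at most this many top-ranked features (default 30).
#' @param ... Ignored.
#' @return A ggplot bar chart of scores, retained features highlighted.
#' @export
autoplot.relief_ranking <- function(x, top = 30, ...) {
  d <- utils::head(dplyr::arrange(x, .data$rank), top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$feature, fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70")) +
    ggplot2::labs(
      x = "ReliefF score", y = NULL,
      title = sprintf("ReliefF ranking (top %d of %d)", nrow(d), nrow(x))
    ) +
    ggplot2::theme_minimal()
}

#' Compare classifier ROC curves
#'
#' @param comparison Result of [compare_classifiers()].
#' @return A ggplot overlaying the ROC of every compared classifier, AUC
#'   in the legend.
#' @export
plot_roc_comparison <- function(comparison) {
  reports <- attr(comparison, "reports")
  if (is.null(reports)) abort("comparison lacks attached eval reports")
  d <- dplyr::bind_rows(lapply(names(reports), function(nm) {
    r <- reports[[nm]]$roc
    r$classifier <- sprintf("%s (AUC %.3f)", nm, reports[[nm]]$pooled$auc)
    r
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$classifier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
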