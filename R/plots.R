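#' Plot an ROC curve
#'
#' Standard ROC figure: true-positive rate against false-positive rate
#' (1 - specificity) with the chance diagonal and the AUC in the subtitle.
#'
#' @param object A `roc_curve`.
#' @param operating_point Optional `operating_point` to mark on the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, operating_point = NULL, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object), fpr = 1 - .data$specificity)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)",
      y = "Sensitivity",
      title = "Cross-validated ROC",
      subtitle = sprintf("AUC = %.3f", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(operating_point)) {
    op <- dplyr::mutate(operating_point, fpr = 1 - .data$specificity)
    p <- p + ggplot2::geom_point(data = op, colour = "red", size = 2)
  }
  p
}

#' Plot a confusion matrix
#'
#' Two-by-two tile plot of the counts behind an operating point or
#' confusion summary.
#'
#' @param object An `operating_point` (from [balanced_operating_point()]
#'   or [confusion_summary()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot operating_point
#' @export
autoplot.operating_point <- function(object, ...) {
  df <- tibble::tibble(
    truth = factor(c("Impaired", "Impaired", "Typical", "Typical"),
                   levels = c("Impaired", "Typical")),
    predicted = factor(c("Impaired", "Typical", "Impaired", "Typical"),
                       levels = c("Impaired", "Typical")),
    count = c(object$tp, object$fn, object$fp, object$tn)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", guide = "none") +
    ggplot2::labs(x = "Predicted", y = "Observed",
                  title = "Balanced confusion matrix") +
    ggplot2::theme_minimal()
}

#' Plot retained subsets of an exhaustive search
#'
#' Cross-validated against apparent score for each retained subset, making
#' the optimism gap visible.
#'
#' @param object A `subset_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot subset_search
#' @export
autoplot.subset_search <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object[c("rank", "label", "cv_score", "apparent_score")]),
    cols = c("cv_score", "apparent_score"),
    names_to = "score", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   y = stats::reorder(.data$label, -.data$rank),
                                   colour = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = attr(object, "score_type"), y = NULL,
                  colour = NULL, title = "Top feature subsets") +
    ggplot2::theme_minimal()
}

#' Plot a permutation-null distribution
#'
#' Histogram of null best scores with the observed best score marked.
#'
#' @param object A `permutation_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot permutation_null
#' @export
autoplot.permutation_null <- function(object, ...) {
  df <- tibble::tibble(score = object$null_scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "Best CV score under permuted outcomes", y = "Count",
                  title = "Selection-optimism null",
                  subtitle = sprintf("observed %.3f, p = %.3f",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}
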