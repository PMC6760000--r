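#' ROC curve from pooled held-out scores
#'
#' Builds the receiver operating characteristic of `scores` against binary
#' `labels` under the rule "predict positive when score >= threshold",
#' with higher scores meaning higher risk. Thresholds are the unique scores
#' in descending order, preceded by a `+Inf` sentinel (nothing predicted
#' positive), so the curve always contains the endpoints
#' (sensitivity 0, specificity 1) and (sensitivity 1, specificity 0).
#' The stored AUC is the trapezoidal area, which equals the Mann-Whitney
#' AUC with midrank ties.
#'
#' @param labels 0/1 labels (or an `impairment_labels` tibble); both
#'   classes must be present.
#' @param scores Numeric risk scores, one per label.
#' @return A `roc_curve` tibble with columns `threshold`, `sensitivity`,
#'   `specificity`, `tp`, `fp`, `tn`, `fn`, and an `auc` attribute.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as_label_vector(labels)
  scores <- as.numeric(scores)
  if (length(labels) != length(scores)) abort("labels and scores differ in length.")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) abort("ROC needs both classes present.")
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tp <- vapply(thresholds, function(t) sum(scores >= t & labels == 1L), 0)
  fp <- vapply(thresholds, function(t) sum(scores >= t & labels == 0L), 0)
  sens <- tp / n_pos
  spec <- (n_neg - fp) / n_neg
  fpr <- fp / n_neg
  auc <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
  structure(
    tibble::tibble(threshold = thresholds, sensitivity = sens,
                   specificity = spec, tp = tp, fp = fp,
                   tn = n_neg - fp, fn = n_pos - tp),
    class = c("roc_curve", class(tibble::tibble())),
    auc = auc, n_pos = n_pos, n_neg = n_neg
  )
}

#' @rdname roc_curve
#' @param curve A `roc_curve`.
#' @return `roc_auc()`: the trapezoidal AUC of the curve.
#' @export
roc_auc <- function(curve) attr(curve, "auc")

#' Balanced operating point of an ROC curve
#'
#' Selects the threshold maximizing `sensitivity^2 + specificity^2`, the
#' balanced criterion used to pick a single sensitivity/specificity pair
#' from the cross-validated curve. Ties are broken toward higher
#' sensitivity (a screening application should not miss impaired
#' subjects), then higher specificity, then higher threshold.
#'
#' @param curve A [roc_curve()].
#' @return An `operating_point`: a one-row tibble with `threshold`,
#'   `sensitivity`, `specificity`, confusion counts `tp`, `fp`, `tn`,
#'   `fn`, and the achieved `objective`.
#' @export
balanced_operating_point <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  obj <- curve$sensitivity^2 + curve$specificity^2
  ord <- order(-obj, -curve$sensitivity, -curve$specificity, -curve$threshold)
  best <- curve[ord[1L], ]
  structure(
    tibble::tibble(
      threshold = best$threshold, sensitivity = best$sensitivity,
      specificity = best$specificity, tp = best$tp, fp = best$fp,
      tn = best$tn, fn = best$fn, objective = obj[ord[1L]]
    ),
    class = c("operating_point", class(tibble::tibble()))
  )
}

#' Confusion counts and rates for binary predictions
#'
#' Tabulates predicted against true labels and reports sensitivity
#' (TP / positives) and specificity (TN / negatives), both as proportions
#' and as whole percents rounded half-up (the convention used in the
#' formatted reports). With no positives, sensitivity is `NaN` with a
#' warning (symmetrically for specificity).
#'
#' @param labels True 0/1 labels (or an `impairment_labels` tibble).
#' @param predicted Predicted 0/1 labels of the same length.
#' @return An `operating_point`-style one-row tibble with counts, rates,
#'   percent columns `sensitivity_pct` / `specificity_pct`, and `"a/b"`
#'   fraction strings `true_pos_frac` / `false_pos_frac`.
#' @export
confusion_summary <- function(labels, predicted) {
  labels <- as_label_vector(labels)
  predicted <- as_label_vector(predicted)
  if (length(labels) != length(predicted)) abort("labels and predicted differ in length.")
  tp <- sum(predicted == 1L & labels == 1L)
  fp <- sum(predicted == 1L & labels == 0L)
  tn <- sum(predicted == 0L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  n_pos <- tp + fn
  n_neg <- tn + fp
  if (n_pos == 0) warn("No positive labels: sensitivity is undefined (NaN).")
  if (n_neg == 0) warn("No negative labels: specificity is undefined (NaN).")
  sens <- if (n_pos == 0) NaN else tp / n_pos
  spec <- if (n_neg == 0) NaN else tn / n_neg
  structure(
    tibble::tibble(
      tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = sens, specificity = spec,
      sensitivity_pct = round_half_up(100 * sens, 0),
      specificity_pct = round_half_up(100 * spec, 0),
      true_pos_frac = fmt_fraction(tp, n_pos),
      false_pos_frac = fmt_fraction(fp, n_neg)
    ),
    class = c("operating_point", class(tibble::tibble()))
  )
}

# Half-up rounding (the tables' convention; R's round() is half-even).
# A tiny epsilon guards values like 0.895 that sit just below the decimal
# midpoint in binary.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  out <- sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
  out[is.nan(x)] <- NaN
  out
}

fmt_fraction <- function(a, b) paste0(a, "/", b)

# Fixed-decimal formatting with half-up rounding, for report tables.
fmt_round <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' @rdname roc_curve
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return `tidy()`: the vertex tibble; `glance()`: a one-row tibble with
#'   `auc`, `n_pos`, `n_neg`.
#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) tibble::as_tibble(x)

#' @rdname roc_curve
#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"),
                 n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg"))
}

#' Export ROC vertices in figure-ready coordinates
#'
#' Writes the curve as delimited text with specificity inverted to a
#' false-positive rate, ready to plot as an ROC figure.
#'
#' @param curve A `roc_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(curve, path) {
  out <- dplyr::mutate(tibble::as_tibble(curve),
                       false_positive_rate = 1 - .data$specificity)
  readr::write_csv(out, path)
  invisible(path)
}
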