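#' Cross-tabulate a single binary MRI finding against impairment
#'
#' Treats the radiological flag itself as the prediction and reports the
#' true-positive and false-positive fractions in the `"a/b"` format used
#' by the comparison tables (detected impaired / all impaired, and flagged
#' unimpaired / all unimpaired).
#'
#' @param finding Per-subject 0/1 flag.
#' @param labels 0/1 impairment labels (or an `impairment_labels` tibble).
#' @return The [confusion_summary()] one-row tibble.
#' @export
crosstab_binary_predictor <- function(finding, labels) {
  confusion_summary(labels, finding)
}

#' LOOCV logistic screen on structural-MRI findings
#'
#' Fits an L2-penalized logistic model on all binary findings jointly,
#' scores it with leave-one-out cross-validation, and selects the balanced
#' operating point — exactly the machinery used for the DTI arm
#' ([loocv_predict()], [cv_auc()], [roc_curve()],
#' [balanced_operating_point()]), so a performance gap between the arms is
#' attributable to the inputs, not the method. Findings enter
#' unstandardized: z-scoring 0/1 flags changes nothing material and harms
#' interpretability.
#'
#' @param findings Data frame of named 0/1 columns (>= 2 findings); a
#'   `subject_id` column, if present, is dropped.
#' @param labels 0/1 impairment labels; both classes must be present.
#' @param spec A logistic [penalty_spec()] (default L2 strength 1.0).
#' @return An `mri_screen` list: `fit` (full-sample refit), `loocv`,
#'   `cv_auc` and `apparent_auc` score rows, `roc` and the balanced
#'   `operating_point`.
#' @export
mri_logistic_screen <- function(findings, labels, spec = penalty_spec("logistic")) {
  findings <- tibble::as_tibble(findings)
  findings$subject_id <- NULL
  if (ncol(findings) < 2) abort("The MRI screen needs at least 2 findings columns.")
  x <- as.matrix(findings)
  labels <- as_label_vector(labels)
  if (length(unique(labels)) < 2) {
    abort("Impairment labels are single-class: the screen is undefined.",
          class = "gaitdti_single_class")
  }
  cv <- loocv_predict(x, labels, spec)
  app <- apparent_score(x, labels, spec)
  curve <- roc_curve(labels, cv$prediction)
  structure(
    list(
      fit = app$fit,
      loocv = cv,
      cv_auc = cv_auc(cv, labels),
      apparent_auc = app$score,
      roc = curve,
      operating_point = balanced_operating_point(curve)
    ),
    class = "mri_screen"
  )
}

#' @export
print.mri_screen <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf(
    "Structural-MRI logistic screen (%d findings, n = %d):\n  CV AUC %.3f (apparent %.3f); balanced sens %.2f, spec %.2f\n",
    length(x$fit$coefficients), x$fit$nobs,
    x$cv_auc$value, x$apparent_auc$value, op$sensitivity, op$specificity
  ))
  invisible(x)
}

#' Comparison table of DTI models and single MRI findings
#'
#' Builds the table comparing, for one outcome, the DTI logistic model
#' without and with cross-validation (each at its balanced operating
#' point) against every single structural-MRI finding used as a direct
#' classifier. Fractions are `"a/b"` strings: true positives over all
#' impaired, false positives over all unimpaired.
#'
#' @param findings Data frame of 0/1 finding columns (plus optional
#'   `subject_id`).
#' @param labels 0/1 impairment labels.
#' @param dti_search A logistic `subset_search` for the same outcome (its
#'   winner supplies the DTI rows); optional.
#' @param outcome Outcome name for the column header.
#' @return A tibble with columns `method`, `true_pos`, `false_pos`
#'   (prefixed by the outcome name when given).
#' @export
compare_mri <- function(findings, labels, dti_search = NULL, outcome = NULL) {
  findings <- tibble::as_tibble(findings)
  findings$subject_id <- NULL
  labels <- as_label_vector(labels)
  rows <- list()
  if (!is.null(dti_search)) {
    stopifnot(inherits(dti_search, "subset_search"))
    rows <- c(rows, list(
      dti_confusion_row("DTI logistic regression", dti_search, labels, cv = FALSE),
      dti_confusion_row("DTI logistic regression with cross-validation",
                        dti_search, labels, cv = TRUE)
    ))
  }
  for (f in names(findings)) {
    cs <- crosstab_binary_predictor(findings[[f]], labels)
    rows <- c(rows, list(tibble::tibble(
      method = f, true_pos = cs$true_pos_frac, false_pos = cs$false_pos_frac
    )))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(outcome)) {
    names(out)[2:3] <- paste0(outcome, c("_true_pos", "_false_pos"))
  }
  out
}

# Confusion row for the DTI winner at its balanced operating point, from
# apparent or cross-validated probabilities (recomputed from the stored
# winner, never from report-only numbers).
dti_confusion_row <- function(method, dti_search, labels, cv) {
  scores <- winner_scores(dti_search, labels, cv = cv)
  curve <- roc_curve(labels, scores)
  op <- balanced_operating_point(curve)
  cs <- confusion_summary(labels, as.integer(scores >= op$threshold))
  tibble::tibble(method = method, true_pos = cs$true_pos_frac,
                 false_pos = cs$false_pos_frac)
}

# Held-out or apparent probabilities of a logistic search winner,
# recomputed from the design the search stored.
winner_scores <- function(dti_search, labels, cv) {
  x <- attr(dti_search, "design")
  if (is.null(x)) abort("This search did not retain its design.")
  cols <- dti_search$features[[1]]
  spec <- attr(dti_search, "spec")
  if (cv) {
    loocv_predict(x[, cols, drop = FALSE], labels, spec,
                  scope = attr(dti_search, "scope"))$prediction
  } else {
    predict(dti_search$fit[[1]], x[, cols, drop = FALSE])
  }
}
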