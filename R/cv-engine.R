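#' Leave-one-out cross-validated predictions
#'
#' Fits n models, each excluding one subject, and predicts the excluded
#' subject from the model that never saw it. With
#' `scope = "per_training_fold"` the standardization parameters (mean and
#' population SD) are recomputed on the n - 1 training rows and applied to
#' the held-out row, so no preprocessing information leaks across the fold
#' boundary; with `scope = "global"` the design is used as given (the
#' caller is assumed to have preprocessed it once on the full sample).
#'
#' A logistic training fold that loses one class entirely (possible when a
#' class has a single member) predicts the training-fold prevalence for its
#' held-out subject and is flagged `degenerate` rather than aborting.
#'
#' For the linear task with a fixed global penalty the engine uses the
#' exact leave-one-out identity for penalized linear smoothers
#' (`e_i / (1 - h_ii)` on the penalized hat matrix), which is algebraically
#' identical to n refits; all other cases refit explicitly per fold.
#'
#' @param x Design matrix or data frame of the selected features.
#' @param y Numeric response (linear) or 0/1 labels (logistic); an
#'   `impairment_labels` tibble is accepted for logistic.
#' @param spec A [penalty_spec()].
#' @param scope Preprocessing scope, `"global"` (default) or
#'   `"per_training_fold"`.
#' @return A `loocv_result` tibble with columns `row`, `prediction`
#'   (held-out fitted value or probability), `converged`, `degenerate`,
#'   and attributes `n`, `p`, `task`.
#' @export
loocv_predict <- function(x, y, spec = penalty_spec("linear"),
                          scope = c("global", "per_training_fold")) {
  scope <- match.arg(scope)
  x <- as_design(x)
  n <- nrow(x)
  if (n < 3) abort("LOOCV needs at least 3 subjects.")
  if (spec$task == "logistic") y <- as_label_vector(y) else y <- as.numeric(y)
  if (length(y) != n) abort("Response length must match rows of the design.")

  if (spec$task == "linear" && scope == "global" && !spec$scale_by_n) {
    pred <- tryCatch(loocv_linear_exact(x, y, spec), error = function(e) NULL)
    if (!is.null(pred)) {
      return(new_loocv(pred, rep(TRUE, n), rep(FALSE, n), n, ncol(x), "linear"))
    }
  }

  pred <- numeric(n)
  conv <- logical(n)
  degen <- logical(n)
  warm <- NULL
  if (spec$task == "logistic" && length(unique(y)) == 2) {
    full <- suppressWarnings(fit_l2_logistic(x, y, spec))
    warm <- c(full$intercept, full$coefficients)
  }
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    xte <- x[i, , drop = FALSE]
    if (scope == "per_training_fold") {
      mu <- colMeans(xtr)
      sigma <- sqrt(colMeans(sweep(xtr, 2, mu)^2))
      if (any(sigma == 0)) abort("Constant feature column inside a training fold.")
      xtr <- sweep(sweep(xtr, 2, mu), 2, sigma, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sigma, "/")
    }
    if (spec$task == "linear") {
      fit <- fit_ridge(xtr, ytr, spec)
      pred[i] <- predict(fit, xte)
      conv[i] <- TRUE
    } else {
      if (length(unique(ytr)) < 2) {
        pred[i] <- mean(ytr)
        conv[i] <- TRUE
        degen[i] <- TRUE
      } else {
        fit <- suppressWarnings(fit_l2_logistic(xtr, ytr, spec, init = warm))
        pred[i] <- predict(fit, xte)
        conv[i] <- fit$converged
      }
    }
  }
  if (any(degen)) {
    inform(sprintf(
      "%d LOOCV fold(s) had single-class training labels; predicted the training prevalence.",
      sum(degen)
    ))
  }
  new_loocv(pred, conv, degen, n, ncol(x), spec$task)
}

new_loocv <- function(pred, conv, degen, n, p, task) {
  structure(
    tibble::tibble(row = seq_len(n), prediction = pred,
                   converged = conv, degenerate = degen),
    class = c("loocv_result", class(tibble::tibble())),
    n = n, p = p, task = task
  )
}

# Exact LOO predictions for penalized least squares with fixed penalty:
# yhat_{-i} = (yhat_i - h_ii y_i) / (1 - h_ii), h the penalized hat matrix
# of the augmented design with unpenalized intercept. Errors out (caught by
# the caller, which falls back to naive refits) when a leverage reaches 1.
loocv_linear_exact <- function(x, y, spec) {
  n <- nrow(x)
  lam <- effective_lambda(spec, n)
  A <- cbind(1, x)
  pen <- c(if (spec$penalize_intercept) lam else 0, rep(lam, ncol(x)))
  M <- crossprod(A)
  diag(M) <- diag(M) + pen
  Minv_At <- solve(M, t(A))
  h <- colSums(t(A) * Minv_At)
  if (any(1 - h < 1e-10)) abort("Leverage ~ 1; exact LOO identity unstable.")
  yhat <- drop(A %*% (Minv_At %*% y))
  (yhat - h * y) / (1 - h)
}

new_score <- function(type, value, n, p) {
  tibble::tibble(score_type = type, value = value, n = n, p = p)
}

# Pooled R^2 and its small-sample adjustment.
r2_pooled <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) abort("Response is constant: R^2 is undefined (SST = 0).")
  1 - sum((y - yhat)^2) / sst
}

#' Adjusted coefficient of determination
#'
#' `adjusted_r2()` applies the standard small-sample adjustment
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` with `p` the number of features
#' (the intercept is not counted). `cv_adjusted_r2()` computes R^2 from the
#' pooled held-out residuals of a leave-one-out result (a single R^2 over
#' all n held-out predictions, not a per-fold average) and then adjusts.
#'
#' @param r2 An unadjusted R^2.
#' @param n Number of subjects.
#' @param p Number of features in the design.
#' @return `adjusted_r2()`: a number (at most 1, possibly negative).
#'   `cv_adjusted_r2()`: a one-row score tibble with `score_type`
#'   `"cv_adjusted_r2"`, `value`, `n`, `p`.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) abort("Adjusted R^2 needs n > p + 1.")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' @rdname adjusted_r2
#' @param loocv A `loocv_result` from [loocv_predict()].
#' @param y The observed continuous response, in subject order.
#' @export
cv_adjusted_r2 <- function(loocv, y) {
  n <- attr(loocv, "n")
  p <- attr(loocv, "p")
  y <- as.numeric(y)
  if (length(y) != n) abort("Response length must match the LOOCV result.")
  new_score("cv_adjusted_r2", adjusted_r2(r2_pooled(y, loocv$prediction), n, p), n, p)
}

# Mann-Whitney AUC with midrank tie handling (equivalent to trapezoidal
# ROC integration).
auc_mann_whitney <- function(labels, scores) {
  labels <- as_label_vector(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated ROC AUC from pooled held-out probabilities
#'
#' The AUC of the pooled held-out scores against the true labels, computed
#' as the Mann-Whitney statistic with ties counted one half (identical to
#' trapezoidal integration of the ROC curve).
#'
#' @param loocv A `loocv_result` from a logistic [loocv_predict()].
#' @param labels 0/1 labels (or an `impairment_labels` tibble), in subject
#'   order; both classes must be present.
#' @return A one-row score tibble with `score_type` `"cv_auc"`, `value` in
#'   \[0, 1\], `n`, `p`.
#' @export
cv_auc <- function(loocv, labels) {
  labels <- as_label_vector(labels)
  n <- attr(loocv, "n")
  if (length(labels) != n) abort("Labels length must match the LOOCV result.")
  new_score("cv_auc", auc_mann_whitney(labels, loocv$prediction), n, attr(loocv, "p"))
}

# Apparent (same-data) scores from a full-sample fit, for the optimism
# comparison the reports make.
apparent_score <- function(x, y, spec) {
  x <- as_design(x)
  n <- nrow(x)
  p <- ncol(x)
  if (spec$task == "linear") {
    fit <- fit_ridge(x, y, spec)
    yhat <- predict(fit, x)
    list(fit = fit,
         score = new_score("apparent_adjusted_r2",
                           adjusted_r2(r2_pooled(as.numeric(y), yhat), n, p), n, p),
         predictions = yhat)
  } else {
    labels <- as_label_vector(y)
    fit <- suppressWarnings(fit_l2_logistic(x, labels, spec))
    prob <- predict(fit, x)
    list(fit = fit,
         score = new_score("apparent_auc", auc_mann_whitney(labels, prob), n, p),
         predictions = prob)
  }
}
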