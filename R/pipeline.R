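#' Simulate a cohort and write it to disk
#'
#' Convenience driver: [generate_cohort()] followed by [write_cohort()].
#'
#' @param config A [cohort_config()].
#' @param dir Output directory.
#' @param null Generate a null cohort (outcome independent of features).
#' @return The `synthetic_cohort`, invisibly.
#' @export
simulate_cohort <- function(config, dir, null = FALSE) {
  cohort <- if (null) generate_null_cohort(config) else generate_cohort(config)
  write_cohort(cohort, dir)
  invisible(cohort)
}

#' Run the full search pipeline for one gait outcome
#'
#' Preprocesses the feature table (scan-age residualization, then
#' standardization, both on the full sample by default), derives
#' impairment labels when a normative reference is given, runs the
#' exhaustive subset search, and — for the logistic task — builds the
#' cross-validated ROC of the winning subset and its balanced operating
#' point. Optionally writes every artifact (full-precision results,
#' formatted report, LOOCV predictions, ROC vertices, confusion counts)
#' as delimited text under `dir`, so every report number can be re-derived
#' from saved raw artifacts.
#'
#' @param features A feature table (e.g. from [read_feature_table()] or
#'   the synthetic generator).
#' @param outcome Numeric outcome values in subject order, or a tibble
#'   with `subject_id` and a column named after `reference$outcome`.
#' @param task `"linear"` (continuous outcome) or `"logistic"`
#'   (impairment classification; requires `reference`).
#' @param reference A [normative_reference()]; required for the logistic
#'   task.
#' @param k Subset size (default 3).
#' @param spec A [penalty_spec()]; defaults to L2 strength 1.0 for the
#'   task.
#' @param scope Preprocessing scope passed to [standardize_features()]
#'   (default `"global"`, matching a single whole-sample preprocessing
#'   pass; `"per_training_fold"` avoids CV leakage).
#' @param top_t,chunk_size,checkpoint,verbose Passed to
#'   [search_feature_sets()].
#' @param dir Optional output directory for report artifacts.
#' @return A `gait_search_report` list: `search` (the `subset_search`),
#'   `report` (formatted winner rows), `cv_predictions`, and for the
#'   logistic task `labels`, `roc`, `operating_point`, `confusion`.
#' @export
run_gait_search <- function(features, outcome,
                            task = c("linear", "logistic"),
                            reference = NULL, k = 3, spec = NULL,
                            scope = c("global", "per_training_fold"),
                            top_t = 10, chunk_size = 10000,
                            checkpoint = NULL, verbose = FALSE,
                            dir = NULL) {
  task <- match.arg(task)
  scope <- match.arg(scope)
  spec <- spec %||% penalty_spec(task)

  if (is.data.frame(outcome)) {
    if (is.null(reference)) {
      abort("Pass 'reference' (or a numeric vector) so the outcome column is identifiable.")
    }
    outcome <- align_by_subject(outcome, features$subject_id)[[reference$outcome]]
  }
  prep <- features |>
    residualize_pma() |>
    standardize_features(scope = scope)

  labels <- NULL
  response <- outcome
  if (task == "logistic") {
    if (is.null(reference)) abort("The logistic task needs a normative reference.")
    labels <- label_impairment(outcome, reference)
    response <- labels$impaired
  }

  search <- search_feature_sets(prep, response, task = task, k = k, spec = spec,
                                top_t = top_t, chunk_size = chunk_size,
                                checkpoint = checkpoint, verbose = verbose)
  if (inherits(search, "subset_search_checkpoint")) return(search)

  x <- attr(search, "design")
  cols <- search$features[[1]]
  cv <- loocv_predict(x[, cols, drop = FALSE], response, spec, scope = scope)
  out <- list(
    task = task,
    search = search,
    report = make_report_row(search),
    cv_predictions = tibble::tibble(
      subject_id = features$subject_id,
      observed = response,
      cv_prediction = cv$prediction
    )
  )
  if (task == "logistic") {
    out$labels <- labels
    out$roc <- roc_curve(response, cv$prediction)
    out$operating_point <- balanced_operating_point(out$roc)
    out$confusion <- confusion_summary(
      response, as.integer(cv$prediction >= out$operating_point$threshold)
    )
  }
  class(out) <- "gait_search_report"

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_search_results(search, file.path(dir, "search_results.csv"))
    readr::write_csv(out$report, file.path(dir, "report.csv"))
    readr::write_csv(out$cv_predictions, file.path(dir, "loocv_predictions.csv"))
    if (task == "logistic") {
      write_roc(out$roc, file.path(dir, "roc.csv"))
      readr::write_csv(tibble::as_tibble(out$confusion), file.path(dir, "confusion.csv"))
    }
  }
  out
}

#' @export
print.gait_search_report <- function(x, ...) {
  g <- glance(x$search)
  cat(sprintf("Gait %s search over %s subsets (n = %d, k = %d)\n",
              x$task, format(g$subsets_scored, big.mark = ","), g$n, g$k))
  cat(sprintf("Winner: %s\n  CV %s = %.3f (apparent %.3f)\n",
              g$winner, attr(x$search, "score_type"), g$cv_score, g$apparent_score))
  if (!is.null(x$operating_point)) {
    cat(sprintf("  Balanced operating point: sensitivity %.2f, specificity %.2f (%s true+, %s false+)\n",
                x$operating_point$sensitivity, x$operating_point$specificity,
                x$confusion$true_pos_frac, x$confusion$false_pos_frac))
  }
  invisible(x)
}

align_by_subject <- function(tbl, subject_ids) {
  if (!"subject_id" %in% names(tbl)) return(tbl)
  idx <- match(subject_ids, tbl$subject_id)
  if (anyNA(idx)) abort("Outcome table is missing some subjects of the feature table.")
  tbl[idx, , drop = FALSE]
}

#' Permutation-null diagnostic for the selected best subset
#'
#' Re-runs the exhaustive search on copies of the data whose outcome has
#' been randomly permuted, giving the null distribution of the best
#' cross-validated score under "no association". Because the best score is
#' a maximum over all subsets, it is optimistically biased; this
#' diagnostic shows how large that selection optimism is and where the
#' real score ranks against it.
#'
#' @inheritParams run_gait_search
#' @param n_permutations Number of permutations (a warning below 10).
#' @param seed Seed for the permutation stream.
#' @return A `permutation_null` list: `observed` (real best CV score),
#'   `null_scores`, `exceedances` (null >= observed) and the one-sided
#'   p-value `(1 + exceedances) / (1 + n_permutations)`.
#' @export
permutation_null <- function(features, outcome,
                             task = c("linear", "logistic"),
                             reference = NULL, k = 3, spec = NULL,
                             scope = c("global", "per_training_fold"),
                             n_permutations = 20, seed = 1) {
  task <- match.arg(task)
  scope <- match.arg(scope)
  spec <- spec %||% penalty_spec(task)
  if (n_permutations < 10) warn("Fewer than 10 permutations gives a very coarse null.")

  real <- run_gait_search(features, outcome, task = task, reference = reference,
                          k = k, spec = spec, scope = scope, top_t = 1)
  response <- if (task == "logistic") real$labels$impaired else real$cv_predictions$observed
  prep <- features |>
    residualize_pma() |>
    standardize_features(scope = scope)

  set.seed(seed)
  perms <- replicate(n_permutations, sample(length(response)), simplify = FALSE)
  null_scores <- vapply(perms, function(p) {
    res <- search_feature_sets(prep, response[p], task = task, k = k,
                               spec = spec, top_t = 1)
    res$cv_score[1]
  }, 0)
  observed <- real$search$cv_score[1]
  exceed <- sum(null_scores >= observed)
  structure(
    list(observed = observed, null_scores = null_scores,
         exceedances = exceed,
         p_value = (1 + exceed) / (1 + n_permutations),
         task = task, n_permutations = n_permutations),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "Permutation null of the best CV score (%d permutations):\n  observed %.3f; null median %.3f; %d exceedance(s); p = %.3f\n",
    x$n_permutations, x$observed, stats::median(x$null_scores),
    x$exceedances, x$p_value
  ))
  invisible(x)
}
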