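#' Count and enumerate k-feature subsets
#'
#' Subsets are enumerated in lexicographic order over the canonical
#' feature order, each exactly once, so the stream is deterministic and
#' restartable from any rank. `n_feature_sets()` gives the total count
#' `choose(m, k)` without enumerating.
#'
#' @param features Character vector of feature identifiers, in canonical
#'   order.
#' @param k Subset size (default 3); must satisfy `k <= length(features)`.
#' @param from,to Rank range to emit (1-based, inclusive); defaults to the
#'   full stream.
#' @return A character matrix with one row per subset and `k` columns.
#' @export
#' @examples
#' enumerate_feature_sets(c("a", "b", "c", "d"), 3)
enumerate_feature_sets <- function(features, k = 3, from = 1, to = NULL) {
  m <- length(features)
  if (k > m) abort(sprintf("k = %d exceeds the %d available features.", k, m))
  total <- n_feature_sets(m, k)
  to <- to %||% total
  if (from < 1 || to > total || from > to) abort("Invalid rank range.")
  idx <- t(vapply(seq(from, to), comb_unrank, integer(k), m = m, k = k))
  matrix(features[idx], ncol = k,
         dimnames = list(NULL, paste0("feature_", seq_len(k))))
}

#' @rdname enumerate_feature_sets
#' @param m Number of features.
#' @export
n_feature_sets <- function(m, k) choose(m, k)

# parse_feature_id that tolerates plain (non "region:metric") names, for
# report formatting of arbitrary designs.
parse_feature_lenient <- function(feature) {
  has_colon <- grepl(":", feature, fixed = TRUE)
  tibble::tibble(
    feature = feature,
    region = ifelse(has_colon, sub(":[^:]*$", "", feature), feature),
    metric = ifelse(has_colon, sub("^.*:", "", feature), NA_character_)
  )
}

# Unrank the r-th (1-based) lexicographic k-combination of 1..m.
comb_unrank <- function(r, m, k) {
  out <- integer(k)
  a <- 1L
  for (j in seq_len(k)) {
    repeat {
      cnt <- choose(m - a, k - j)
      if (r <= cnt) break
      r <- r - cnt
      a <- a + 1L
    }
    out[j] <- a
    a <- a + 1L
  }
  out
}

#' Exhaustive best-subset search scored by leave-one-out cross-validation
#'
#' Enumerates every k-feature subset of the table's features, scores each
#' by the task's cross-validated criterion — pooled CV adjusted R^2 for
#' linear regression, pooled CV ROC-AUC for logistic classification — and
#' returns the `top_t` subsets with apparent (same-data) scores and a
#' full-sample refit whose coefficients are the reportable model. The
#' winner's CV score is maximal over all `choose(m, k)` subsets; exact
#' score ties are broken by lexicographic feature order, so the ranking is
#' fully deterministic.
#'
#' Enumeration is chunked; with a `checkpoint` path the chunk index and the
#' best-so-far buffer are persisted after every chunk, and an interrupted
#' run (see `max_chunks`) resumes from the checkpoint to a result
#' identical to an uninterrupted run. A logistic subset whose evaluation
#' fails entirely (e.g. all folds degenerate) is scored `-Inf` with the
#' reason logged.
#'
#' @param data A feature table (as from [as_feature_table()] or the
#'   synthetic generator), or a plain matrix/data frame of features.
#'   Preprocess first ([residualize_pma()], [standardize_features()]); a
#'   `standardized = "per_training_fold"` attribute makes the CV engine
#'   refit standardization inside each training fold.
#' @param response Continuous outcome (linear) or 0/1 labels /
#'   `impairment_labels` (logistic), in subject order.
#' @param task `"linear"` or `"logistic"`.
#' @param k Subset size (default 3).
#' @param spec A [penalty_spec()] for the task; default L2 strength 1.0.
#' @param top_t How many top subsets to retain (default 10).
#' @param chunk_size Subsets per enumeration chunk (default 10000).
#' @param checkpoint Optional path to a JSON checkpoint file.
#' @param max_chunks Process at most this many chunks in this call; if the
#'   stream is not finished a `subset_search_checkpoint` stub is returned
#'   (call again with the same `checkpoint` to resume).
#' @param verbose Log per-chunk progress.
#' @return A `subset_search` tibble: one row per retained subset with
#'   `rank`, `features` (list column), `label`, `cv_score`,
#'   `apparent_score` and `fit` (list column of `penalized_fit`), plus
#'   attributes recording the task, scores' type, n, k, m and the number
#'   of subsets scored.
#' @export
search_feature_sets <- function(data, response, task = c("linear", "logistic"),
                                k = 3, spec = NULL, top_t = 10,
                                chunk_size = 10000, checkpoint = NULL,
                                max_chunks = Inf, verbose = FALSE) {
  task <- match.arg(task)
  spec <- spec %||% penalty_spec(task)
  if (spec$task != task) abort("spec$task does not match 'task'.")
  is_table <- is.data.frame(data) && all(c("subject_id", "pma_weeks") %in% names(data))
  x <- if (is_table) feature_matrix(data) else as_design(data)
  feats <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  colnames(x) <- feats
  scope <- if (identical(attr(data, "standardized"), "per_training_fold")) {
    "per_training_fold"
  } else {
    "global"
  }
  y <- if (task == "logistic") as_label_vector(response) else as.numeric(response)
  if (length(y) != nrow(x)) abort("Response length must match the subject count.")
  m <- length(feats)
  if (k < 1 || k > m) abort(sprintf("k must be in 1..%d.", m))
  total <- n_feature_sets(m, k)

  fingerprint <- list(
    m = m, k = k, n = nrow(x), task = task,
    lambda = spec$lambda, scope = scope,
    x_sum = format(sum(x), digits = 17),
    y_sum = format(sum(y), digits = 17)
  )
  state <- list(next_rank = 1, top_rank = integer(0), top_score = numeric(0))
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    ck <- jsonlite::read_json(checkpoint, simplifyVector = TRUE)
    if (!identical(lapply(ck$fingerprint, as.character),
                   lapply(fingerprint, as.character))) {
      abort("Checkpoint does not match this search configuration.")
    }
    state <- list(next_rank = ck$next_rank,
                  top_rank = as.numeric(ck$top_rank),
                  # scores are stored as 17-significant-digit strings so the
                  # resumed ranking is bit-identical to an uninterrupted run
                  top_score = as.numeric(ck$top_score))
    if (verbose) inform(sprintf("Resuming from subset %d of %d.", state$next_rank, total))
  }

  score_one <- function(cols) {
    tryCatch({
      cv <- loocv_predict(x[, cols, drop = FALSE], y, spec, scope = scope)
      if (task == "linear") cv_adjusted_r2(cv, y)$value else cv_auc(cv, y)$value
    }, error = function(e) {
      inform(paste0("Subset scored -Inf: ", conditionMessage(e)))
      -Inf
    })
  }

  chunks_done <- 0
  while (state$next_rank <= total && chunks_done < max_chunks) {
    hi <- min(state$next_rank + chunk_size - 1, total)
    ranks <- seq(state$next_rank, hi)
    scores <- vapply(ranks, function(r) score_one(comb_unrank(r, m, k)), 0)
    cand_rank <- c(state$top_rank, ranks)
    cand_score <- c(state$top_score, scores)
    keep <- order(-cand_score, cand_rank)[seq_len(min(top_t, length(cand_rank)))]
    state$top_rank <- cand_rank[keep]
    state$top_score <- cand_score[keep]
    state$next_rank <- hi + 1
    chunks_done <- chunks_done + 1
    if (verbose) {
      inform(sprintf("Scored %d / %d subsets; best CV score %.4f.",
                     hi, total, state$top_score[1]))
    }
    if (!is.null(checkpoint)) {
      jsonlite::write_json(
        list(next_rank = state$next_rank, top_rank = state$top_rank,
             top_score = sprintf("%.17g", state$top_score),
             fingerprint = fingerprint),
        checkpoint, auto_unbox = TRUE, digits = NA
      )
    }
  }
  if (state$next_rank <= total) {
    return(structure(
      list(complete = FALSE, next_rank = state$next_rank, total = total,
           checkpoint = checkpoint),
      class = "subset_search_checkpoint"
    ))
  }

  ord <- order(-state$top_score, state$top_rank)
  rows <- purrr::map(seq_along(ord), function(i) {
    r <- state$top_rank[ord[i]]
    cols <- comb_unrank(r, m, k)
    sub <- feats[cols]
    app <- apparent_score(x[, cols, drop = FALSE], y, spec)
    tibble::tibble(
      rank = i,
      features = list(sub),
      label = paste(sub, collapse = " + "),
      cv_score = state$top_score[ord[i]],
      apparent_score = app$score$value,
      fit = list(app$fit)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    class = c("subset_search", class(tibble::tibble())),
    task = task, k = k, n = nrow(x), m = m,
    score_type = if (task == "linear") "cv_adjusted_r2" else "cv_auc",
    spec = spec, scope = scope, total_subsets = total,
    design = x
  )
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf(
    "Exhaustive %s search: %d of %s %d-feature subsets retained (n = %d)\n",
    attr(x, "task"), nrow(x), format(attr(x, "total_subsets"), big.mark = ","),
    attr(x, "k"), attr(x, "n")
  ))
  print(tibble::as_tibble(x[c("rank", "label", "cv_score", "apparent_score")]))
  invisible(x)
}

#' Tidy an exhaustive-search result
#'
#' `tidy()` expands retained subsets to one row per (subset, feature) with
#' the full-sample refit coefficient; `glance()` summarizes the winner.
#'
#' @param x A `subset_search`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy subset_search
#' @export
tidy.subset_search <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    fit <- x$fit[[i]]
    ids <- parse_feature_lenient(x$features[[i]])
    tibble::tibble(
      rank = x$rank[i],
      feature = ids$feature, region = ids$region, metric = ids$metric,
      coefficient = unname(fit$coefficients[ids$feature]),
      cv_score = x$cv_score[i], apparent_score = x$apparent_score[i]
    )
  })
}

#' @rdname tidy.subset_search
#' @method glance subset_search
#' @export
glance.subset_search <- function(x, ...) {
  tibble::tibble(
    task = attr(x, "task"), score_type = attr(x, "score_type"),
    n = attr(x, "n"), k = attr(x, "k"), m = attr(x, "m"),
    subsets_scored = attr(x, "total_subsets"),
    winner = x$label[1], cv_score = x$cv_score[1],
    apparent_score = x$apparent_score[1]
  )
}

#' Format a search result as a publication-style report row
#'
#' One row per selected feature, displayed as `"region (metric)"`, with
#' the full-sample refit coefficient and the apparent and cross-validated
#' scores, all rounded half-up to `digits` decimals (scores repeated on
#' every row of the subset for a self-contained record).
#'
#' @param result A `subset_search`.
#' @param rank Which retained subset to format (default 1, the winner).
#' @param digits Decimals for coefficients and scores (default 2).
#' @return A tibble with columns `feature_display`, `coefficient`,
#'   `apparent_score`, `cv_score` (all character).
#' @export
make_report_row <- function(result, rank = 1, digits = 2) {
  stopifnot(inherits(result, "subset_search"))
  i <- match(rank, result$rank)
  if (is.na(i)) abort("No retained subset with that rank.")
  fit <- result$fit[[i]]
  ids <- parse_feature_lenient(result$features[[i]])
  tibble::tibble(
    feature_display = ifelse(is.na(ids$metric), ids$feature,
                             paste0(ids$region, " (", ids$metric, ")")),
    coefficient = fmt_round(unname(fit$coefficients[ids$feature]), digits),
    apparent_score = fmt_round(result$apparent_score[i], digits),
    cv_score = fmt_round(result$cv_score[i], digits)
  )
}

#' Write search results as delimited text
#'
#' One record per retained subset (machine-readable, full precision) via
#' `write_search_results()`, or the formatted report via
#' [make_report_row()] rows for every retained subset.
#'
#' @param result A `subset_search`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_search_results <- function(result, path) {
  out <- tidy(result)
  readr::write_csv(out, path)
  invisible(path)
}
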