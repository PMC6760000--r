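#' Validate a subjects-by-features DTI table
#'
#' A feature table is a data frame with one row per subject, a `subject_id`
#' column, a `pma_weeks` column (postmenstrual age at scan, weeks) and one
#' numeric column per `"<region>:<metric>"` feature. Validation enforces
#' unique subject identifiers, positive scan ages, known metrics, complete
#' cells, and FA values in \[0, 1\] (FA is dimensionless; diffusivities are
#' in mm^2/s and unconstrained beyond being finite).
#'
#' @param data A data frame in the layout above.
#' @param atlas Character vector of admissible region labels
#'   (default [dti_atlas()]). Unknown regions raise a warning, or an error
#'   when `strict = TRUE`.
#' @param strict Logical; treat unknown regions as errors.
#' @return A validated feature-table tibble carrying `residualized` and
#'   `standardized` attributes (initialized to `FALSE` / `"none"`).
#' @export
as_feature_table <- function(data, atlas = dti_atlas(), strict = FALSE) {
  data <- tibble::as_tibble(data)
  for (col in c("subject_id", "pma_weeks")) {
    if (!col %in% names(data)) {
      abort(paste0("Feature table must have a '", col, "' column."))
    }
  }
  if (anyDuplicated(data$subject_id)) {
    dup <- unique(data$subject_id[duplicated(data$subject_id)])
    abort(paste0("Duplicate subject IDs: ", paste(dup, collapse = ", ")))
  }
  data$subject_id <- as.character(data$subject_id)
  if (!is.numeric(data$pma_weeks) || anyNA(data$pma_weeks) ||
      any(data$pma_weeks <= 0)) {
    abort("'pma_weeks' must be complete, numeric and positive.")
  }
  feats <- feature_cols(data)
  if (length(feats) == 0) abort("No '<region>:<metric>' feature columns found.")
  ids <- parse_feature_id(feats)
  bad_metric <- ids$feature[!ids$metric %in% dti_metrics()]
  if (length(bad_metric) > 0) {
    abort(paste0(
      "Unknown DTI metric in column(s): ", paste(bad_metric, collapse = ", "),
      " (metrics must be one of ", paste(dti_metrics(), collapse = "/"), ")"
    ))
  }
  unknown <- unique(ids$region[!ids$region %in% atlas])
  if (length(unknown) > 0) {
    msg <- paste0("Region(s) not in atlas: ", paste(unknown, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }
  vals <- as.matrix(data[feats])
  if (!is.numeric(vals)) abort("Feature columns must be numeric.")
  if (anyNA(vals)) {
    miss <- which(is.na(vals), arr.ind = TRUE)
    where <- paste0(
      data$subject_id[miss[, 1]], " / ", feats[miss[, 2]]
    )
    abort(paste0(
      "Missing feature cells (subject / feature): ",
      paste(unique(where), collapse = "; ")
    ))
  }
  fa_cols <- feats[ids$metric == "FA"]
  for (col in fa_cols) {
    if (any(data[[col]] < 0 | data[[col]] > 1)) {
      abort(paste0("FA column out of [0, 1]: ", col))
    }
  }
  attr(data, "residualized") <- FALSE
  attr(data, "standardized") <- "none"
  data
}

#' Read a regional DTI feature table from delimited text
#'
#' Reads a comma- or tab-delimited file (delimiter sniffed from the header
#' line) with a `subject_id` column, a `pma_weeks` column and
#' `"<region>:<metric>"` feature columns, then validates it with
#' [as_feature_table()].
#'
#' @inheritParams as_feature_table
#' @param path Path to the delimited file.
#' @return A validated feature-table tibble.
#' @export
read_feature_table <- function(path, atlas = dti_atlas(), strict = FALSE) {
  delim <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  data <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE
  )
  as_feature_table(data, atlas = atlas, strict = strict)
}

#' Names of the feature columns of a feature table
#'
#' @param data A feature table.
#' @return Character vector of `"<region>:<metric>"` column names, in table
#'   order (the canonical feature order used throughout).
#' @export
feature_cols <- function(data) {
  setdiff(names(data), c("subject_id", "pma_weeks"))
}

#' @rdname feature_cols
#' @return `feature_matrix()`: the numeric subjects-by-features matrix.
#' @export
feature_matrix <- function(data) {
  as.matrix(data[feature_cols(data)])
}

#' Adjust features for postmenstrual age at scan
#'
#' Replaces every feature column by the residuals of an ordinary
#' least-squares fit of that column on an intercept and `pma_weeks`,
#' removing the scan-age confound. Residual columns have mean zero. The
#' operation is a linear projection, so applying it twice equals applying
#' it once.
#'
#' @param data A feature table with at least 3 subjects and non-constant
#'   `pma_weeks`.
#' @return The feature table with residualized feature columns and the
#'   `residualized` attribute set.
#' @export
residualize_pma <- function(data) {
  if (nrow(data) < 3) abort("Residualization needs at least 3 subjects.")
  pma <- data$pma_weeks
  if (isTRUE(all.equal(var(pma), 0)) || var(pma) == 0) {
    abort("'pma_weeks' is constant: the PMA slope is unidentifiable.")
  }
  X <- cbind(1, pma)
  qrX <- qr(X)
  vals <- feature_matrix(data)
  res <- qr.resid(qrX, vals)
  out <- data
  out[feature_cols(data)] <- tibble::as_tibble(res, .name_repair = "minimal")
  attr(out, "residualized") <- TRUE
  attr(out, "standardized") <- attr(data, "standardized") %||% "none"
  out
}

#' Standardize feature columns to zero mean and unit variance
#'
#' With `scope = "global"` every feature column is centered and scaled on
#' the full sample using the population (divisor-n) standard deviation.
#' With `scope = "per_training_fold"` the table is returned unchanged and
#' only the intent is recorded: the cross-validation engine then computes
#' standardization parameters on each training fold and applies them to the
#' held-out subject, avoiding leakage.
#'
#' @param data A feature table with no constant feature columns.
#' @param scope `"global"` (default) or `"per_training_fold"`.
#' @return The feature table, transformed when `scope = "global"`, with the
#'   `standardized` attribute recording the scope.
#' @export
standardize_features <- function(data, scope = c("global", "per_training_fold")) {
  scope <- match.arg(scope)
  out <- data
  if (scope == "global") {
    vals <- feature_matrix(data)
    mu <- colMeans(vals)
    sigma <- sqrt(colMeans(sweep(vals, 2, mu)^2))  # population SD
    if (any(sigma == 0)) {
      abort(paste0(
        "Constant feature column(s): ",
        paste(feature_cols(data)[sigma == 0], collapse = ", ")
      ))
    }
    z <- sweep(sweep(vals, 2, mu), 2, sigma, "/")
    out[feature_cols(data)] <- tibble::as_tibble(z, .name_repair = "minimal")
  }
  attr(out, "residualized") <- attr(data, "residualized") %||% FALSE
  attr(out, "standardized") <- scope
  out
}

#' Normative reference for a gait outcome
#'
#' The typically-developing cohort mean and standard deviation against which
#' impairment is defined, together with the direction in which scores are
#' "worse": `low_is_impaired` for e.g. velocity or single-limb support,
#' `high_is_impaired` for e.g. step width.
#'
#' @param outcome Outcome name (e.g. `"velocity"`).
#' @param mean Typical-cohort mean, on the outcome's clinical scale.
#' @param sd Typical-cohort standard deviation (> 0).
#' @param direction `"low_is_impaired"` or `"high_is_impaired"`. Required:
#'   never defaulted, since the impaired direction is outcome-specific.
#' @param n Typical-cohort size (informational).
#' @return A `normative_reference` object.
#' @export
normative_reference <- function(outcome, mean, sd,
                                direction = c("low_is_impaired", "high_is_impaired"),
                                n = NA_integer_) {
  direction <- match.arg(direction)
  if (!is.numeric(sd) || sd <= 0) abort("'sd' must be a positive number.")
  structure(
    list(outcome = outcome, mean = mean, sd = sd, n = n, direction = direction),
    class = "normative_reference"
  )
}

#' @export
print.normative_reference <- function(x, ...) {
  cat(sprintf(
    "Normative reference for %s: mean %.3g, SD %.3g (n = %s), %s\n",
    x$outcome, x$mean, x$sd, x$n, x$direction
  ))
  invisible(x)
}

#' Label gait impairment against a normative reference
#'
#' A subject is labeled impaired (1) when the outcome is worse than one
#' reference standard deviation from the typical-cohort mean (strictly
#' beyond the threshold; a score exactly at the threshold is not impaired):
#' below `mean - sd_multiplier * sd` when low scores are impaired, above
#' `mean + sd_multiplier * sd` when high scores are impaired.
#'
#' @param values Numeric outcome values (one per subject), or a data frame
#'   holding the outcome in a column named after `ref$outcome`.
#' @param ref A [normative_reference()].
#' @param sd_multiplier How many reference SDs define the threshold
#'   (default 1).
#' @return An `impairment_labels` tibble with columns `value` and
#'   `impaired` (0/1 integer), plus `threshold`, `direction` and `outcome`
#'   attributes. If `values` was a data frame with a `subject_id` column it
#'   is carried through.
#' @export
label_impairment <- function(values, ref, sd_multiplier = 1) {
  stopifnot(inherits(ref, "normative_reference"))
  subject_id <- NULL
  if (is.data.frame(values)) {
    if (!ref$outcome %in% names(values)) {
      abort(paste0("No column '", ref$outcome, "' in the outcomes table."))
    }
    subject_id <- values[["subject_id"]]
    values <- values[[ref$outcome]]
  }
  if (anyNA(values)) abort("Outcome values contain missing entries.")
  if (ref$direction == "low_is_impaired") {
    threshold <- ref$mean - sd_multiplier * ref$sd
    lab <- as.integer(values < threshold)
  } else {
    threshold <- ref$mean + sd_multiplier * ref$sd
    lab <- as.integer(values > threshold)
  }
  out <- tibble::tibble(value = values, impaired = lab)
  if (!is.null(subject_id)) out <- tibble::add_column(out, subject_id = subject_id, .before = 1)
  structure(
    out,
    class = c("impairment_labels", class(out)),
    threshold = threshold,
    direction = ref$direction,
    outcome = ref$outcome
  )
}

# 0/1 vector from whatever the user passed as labels.
as_label_vector <- function(labels) {
  if (inherits(labels, "impairment_labels") ||
      (is.data.frame(labels) && "impaired" %in% names(labels))) {
    labels <- labels$impaired
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    abort("Labels must be binary 0/1 with no missing values.")
  }
  labels
}

#' Read per-subject gait outcomes or binary MRI findings
#'
#' Both files are delimited text keyed by a `subject_id` column;
#' outcome files have numeric outcome columns, findings files have named
#' 0/1 columns.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @return A tibble.
#' @export
read_gait_outcomes <- function(path) {
  delim <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!"subject_id" %in% names(out)) abort("Outcomes file needs 'subject_id'.")
  out$subject_id <- as.character(out$subject_id)
  out
}

#' @rdname read_gait_outcomes
#' @export
read_mri_findings <- function(path) {
  out <- read_gait_outcomes(path)
  flags <- setdiff(names(out), "subject_id")
  for (col in flags) {
    if (!all(out[[col]] %in% c(0, 1))) {
      abort(paste0("Finding column '", col, "' is not binary 0/1."))
    }
  }
  out
}

#' Read or write a normative-reference block
#'
#' Normative references are stored as a small YAML block with fields
#' `outcome`, `mean`, `sd`, `n`, `direction` (one document per outcome,
#' or a list of such blocks).
#'
#' @param path YAML file path.
#' @return A list of [normative_reference()] objects, named by outcome.
#' @export
read_normative_references <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$outcome)) raw <- list(raw)
  refs <- lapply(raw, function(r) {
    normative_reference(r$outcome, r$mean, r$sd, direction = r$direction,
                        n = r$n %||% NA_integer_)
  })
  setNames(refs, vapply(refs, `[[`, "", "outcome"))
}

#' @rdname read_normative_references
#' @param refs A `normative_reference` or list of them.
#' @export
write_normative_references <- function(refs, path) {
  if (inherits(refs, "normative_reference")) refs <- list(refs)
  yaml::write_yaml(lapply(unname(refs), unclass), path)
  invisible(path)
}
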