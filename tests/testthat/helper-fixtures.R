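# Small in-code fixtures shared across test files.

# A tiny well-formed feature table (3 subjects x 2 features by default).
tiny_feature_table <- function(n = 3, features = c("L Amygdala:FA", "Genu of the corpus callosum:MD"),
                               seed = 11) {
  set.seed(seed)
  df <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    pma_weeks = 35 + seq_len(n)
  )
  for (f in features) {
    df[[f]] <- if (grepl(":FA$", f)) runif(n, 0.1, 0.5) else runif(n, 8e-4, 1.6e-3)
  }
  as_feature_table(df)
}

write_tiny_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# Random small regression/classification instance for oracle suites.
random_instance <- function(n, p, task = "linear", seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  beta <- rnorm(p)
  eta <- drop(x %*% beta)
  y <- if (task == "linear") {
    eta + rnorm(n)
  } else {
    lab <- rbinom(n, 1, plogis(eta))
    if (length(unique(lab)) < 2) lab[1:2] <- c(0L, 1L)  # guarantee both classes
    lab
  }
  list(x = x, y = y)
}

# Naive LOOCV oracle: refits from scratch per fold using only the public
# fitting functions, with none of the engine's shortcuts.
naive_loocv <- function(x, y, spec, scope = "global") {
  n <- nrow(x)
  vapply(seq_len(n), function(i) {
    xtr <- x[-i, , drop = FALSE]
    xte <- x[i, , drop = FALSE]
    if (scope == "per_training_fold") {
      mu <- colMeans(xtr)
      sg <- sqrt(colMeans(sweep(xtr, 2, mu)^2))
      xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sg, "/")
    }
    if (spec$task == "linear") {
      predict(fit_ridge(xtr, y[-i], spec), xte)
    } else {
      if (length(unique(y[-i])) < 2) return(mean(y[-i]))
      predict(suppressWarnings(fit_l2_logistic(xtr, y[-i], spec)), xte)
    }
  }, 0)
}

# Wrap raw scores as a loocv_result so the score functions can be tested
# directly on hand-constructed held-out predictions.
fake_loocv <- function(pred, p = 1, task = "logistic") {
  n <- length(pred)
  structure(
    tibble::tibble(row = seq_len(n), prediction = pred,
                   converged = TRUE, degenerate = FALSE),
    class = c("loocv_result", class(tibble::tibble())),
    n = n, p = p, task = task
  )
}

# Apparent (same-data) AUC of a full-sample logistic fit.
apparent_auc_of <- function(x, y, spec) {
  fit <- suppressWarnings(fit_l2_logistic(x, y, spec))
  prob <- predict(fit, x)
  cv_auc(fake_loocv(prob), y)$value
}

# Logistic objective for the optimizer oracle.
logistic_objective <- function(beta, x, y, lambda) {
  eta <- beta[1] + drop(x %*% beta[-1])
  sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lambda / 2 * sum(beta[-1]^2)
}
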