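#' Specification of an L2-penalized fit
#'
#' Holds the task and penalty conventions shared by the ridge and logistic
#' fitters. The penalized objectives are, with unpenalized intercept b0:
#' ridge `sum((y - b0 - X b)^2) + lambda * ||b||^2`, logistic
#' `-loglik + (lambda / 2) * ||b||^2`. `"strength 1.0"` is interpreted as
#' `lambda = 1`; the `inverse_strength` convention (strength `c` mapping to
#' `lambda = 1 / c`, as in regularization parameters expressed as inverse
#' penalties) is available as a switch.
#'
#' @param task `"linear"` or `"logistic"`.
#' @param lambda Non-negative regularization strength (default 1.0).
#' @param convention `"strength"` (lambda as given) or `"inverse_strength"`
#'   (effective lambda is `1 / lambda`).
#' @param max_iter Newton iteration cap for the logistic fit.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param scale_by_n Multiply the effective penalty by the number of
#'   training rows (off by default).
#' @param penalize_intercept Also penalize the intercept (off by default;
#'   standard practice leaves it unpenalized).
#' @return A `penalty_spec` object.
#' @export
penalty_spec <- function(task = c("linear", "logistic"), lambda = 1,
                         convention = c("strength", "inverse_strength"),
                         max_iter = 100L, tol = 1e-8,
                         scale_by_n = FALSE, penalize_intercept = FALSE) {
  task <- match.arg(task)
  convention <- match.arg(convention)
  if (!is.numeric(lambda) || lambda < 0) abort("'lambda' must be >= 0.")
  if (tol <= 0) abort("'tol' must be > 0.")
  structure(
    list(task = task, lambda = lambda, convention = convention,
         max_iter = as.integer(max_iter), tol = tol,
         scale_by_n = scale_by_n, penalize_intercept = penalize_intercept),
    class = "penalty_spec"
  )
}

# Effective penalty for a training set of n rows.
effective_lambda <- function(spec, n) {
  lam <- if (spec$convention == "inverse_strength") {
    if (spec$lambda == 0) abort("inverse_strength 0 is undefined.") else 1 / spec$lambda
  } else {
    spec$lambda
  }
  if (spec$scale_by_n) lam * n else lam
}

as_design <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  x
}

new_penalized_fit <- function(task, intercept, coefficients, spec, converged,
                              objective, nobs) {
  structure(
    list(task = task, intercept = intercept, coefficients = coefficients,
         spec = spec, converged = converged, objective = objective,
         nobs = nobs),
    class = "penalized_fit"
  )
}

#' Ridge regression with an unpenalized intercept
#'
#' Minimizes `sum((y - b0 - X b)^2) + lambda * ||b||^2` in closed form via
#' centering, leaving the intercept unpenalized. At `lambda = 0` this is
#' ordinary least squares; a rank-deficient unpenalized design falls back
#' to the minimum-norm (pseudo-inverse) solution with a warning.
#'
#' @param x Design matrix or data frame of features (rows = subjects).
#' @param y Numeric response, one per row of `x`.
#' @param spec A [penalty_spec()] with `task = "linear"`.
#' @return A `penalized_fit` object.
#' @export
fit_ridge <- function(x, y, spec = penalty_spec("linear")) {
  x <- as_design(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) abort("rows(x) must equal length(y).")
  if (nrow(x) < 2) abort("Ridge fit needs at least 2 rows.")
  if (spec$task != "linear") abort("spec$task must be 'linear'.")
  lam <- effective_lambda(spec, nrow(x))
  cn <- colnames(x) %||% paste0("x", seq_len(ncol(x)))

  if (spec$penalize_intercept) {
    A <- cbind(`(Intercept)` = 1, x)
    M <- crossprod(A) + diag(lam, ncol(A))
    beta_all <- solve_or_pinv(M, crossprod(A, y), lam)
    b0 <- beta_all[1L]
    beta <- beta_all[-1L]
  } else {
    mx <- colMeans(x)
    my <- mean(y)
    xc <- sweep(x, 2, mx)
    M <- crossprod(xc) + diag(lam, ncol(x))
    beta <- solve_or_pinv(M, crossprod(xc, y - my), lam)
    b0 <- my - sum(mx * beta)
  }
  beta <- drop(beta)
  names(beta) <- cn
  resid <- y - b0 - drop(x %*% beta)
  obj <- sum(resid^2) + lam * sum(beta^2) +
    if (spec$penalize_intercept) lam * b0^2 else 0
  new_penalized_fit("linear", b0, beta, spec, TRUE, obj, length(y))
}

# Solve M b = v; if M is singular (only possible at lambda = 0 with a
# collinear design) use the pseudo-inverse minimum-norm solution and warn.
solve_or_pinv <- function(M, v, lam) {
  out <- tryCatch(solve(M, v), error = function(e) NULL)
  if (is.null(out)) {
    warn("Collinear unpenalized design: using the pseudo-inverse (minimum-norm) solution.")
    s <- svd(M)
    pos <- s$d > max(s$d) * 1e-12
    out <- s$v[, pos, drop = FALSE] %*%
      ((crossprod(s$u[, pos, drop = FALSE], v)) / s$d[pos])
  }
  drop(out)
}

#' L2-penalized logistic regression
#'
#' Minimizes the negative Bernoulli log-likelihood plus
#' `(lambda / 2) * ||b||^2` (intercept unpenalized) by Newton iterations
#' from zero initialization, with step-halving whenever a step would
#' increase the objective. Deterministic; convergence is declared when the
#' gradient max-norm drops below `spec$tol`. The penalty keeps coefficients
#' finite even on separable data.
#'
#' @param x Design matrix or data frame (rows = subjects).
#' @param y Binary 0/1 labels; both classes must be present.
#' @param spec A [penalty_spec()] with `task = "logistic"`.
#' @param init Optional warm-start coefficient vector
#'   `c(intercept, slopes)`; used by the cross-validation engine.
#' @return A `penalized_fit`; `converged` is `FALSE` (with a warning) if
#'   the iteration cap is hit.
#' @export
fit_l2_logistic <- function(x, y, spec = penalty_spec("logistic"), init = NULL) {
  x <- as_design(x)
  y <- as_label_vector(y)
  if (nrow(x) != length(y)) abort("rows(x) must equal length(y).")
  if (length(unique(y)) < 2) {
    abort("Training labels are single-class: logistic fit is undefined.", class = "gaitdti_single_class")
  }
  if (spec$task != "logistic") abort("spec$task must be 'logistic'.")
  lam <- effective_lambda(spec, nrow(x))
  cn <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  A <- cbind(1, x)
  p <- ncol(A)
  pen <- c(if (spec$penalize_intercept) lam else 0, rep(lam, p - 1L))

  objective <- function(beta) {
    eta <- drop(A %*% beta)
    # log(1 + exp(eta)) - y * eta, numerically stable
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) + sum(pen * beta^2) / 2
  }
  beta <- if (is.null(init)) numeric(p) else as.numeric(init)
  obj <- objective(beta)
  converged <- FALSE
  for (it in seq_len(spec$max_iter)) {
    eta <- drop(A %*% beta)
    mu <- plogis(eta)
    g <- drop(crossprod(A, mu - y)) + pen * beta
    if (max(abs(g)) < spec$tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(A * w, A)
    diag(H) <- diag(H) + pen
    step <- drop(solve(H, g))
    t <- 1
    repeat {
      cand <- beta - t * step
      cobj <- objective(cand)
      if (cobj <= obj + 1e-12 || t < 1e-8) break
      t <- t / 2
    }
    beta <- cand
    obj <- cobj
  }
  if (!converged) {
    # final gradient check: the loop may exit at max_iter already converged
    eta <- drop(A %*% beta)
    g <- drop(crossprod(A, plogis(eta) - y)) + pen * beta
    converged <- max(abs(g)) < spec$tol
    if (!converged) warn("Logistic fit did not converge; returning last iterate.")
  }
  slopes <- beta[-1L]
  names(slopes) <- cn
  new_penalized_fit("logistic", beta[1L], slopes, spec, converged, obj, length(y))
}

#' Predict from a penalized fit
#'
#' @param object A `penalized_fit`.
#' @param newdata Matrix or data frame with the same number of feature
#'   columns as the fit.
#' @param type `"response"` (default: fitted values for linear, class-1
#'   probabilities strictly inside (0, 1) for logistic) or `"link"` (linear
#'   predictor).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.penalized_fit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- as_design(newdata)
  if (ncol(x) != length(object$coefficients)) {
    abort(sprintf(
      "Design has %d columns but the fit has %d coefficients.",
      ncol(x), length(object$coefficients)
    ))
  }
  eta <- object$intercept + drop(x %*% object$coefficients)
  if (object$task == "logistic" && type == "response") plogis(eta) else eta
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf(
    "L2-penalized %s fit (lambda = %g%s): intercept %.4g, %d feature(s)%s\n",
    x$task, x$spec$lambda,
    if (x$spec$convention == "inverse_strength") ", inverse convention" else "",
    x$intercept, length(x$coefficients),
    if (x$converged) "" else " [not converged]"
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a penalized fit into a coefficient table
#'
#' @param x A `penalized_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (intercept first).
#' @method tidy penalized_fit
#' @export
tidy.penalized_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = unname(c(x$intercept, x$coefficients))
  )
}

#' @rdname tidy.penalized_fit
#' @return `glance()`: a one-row tibble with `task`, `lambda`, `objective`,
#'   `converged` and `nobs`.
#' @method glance penalized_fit
#' @export
glance.penalized_fit <- function(x, ...) {
  tibble::tibble(
    task = x$task, lambda = x$spec$lambda, objective = x$objective,
    converged = x$converged, nobs = x$nobs
  )
}

#' Serialize a fit to (and from) a plain key-value text record
#'
#' @param fit A `penalized_fit`.
#' @param path File path.
#' @return `write_fit()` returns `path` invisibly; `read_fit_record()`
#'   returns a tibble of terms and estimates.
#' @export
write_fit <- function(fit, path) {
  lines <- c(
    paste0("task: ", fit$task),
    paste0("lambda: ", format(fit$spec$lambda, digits = 17)),
    paste0("(Intercept): ", format(fit$intercept, digits = 17)),
    paste0(names(fit$coefficients), ": ",
           vapply(fit$coefficients, format, "", digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit_record <- function(path) {
  lines <- readLines(path)
  key <- sub(": .*$", "", lines)
  val <- sub("^.*: ", "", lines)
  tibble::tibble(term = key, value = val)
}
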