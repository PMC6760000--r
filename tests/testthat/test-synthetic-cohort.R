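test_that("tensor identities hold exactly and FA stays in [0, 1]", {
  # isotropy: FA 0, all scalars equal
  iso <- tensor_scalars(1e-3, 1e-3, 1e-3)
  expect_equal(iso$FA, 0)
  expect_equal(iso$MD, 1e-3)
  expect_equal(iso$AD, 1e-3)
  expect_equal(iso$RD, 1e-3)

  # maximal anisotropy limit: FA = (1 - t)/sqrt(1 + 2 t^2) with
  # t = l2/l1 = 1e-6, i.e. 1 - FA is of order t itself
  aniso <- tensor_scalars(1e-3, 1e-9, 1e-9)
  expect_equal(aniso$FA, 1, tolerance = 2e-6)

  # hand evaluation at (1.6, 0.5, 0.3)e-3
  sc <- tensor_scalars(1.6e-3, 0.5e-3, 0.3e-3)
  expect_equal(sc$MD, 0.8e-3)
  expect_equal(sc$RD, 0.4e-3)
  l <- c(1.6, 0.5, 0.3) * 1e-3
  fa_hand <- sqrt(3 / 2) * sqrt(sum((l - mean(l))^2)) / sqrt(sum(l^2))
  expect_equal(sc$FA, fa_hand, tolerance = 1e-12)

  # identity MD = (AD + 2 RD) / 3 exactly on generated data
  co <- generate_cohort(cohort_config(seed = 5, n_subjects = 30))
  pr <- co$features
  regions <- unique(parse_feature_id(feature_cols(pr))$region)
  for (r in regions) {
    md <- pr[[feature_id(r, "MD")]]
    ad <- pr[[feature_id(r, "AD")]]
    rd <- pr[[feature_id(r, "RD")]]
    fa <- pr[[feature_id(r, "FA")]]
    expect_true(all(abs(md - (ad + 2 * rd) / 3) <= 1e-15))
    expect_true(all(fa >= 0 & fa <= 1))
  }
})

test_that("the same seed reproduces the cohort bit for bit", {
  a <- generate_cohort(cohort_config(seed = 42))
  b <- generate_cohort(cohort_config(seed = 42))
  expect_identical(feature_matrix(a$features), feature_matrix(b$features))
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$findings, b$findings)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(seed = 43))
  expect_false(identical(a$outcome, c$outcome))
})

test_that("maturation directionality: FA rises with scan age, MD and RD fall", {
  co <- generate_cohort(cohort_config(seed = 2, n_subjects = 500))
  ft <- co$features
  ids <- parse_feature_id(feature_cols(ft))
  rho <- vapply(seq_along(ids$feature), function(j) {
    cor(ft$pma_weeks, ft[[ids$feature[j]]], method = "spearman")
  }, 0)
  expect_true(all(rho[ids$metric == "FA"] > 0))
  expect_true(all(rho[ids$metric == "MD"] < 0))
  expect_true(all(rho[ids$metric == "RD"] < 0))
})

test_that("realized impairment prevalence tracks the 14/52 target", {
  prev <- vapply(1:50, function(s) {
    generate_cohort(cohort_config(seed = s))$truth$realized_prevalence
  }, 0)
  expect_gte(mean(prev), 0.17)
  expect_lte(mean(prev), 0.37)
})

test_that("ridge on the true planted set recovers the standardized weights", {
  # on the standardized outcome the population coefficients of the
  # scan-age-adjusted standardized planted features are
  # w * sqrt(R2_realized) / ||w|| (planted regions are distinct, hence
  # independent)
  for (s in 1:20) {
    co <- generate_cohort(cohort_config(seed = 100 + s, n_subjects = 300))
    w <- co$truth$planted_weights
    x <- feature_matrix(standardize_features(residualize_pma(co$features)))[, co$truth$planted_features]
    y <- co$outcome[[co$truth$outcome]]
    y <- (y - mean(y)) / gaitdti:::pop_sd(y)
    fit <- fit_ridge(x, y, penalty_spec("linear", lambda = 1))
    expected <- w * sqrt(co$truth$realized_signal_fraction) / sqrt(sum(w^2))
    expect_lt(max(abs(unname(fit$coefficients) - expected)), 0.15)
  }
})

test_that("a noiseless planted cohort is recovered with near-perfect CV fit", {
  co <- generate_cohort(cohort_config(seed = 3, n_subjects = 60, noise_sd = 0))
  prep <- standardize_features(residualize_pma(co$features))
  # at lambda = 0, subsets holding MD, AD and RD of one region are exactly
  # collinear and warn about the pseudo-inverse fallback
  res <- suppressWarnings(
    search_feature_sets(prep, co$outcome$velocity, task = "linear", k = 3,
                        spec = penalty_spec("linear", lambda = 0), top_t = 1)
  )
  expect_setequal(res$features[[1]], co$truth$planted_features)
  expect_gte(res$cv_score[1], 0.99)
})

test_that("null cohorts decouple the outcome from every feature", {
  aucs <- vapply(1:50, function(s) {
    co <- generate_null_cohort(cohort_config(seed = 200 + s))
    prep <- standardize_features(residualize_pma(co$features))
    x <- feature_matrix(prep)[, co$truth$planted_features]
    cv <- loocv_predict(x, co$labels$impaired, penalty_spec("logistic"))
    cv_auc(cv, co$labels$impaired)$value
  }, 0)
  expect_gte(median(aucs), 0.4)
  expect_lte(median(aucs), 0.6)

  a <- generate_null_cohort(cohort_config(seed = 7))
  b <- generate_null_cohort(cohort_config(seed = 7))
  expect_identical(a$outcome, b$outcome)
  expect_true(all(a$truth$planted_weights == 0))
})

test_that("best-of-many-subsets selection inflates the null CV score", {
  # direction-only demonstration of selection bias on null data
  singles <- best <- numeric(8)
  for (s in 1:8) {
    co <- generate_null_cohort(cohort_config(seed = 300 + s, n_features = 12))
    prep <- standardize_features(residualize_pma(co$features))
    x <- feature_matrix(prep)
    cv <- loocv_predict(x[, 1, drop = FALSE], co$labels$impaired, penalty_spec("logistic"))
    singles[s] <- cv_auc(cv, co$labels$impaired)$value
    res <- search_feature_sets(prep, co$labels, task = "logistic", k = 1, top_t = 1)
    best[s] <- res$cv_score[1]
  }
  expect_gt(mean(best), median(singles))
})

test_that("cohorts round-trip through the delimited writers and readers", {
  co <- generate_cohort(cohort_config(seed = 9, n_subjects = 20))
  dir <- tempfile()
  write_cohort(co, dir)
  ft <- read_feature_table(file.path(dir, "features.csv"))
  expect_equal(feature_matrix(ft), feature_matrix(co$features), tolerance = 1e-12)
  out <- read_gait_outcomes(file.path(dir, "outcomes.csv"))
  expect_equal(out$velocity, co$outcome$velocity, tolerance = 1e-12)
  fnd <- read_mri_findings(file.path(dir, "findings.csv"))
  expect_equal(fnd, co$findings)
  refs <- read_normative_references(file.path(dir, "reference.yaml"))
  expect_equal(refs$velocity$mean, co$reference$mean)
  truth <- read_truth_record(dir)
  expect_setequal(truth$planted_features, co$truth$planted_features)
})

test_that("degenerate latent outcomes are rejected with a recalibration hint", {
  cfg <- cohort_config(seed = 1, noise_sd = 0,
                       planted_weights = c(0, 0, 0))
  expect_error(generate_cohort(cfg), "recalibrate")
})
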