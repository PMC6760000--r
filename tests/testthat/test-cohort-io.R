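test_that("a well-formed file round-trips through read_feature_table", {
  ft <- tiny_feature_table()
  path <- write_tiny_csv(tibble::as_tibble(ft))
  back <- read_feature_table(path)
  expect_equal(dim(feature_matrix(back)), c(3, 2))
  expect_equal(feature_matrix(back), feature_matrix(ft))
  expect_equal(back$subject_id, ft$subject_id)
  expect_false(attr(back, "residualized"))
  expect_identical(attr(back, "standardized"), "none")
})

test_that("validation rejects bad metrics, missing cells and duplicate IDs", {
  df <- tibble::as_tibble(tiny_feature_table())

  bad_metric <- dplyr::rename(df, "L Amygdala:QA" = "L Amygdala:FA")
  expect_error(as_feature_table(bad_metric), "L Amygdala:QA")

  miss <- df
  miss[["Genu of the corpus callosum:MD"]][2] <- NA
  err <- expect_error(as_feature_table(miss), "S02")
  expect_match(conditionMessage(err), "Genu of the corpus callosum:MD", fixed = TRUE)

  dup <- df
  dup$subject_id[2] <- dup$subject_id[1]
  expect_error(as_feature_table(dup), "Duplicate")

  unknown <- dplyr::rename(df, "Atlantis:FA" = "L Amygdala:FA")
  expect_warning(as_feature_table(unknown), "Atlantis")
  expect_error(as_feature_table(unknown, strict = TRUE), "Atlantis")
})

test_that("tab-delimited input is sniffed and read", {
  ft <- tibble::as_tibble(tiny_feature_table())
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(ft, path)
  expect_equal(feature_matrix(read_feature_table(path)),
               feature_matrix(tiny_feature_table()))
})

test_that("the atlas has 99 regions: 48 bilateral pairs plus three callosal", {
  atlas <- dti_atlas()
  expect_length(atlas, 99)
  expect_length(unique(atlas), 99)
  expect_equal(sum(grepl("^L ", atlas)), 48)
  expect_equal(sum(grepl("^R ", atlas)), 48)
  expect_equal(sum(grepl("corpus callosum", atlas)), 3)
  expect_length(feature_grid(), 396)
})

test_that("PMA residualization matches hand OLS and zeroes explained columns", {
  df <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    pma_weeks = c(35, 36, 37, 38),
    `L Amygdala:FA` = c(0.2, 0.2, 0.2, 0.2),        # constant column
    `L Amygdala:MD` = 3e-4 * c(35, 36, 37, 38) + 2e-4, # exactly 3*PMA + 2 (scaled)
    `Genu of the corpus callosum:MD` = c(1, 2, 2, 3) * 1e-3
  )
  ft <- as_feature_table(df)
  res <- residualize_pma(ft)
  expect_true(attr(res, "residualized"))
  expect_equal(unname(res[["L Amygdala:FA"]]), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(res[["L Amygdala:MD"]]), rep(0, 4), tolerance = 1e-12)
  # hand OLS on PMA (35..38), y (1,2,2,3): slope 0.6, intercept -19.9
  expect_equal(res[["Genu of the corpus callosum:MD"]],
               c(-0.1, 0.3, -0.3, 0.1) * 1e-3, tolerance = 1e-12)
  # every residual column has mean zero
  expect_true(all(abs(colMeans(feature_matrix(res))) < 1e-15))
})

test_that("residualization is a projection and rejects constant PMA", {
  ft <- tiny_feature_table(n = 8)
  once <- residualize_pma(ft)
  twice <- residualize_pma(once)
  expect_equal(feature_matrix(twice), feature_matrix(once), tolerance = 1e-10)

  const <- tibble::as_tibble(ft)
  const$pma_weeks <- 36
  expect_error(residualize_pma(as_feature_table(const)), "constant")
})

test_that("global standardization hits the derived values and is idempotent", {
  df <- tibble::tibble(
    subject_id = c("a", "b", "c"), pma_weeks = c(35, 36, 37),
    `L Amygdala:FA` = c(0.1, 0.2, 0.3)
  )
  ft <- as_feature_table(df)
  z <- standardize_features(ft)
  # column (1,2,3): mean 2, population SD sqrt(2/3)
  expect_equal(z[["L Amygdala:FA"]], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  z2 <- standardize_features(z)
  expect_equal(feature_matrix(z2), feature_matrix(z), tolerance = 1e-12)
  expect_identical(attr(z, "standardized"), "global")

  const <- df
  const$`L Amygdala:FA` <- 0.5
  expect_error(standardize_features(as_feature_table(const)), "L Amygdala:FA")
})

test_that("standardized columns have zero mean and unit population variance", {
  ft <- tiny_feature_table(n = 23, seed = 4)
  z <- feature_matrix(standardize_features(residualize_pma(ft)))
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(colMeans(z^2) - 1) < 1e-10))
})

test_that("per_training_fold standardization records intent without transforming", {
  ft <- tiny_feature_table(n = 6)
  z <- standardize_features(ft, scope = "per_training_fold")
  expect_equal(feature_matrix(z), feature_matrix(ft))
  expect_identical(attr(z, "standardized"), "per_training_fold")
})

test_that("impairment labeling is strict and direction-aware", {
  low <- normative_reference("velocity", 100, 10, "low_is_impaired")
  lab <- label_impairment(c(89, 91, 90), low)
  expect_equal(lab$impaired, c(1L, 0L, 0L))  # exactly at threshold -> 0
  expect_equal(attr(lab, "threshold"), 90)

  high <- normative_reference("step_width", 8, 1.5, "high_is_impaired")
  lab2 <- label_impairment(c(10, 9.5, 9), high)
  expect_equal(lab2$impaired, c(1L, 0L, 0L))  # 10 > 9.5, 9.5 is at threshold
})

test_that("impairment prevalence is monotone non-increasing in the SD multiplier", {
  set.seed(7)
  vals <- rnorm(200, 100, 12)
  ref <- normative_reference("velocity", 100, 10, "low_is_impaired")
  prev <- vapply(c(0.5, 1, 1.5, 2, 3),
                 function(m) mean(label_impairment(vals, ref, sd_multiplier = m)$impaired), 0)
  expect_true(all(diff(prev) <= 0))
})

test_that("normative references round-trip through YAML", {
  refs <- list(
    normative_reference("velocity", 95, 16, "low_is_impaired", n = 42),
    normative_reference("step_width", 8, 1.5, "high_is_impaired", n = 42)
  )
  path <- tempfile(fileext = ".yaml")
  write_normative_references(refs, path)
  back <- read_normative_references(path)
  expect_named(back, c("velocity", "step_width"))
  expect_equal(back$velocity$mean, 95)
  expect_identical(back$step_width$direction, "high_is_impaired")
})
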