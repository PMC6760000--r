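test_that("subset enumeration is lexicographic, complete and restartable", {
  sets <- enumerate_feature_sets(c("a", "b", "c", "d"), 3)
  expect_equal(nrow(sets), 4)
  expect_equal(sets[, 1], c("a", "a", "a", "b"))
  expect_equal(unname(sets[1, ]), c("a", "b", "c"))
  expect_equal(unname(sets[4, ]), c("b", "c", "d"))

  # full stream equals combn order on a larger pool
  feats <- letters[1:7]
  ours <- enumerate_feature_sets(feats, 3)
  ref <- t(combn(feats, 3))
  expect_equal(unname(ours), unname(ref))

  # a rank range picks out the same rows
  mid <- enumerate_feature_sets(feats, 3, from = 10, to = 20)
  expect_equal(unname(mid), unname(ref[10:20, ]))

  # k = m -> exactly one subset; k > m -> error
  expect_equal(nrow(enumerate_feature_sets(feats, 7)), 1)
  expect_error(enumerate_feature_sets(feats, 8), "exceeds")
})

test_that("the 396-feature grid yields 10,271,580 three-feature subsets", {
  expect_equal(n_feature_sets(396, 3), 10271580)
  expect_equal(n_feature_sets(length(feature_grid()), 3), 396 * 395 * 394 / 6)
})

test_that("a perfectly predictive single feature wins with CV adjusted R^2 of 1", {
  set.seed(4)
  x <- cbind(A = rnorm(12), B = rnorm(12))
  y <- x[, "A"]
  res <- search_feature_sets(x, y, task = "linear", k = 1,
                             spec = penalty_spec("linear", lambda = 0), top_t = 2)
  expect_equal(res$features[[1]], "A")
  expect_equal(res$cv_score[1], 1, tolerance = 1e-8)
})

test_that("search ranking equals an independent brute-force composition", {
  # 8 features, k = 2: compose the ranking from only the model and CV
  # primitives, independently of the search machinery
  inst <- random_instance(14, 8, seed = 42)
  spec <- penalty_spec("linear", lambda = 1)
  res <- search_feature_sets(inst$x, inst$y, task = "linear", k = 2,
                             spec = spec, top_t = 28)
  pairs <- t(combn(colnames(inst$x), 2))
  brute <- tibble::tibble(
    label = apply(pairs, 1, paste, collapse = " + "),
    score = apply(pairs, 1, function(fs) {
      cv <- loocv_predict(inst$x[, fs], inst$y, spec)
      cv_adjusted_r2(cv, inst$y)$value
    })
  )
  brute <- brute[order(-brute$score), ]
  expect_equal(res$label, brute$label)
  expect_equal(res$cv_score, brute$score, tolerance = 1e-12)

  # the winner's reported score equals re-evaluating the subset in isolation
  iso <- cv_adjusted_r2(loocv_predict(inst$x[, res$features[[1]]], inst$y, spec), inst$y)
  expect_equal(res$cv_score[1], iso$value, tolerance = 1e-12)
})

test_that("checkpointed interrupted runs resume to an identical ranking", {
  inst <- random_instance(10, 8, seed = 17)
  spec <- penalty_spec("linear", lambda = 1)
  full <- search_feature_sets(inst$x, inst$y, task = "linear", k = 3,
                              spec = spec, top_t = 5)
  ck <- tempfile(fileext = ".json")
  part <- search_feature_sets(inst$x, inst$y, task = "linear", k = 3,
                              spec = spec, top_t = 5,
                              chunk_size = 13, checkpoint = ck, max_chunks = 2)
  expect_s3_class(part, "subset_search_checkpoint")
  expect_false(part$complete)
  resumed <- search_feature_sets(inst$x, inst$y, task = "linear", k = 3,
                                 spec = spec, top_t = 5,
                                 chunk_size = 13, checkpoint = ck)
  expect_equal(resumed$label, full$label)
  expect_equal(resumed$cv_score, full$cv_score, tolerance = 0)
  expect_equal(resumed$apparent_score, full$apparent_score, tolerance = 0)

  # a checkpoint from different data is refused
  other <- random_instance(10, 8, seed = 18)
  expect_error(
    search_feature_sets(other$x, other$y, task = "linear", k = 3,
                        spec = spec, top_t = 5, chunk_size = 13, checkpoint = ck),
    "Checkpoint"
  )
})

test_that("chunk size does not affect the ranking", {
  inst <- random_instance(10, 7, seed = 3)
  spec <- penalty_spec("linear", lambda = 1)
  a <- search_feature_sets(inst$x, inst$y, task = "linear", k = 2, spec = spec,
                           top_t = 5, chunk_size = 3)
  b <- search_feature_sets(inst$x, inst$y, task = "linear", k = 2, spec = spec,
                           top_t = 5, chunk_size = 1000)
  expect_equal(a$label, b$label)
  expect_equal(a$cv_score, b$cv_score, tolerance = 0)
})

test_that("report rows use region (metric) display and half-up 2-decimal rounding", {
  set.seed(8)
  n <- 15
  x <- cbind(rnorm(n), rnorm(n), rnorm(n))
  colnames(x) <- c("R Inferior frontal gyrus:FA", "L Hippocampus:AD",
                   "Genu of the corpus callosum:MD")
  y <- drop(x %*% c(-1, 0.5, 0.8)) + rnorm(n, sd = 0.3)
  res <- search_feature_sets(x, y, task = "linear", k = 3, top_t = 1)
  row <- make_report_row(res)
  expect_equal(row$feature_display[1], "R Inferior frontal gyrus (FA)")
  fit <- res$fit[[1]]
  expect_equal(row$coefficient,
               gaitdti:::fmt_round(unname(fit$coefficients[res$features[[1]]])))
  expect_match(row$cv_score[1], "^-?\\d+\\.\\d{2}$")
  # rounding convention on known values
  expect_equal(gaitdti:::fmt_round(-3.1349), "-3.13")
  expect_equal(gaitdti:::fmt_round(0.895), "0.90")
  expect_equal(gaitdti:::fmt_round(0.9286), "0.93")
})

test_that("tidy and glance summarize retained subsets", {
  inst <- random_instance(12, 5, seed = 6)
  res <- search_feature_sets(inst$x, inst$y, task = "linear", k = 2, top_t = 3)
  td <- tidy(res)
  expect_equal(nrow(td), 6)  # 3 subsets x 2 features
  expect_true(all(c("rank", "feature", "coefficient", "cv_score") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$subsets_scored, choose(5, 2))
  expect_equal(gl$winner, res$label[1])
})
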