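test_that("LOPO folds partition the cohort with no participant leakage", {
  ft <- make_classifier_table(n_participants = 19, n_per_condition = 3)
  folds <- lopo_splits(ft)
  expect_length(folds, 19)
  test_ids <- vapply(folds, `[[`, "", "test")
  expect_setequal(test_ids, unique(ft$participant))
  for (fold in folds) {
    expect_false(fold$test %in% fold$train)
    expect_setequal(c(fold$train, fold$test), unique(ft$participant))
  }
})

test_that("rank AUC matches pair counting, ties, and an external reference", {
  expect_equal(auc_rank(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  expect_equal(auc_rank(c(5, 6), c(1, 2)), 1)
  expect_equal(auc_rank(rep(1, 5), rep(1, 7)), 0.5)
  expect_true(is.na(auc_rank(numeric(0), c(1))))
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    set.seed(seed)
    pos <- rnorm(30, 0.5); neg <- rnorm(40)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = c(rep(1, 30), rep(0, 40)), predictor = c(pos, neg),
      direction = "<", quiet = TRUE)))
    expect_equal(auc_rank(pos, neg), ref)
  }
})

test_that("all three feature models separate an easy regime under LOPO", {
  ft <- make_classifier_table(n_participants = 5, n_per_condition = 30,
                              shift = 4, intercept_sd = 0.2, seed = 2)
  for (model in c("rf", "svm", "gb")) {
    res <- train_eval_feature_model(ft, model, features = feature_cols(ft),
                                    seed = 7)
    expect_gte(res$summary$accuracy[1], 0.9, label = model)
    expect_equal(nrow(res$per_participant), 5)
    expect_true(all(res$per_participant$auc >= 0.9))
  }
})

test_that("label-shuffled cohorts score at chance", {
  accs <- vapply(1:5, function(seed) {
    ft <- make_classifier_table(n_participants = 5, n_per_condition = 25,
                                shift = 3, seed = seed)
    set.seed(seed + 100)
    for (p in unique(ft$participant)) {
      sel <- ft$participant == p
      ft$condition[sel] <- sample(ft$condition[sel])
    }
    res <- train_eval_feature_model(ft, "rf", features = feature_cols(ft),
                                    seed = seed)
    res$summary$accuracy[1]
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.1)
})

test_that("the aggregate row is the arithmetic mean of per-participant metrics", {
  ft <- make_classifier_table(n_participants = 4, n_per_condition = 20,
                              shift = 2, seed = 3)
  res <- train_eval_feature_model(ft, "rf", features = feature_cols(ft),
                                  seed = 1)
  expect_equal(res$summary$accuracy[1], mean(res$per_participant$accuracy))
  expect_equal(res$summary$f1[1], mean(res$per_participant$f1))
  expect_false(is.null(res$importance))
  expect_true(all(diff(res$importance$importance) <= 0))
})

test_that("held-out predictions never depend on the test participant's labels", {
  ft <- make_classifier_table(n_participants = 4, n_per_condition = 20,
                              shift = 2, seed = 6)
  res1 <- train_eval_feature_model(ft, "rf", features = feature_cols(ft),
                                   seed = 5)
  flipped <- ft
  sel <- flipped$participant == "P02"
  flipped$condition[sel] <- 1L - flipped$condition[sel]
  res2 <- train_eval_feature_model(flipped, "rf",
                                   features = feature_cols(ft), seed = 5)
  a1 <- res1$per_participant$accuracy[res1$per_participant$participant == "P02"]
  a2 <- res2$per_participant$accuracy[res2$per_participant$participant == "P02"]
  expect_equal(a2, 1 - a1)
})

test_that("the CNN stage disables cleanly without a deep-learning backend", {
  ft <- make_classifier_table(n_participants = 2, n_per_condition = 5)
  expect_message(res <- train_eval_cnn(list(), lopo_splits(ft)), "disabled")
  expect_s3_class(res, "cnn_result")
  expect_equal(res$status, "disabled")
})
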