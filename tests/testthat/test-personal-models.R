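test_that("stratified folds preserve class proportions within one stride", {
  set.seed(1)
  y <- c(rep(0L, 37), rep(1L, 23))[sample(60)]
  folds <- stratified_folds(y, 5)
  overall <- mean(y)
  for (k in 1:5) {
    in_fold <- y[folds == k]
    expect_lte(abs(sum(in_fold) - overall * length(in_fold)), 1)
  }
})

test_that("a separable participant is classified nearly perfectly", {
  ft <- make_classifier_table(n_participants = 1, n_per_condition = 40,
                              shift = 5, seed = 2)
  res <- personal_supervised_cv(ft, K = 5, features = feature_cols(ft),
                                seed = 3)
  expect_gte(res$cv_accuracy, 0.95)
  expect_gte(res$cv_auc, 0.99)
  expect_equal(res$n_f + res$n_nf, res$n_strides)
})

test_that("shuffled labels give chance-level personal accuracy", {
  accs <- vapply(1:3, function(seed) {
    ft <- make_classifier_table(n_participants = 1, n_per_condition = 30,
                                shift = 4, seed = seed)
    set.seed(seed + 50)
    ft$condition <- sample(ft$condition)
    personal_supervised_cv(ft, K = 5, features = feature_cols(ft),
                           seed = seed)$cv_accuracy
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.15)
})

test_that("K is reduced with a warning when a class is small", {
  ft <- make_classifier_table(n_participants = 1, n_per_condition = 10,
                              shift = 4, seed = 4)
  ft <- ft[c(which(ft$condition == 0), which(ft$condition == 1)[1:3]), ]
  expect_warning(res <- personal_supervised_cv(ft, K = 5,
                                               features = feature_cols(ft)),
                 "K reduced")
  expect_s3_class(res, "personal_supervised_result")
})

test_that("the NF-only boundary honours the nu contract and determinism", {
  set.seed(5)
  nf <- matrix(rnorm(200 * 6), 200, 6,
               dimnames = list(NULL, paste0("feat", 1:6)))
  expect_error(fit_nf_ocsvm(nf[1:10, ]), "at least 20")
  model <- fit_nf_ocsvm(nf, nu = 0.1)
  inlier_frac <- mean(predict(model$fit, model$standardize(nf)))
  expect_equal(inlier_frac, 0.9, tolerance = 0.05)

  model2 <- fit_nf_ocsvm(nf, nu = 0.1)
  probe <- matrix(rnorm(50 * 6), 50, 6)
  expect_equal(predict(model$fit, model$standardize(probe)),
               predict(model2$fit, model2$standardize(probe)))
})

test_that("anomaly evaluation flags shifted fatigued strides as deviations", {
  set.seed(6)
  p <- 6
  nf <- matrix(rnorm(120 * p), 120, p,
               dimnames = list(NULL, paste0("feat", 1:p)))
  f <- matrix(rnorm(100 * p), 100, p,
              dimnames = list(NULL, paste0("feat", 1:p)))
  f[, 1] <- f[, 1] + 5  # five pooled SDs from baseline
  ft <- data.frame(participant = "P01",
                   condition = c(rep(0L, 120), rep(1L, 100)),
                   stride_index = 1:220)
  ft <- cbind(ft, as.data.frame(rbind(nf, f)))
  model <- fit_nf_ocsvm(ft[ft$condition == 0, paste0("feat", 1:p)], nu = 0.1)
  res <- evaluate_anomaly(model, ft)
  expect_gte(res$recall_f, 0.95)
  expect_lt(res$fpr_nf, 0.25)
  expect_gt(res$auc, 0.5)   # scores rank F above NF when recall > FPR

  # exchangeable F rows (drawn from the NF distribution) score like NF
  set.seed(7)
  ft_null <- ft
  ft_null[ft_null$condition == 1, paste0("feat", 1:p)] <-
    matrix(rnorm(100 * p), 100, p)
  res_null <- evaluate_anomaly(model, ft_null)
  expect_lte(abs(res_null$recall_f - res_null$fpr_nf), 0.15)
})

test_that("increasing the fatigue shift never lowers mean recall", {
  recalls <- vapply(c(1, 2.5, 4), function(shift) {
    set.seed(42)
    p <- 4
    nf <- matrix(rnorm(100 * p), 100, p,
                 dimnames = list(NULL, paste0("feat", 1:p)))
    f <- matrix(rnorm(80 * p), 80, p,
                dimnames = list(NULL, paste0("feat", 1:p)))
    f[, 1] <- f[, 1] + shift
    ft <- data.frame(participant = "P01",
                     condition = c(rep(0L, 100), rep(1L, 80)),
                     stride_index = 1:180)
    ft <- cbind(ft, as.data.frame(rbind(nf, f)))
    model <- fit_nf_ocsvm(ft[ft$condition == 0, paste0("feat", 1:p)],
                          nu = 0.1)
    evaluate_anomaly(model, ft)$recall_f
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("cohort aggregation is the exact column mean with range statistics", {
  set.seed(8)
  df <- data.frame(participant = sprintf("P%02d", 1:7),
                   n_strides = 100, n_f = 50, n_nf = 50,
                   accuracy = runif(7), f1 = runif(7), auc = runif(7))
  agg <- aggregate_personal(df)
  expect_equal(agg$accuracy[agg$statistic == "mean"], mean(df$accuracy),
               tolerance = 1e-4)
  expect_equal(agg$auc[agg$statistic == "min"], min(df$auc))
  one <- aggregate_personal(df[3, ])
  expect_equal(one$f1[one$statistic == "mean"], df$f1[3])
  expect_equal(one$f1[one$statistic == "sd"], 0)
})
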