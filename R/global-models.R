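#' Leave-one-participant-out folds
#'
#' One fold per participant: the test fold holds exactly all of that
#' participant's strides and its participant never appears in the train
#' fold, so folds partition the table.
#'
#' @param ft A feature table.
#' @return List of folds, each \code{list(train = <participant ids>,
#'   test = <participant id>)}.
#' @export
lopo_splits <- function(ft) {
  participants <- unique(as.character(ft$participant))
  if (length(participants) < 2) stop("need at least 2 participants for LOPO")
  lapply(participants, function(p)
    list(train = setdiff(participants, p), test = p))
}

#' Rank (Mann-Whitney) AUC
#'
#' Probability that a random class-1 score exceeds a random class-0 score,
#' with ties counted one half.
#'
#' @param scores_pos Scores of the positive (class-1) examples.
#' @param scores_neg Scores of the negative (class-0) examples.
#' @return AUC in [0, 1]; \code{NA} when either class is empty.
#' @export
auc_rank <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_metrics <- function(truth, predicted, scores) {
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = mean(predicted == truth),
    f1 = f1,
    auc = auc_rank(scores[truth == 1], scores[truth == 0]))
}

# Standardize columns by train-fold statistics only (leakage guard);
# zero-variance columns are left centred with unit divisor.
fold_standardizer <- function(train_x) {
  centre <- colMeans(train_x)
  scale <- apply(train_x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  function(x) sweep(sweep(x, 2, centre), 2, scale, "/")
}

median_distance_gamma <- function(x, max_points = 200L) {
  if (nrow(x) > max_points) x <- x[seq_len(max_points), , drop = FALSE]
  d <- stats::dist(x)
  sigma <- stats::median(d[d > 0])
  if (!is.finite(sigma) || sigma == 0) return(1 / ncol(x))
  1 / (2 * sigma^2)
}

fit_predict_model <- function(model, train_x, train_y, test_x, seed) {
  set.seed(seed)
  if (model == "rf") {
    fit <- randomForest::randomForest(train_x, factor(train_y, levels = 0:1),
                                      ntree = 300)
    scores <- stats::predict(fit, test_x, type = "prob")[, "1"]
    list(scores = scores, predicted = as.integer(scores > 0.5),
         importance = randomForest::importance(fit)[, 1])
  } else if (model == "svm") {
    fit <- e1071::svm(train_x, factor(train_y, levels = 0:1),
                      kernel = "radial", cost = 1,
                      gamma = median_distance_gamma(train_x), scale = FALSE)
    pred <- stats::predict(fit, test_x, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # decision values are oriented "first/second" class of the colname
    scores <- if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
    list(scores = scores, predicted = as.integer(as.character(pred)),
         importance = NULL)
  } else if (model == "gb") {
    dtrain <- xgboost::xgb.DMatrix(train_x, label = train_y)
    fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                            eta = 0.1, nthread = 1),
                              data = dtrain, nrounds = 200)
    scores <- stats::predict(fit, xgboost::xgb.DMatrix(test_x))
    list(scores = scores, predicted = as.integer(scores > 0.5),
         importance = NULL)
  } else stop("unknown model: ", model)
}

#' Train and evaluate a global classifier under LOPO cross-validation
#'
#' For each fold, features are standardized using train-fold statistics
#' only, the model is fitted on all training participants' strides and
#' evaluated on the held-out participant. Per-participant accuracy, F1 and
#' rank AUC are reported together with their arithmetic mean and SD across
#' participants (never stride-pooled). Random-forest feature importances
#' are averaged over folds and ranked.
#'
#' @param ft A feature table.
#' @param model One of "rf" (random forest, 300 trees), "svm" (RBF SVM,
#'   C = 1, bandwidth by the median-distance heuristic) or "gb" (gradient
#'   boosting, 200 stages, learning rate 0.1).
#' @param folds Folds from \code{\link{lopo_splits}}.
#' @param features Feature columns to use (default: the base 64 moment
#'   features).
#' @param seed Integer seed for the model fits.
#' @return Object of class \code{lopo_result}: list with \code{model},
#'   \code{per_participant} (data frame), \code{summary} (mean/sd rows) and
#'   \code{importance} (ranked data frame, RF only).
#' @export
train_eval_feature_model <- function(ft, model = c("rf", "svm", "gb"),
                                     folds = lopo_splits(ft),
                                     features = base_feature_names(ft),
                                     seed = 1L) {
  model <- match.arg(model)
  X <- as.matrix(ft[, features])
  y <- as.integer(ft$condition)
  pid <- as.character(ft$participant)
  rows <- list()
  importances <- list()
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    tr <- pid %in% fold$train
    te <- pid == fold$test
    if (length(unique(y[tr])) < 2) {
      warning("fold ", fold$test, " skipped: single-class training data")
      next
    }
    std <- fold_standardizer(X[tr, , drop = FALSE])
    out <- fit_predict_model(model, std(X[tr, , drop = FALSE]), y[tr],
                             std(X[te, , drop = FALSE]), seed + i)
    m <- binary_metrics(y[te], out$predicted, out$scores)
    rows[[fold$test]] <- data.frame(participant = fold$test,
                                    n_strides = sum(te),
                                    accuracy = m[["accuracy"]],
                                    f1 = m[["f1"]], auc = m[["auc"]])
    if (!is.null(out$importance)) importances[[fold$test]] <- out$importance
  }
  per <- do.call(rbind, c(rows, make.row.names = FALSE))
  metric_cols <- c("accuracy", "f1", "auc")
  summary <- data.frame(
    statistic = c("mean", "sd"),
    rbind(colMeans(per[, metric_cols], na.rm = TRUE),
          apply(per[, metric_cols], 2, stats::sd, na.rm = TRUE)))
  importance <- NULL
  if (length(importances)) {
    imp <- rowMeans(do.call(cbind, importances))
    importance <- data.frame(feature = names(imp), importance = unname(imp))
    importance <- importance[order(-importance$importance), ]
    rownames(importance) <- NULL
  }
  structure(list(model = model, per_participant = per, summary = summary,
                 importance = importance),
            class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("Global %s model, LOPO over %d participants: mean accuracy %.4f (sd %.4f)\n",
              x$model, nrow(x$per_participant),
              x$summary$accuracy[1], x$summary$accuracy[2]))
  invisible(x)
}

#' Shallow 1D-CNN stage on raw stride tensors (optional)
#'
#' Population-level classification on the raw \code{N x 8} stride windows
#' with a shallow one-dimensional convolutional network. The stage requires
#' an optional deep-learning backend (the \pkg{torch} package); when the
#' backend is not installed the stage is cleanly disabled and the pipeline
#' proceeds without it.
#'
#' @param windows A \code{stride_windows} object.
#' @param folds LOPO folds.
#' @param config Architecture/training configuration (unused when the
#'   stage is disabled).
#' @return A \code{cnn_result}: either a disabled-status marker (no
#'   backend) or LOPO metrics analogous to
#'   \code{\link{train_eval_feature_model}}.
#' @export
train_eval_cnn <- function(windows, folds, config = list()) {
  if (!requireNamespace("torch", quietly = TRUE)) {
    message("CNN stage disabled: no deep-learning backend installed")
    return(structure(list(status = "disabled",
                          reason = "deep-learning backend (torch) not installed"),
                     class = "cnn_result"))
  }
  stop("CNN stage: backend present but architecture support is not bundled ",
       "in this release; use the feature-based models")
}
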