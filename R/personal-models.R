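#' Stratified fold assignment
#'
#' Assigns fold ids 1..K so that each class is spread across folds by
#' shuffled round robin; per-fold class proportions match the overall
#' proportions within one stride.
#'
#' @param y 0/1 class labels.
#' @param K Number of folds.
#' @return Integer vector of fold ids, same length as \code{y}.
#' @export
stratified_folds <- function(y, K) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(K), length(idx))
  }
  folds
}

#' Within-participant supervised cross-validation
#'
#' Trains a random-forest classifier on one participant's own NF and F
#' strides under stratified K-fold cross-validation; features are
#' standardized inside each fold with train-fold statistics. Metrics are
#' averaged over folds.
#'
#' @param ft_one Feature table restricted to one participant, both
#'   conditions present.
#' @param K Number of folds (default 5); reduced with a warning (floor 2)
#'   when a class has fewer than K strides.
#' @param features Feature columns (default base moment features).
#' @param seed Integer seed.
#' @param ntree Random-forest size (default 300).
#' @return Object of class \code{personal_supervised_result}: one-row data
#'   frame with participant id, stride counts (total, F, NF) and
#'   cross-validated accuracy, F1 and AUC.
#' @export
personal_supervised_cv <- function(ft_one, K = 5L,
                                   features = base_feature_names(ft_one),
                                   seed = 1L, ntree = 300L) {
  pid <- unique(as.character(ft_one$participant))
  if (length(pid) != 1) stop("ft_one must hold exactly one participant")
  y <- as.integer(ft_one$condition)
  n_f <- sum(y == 1); n_nf <- sum(y == 0)
  if (n_f == 0 || n_nf == 0) stop("both conditions must be present")
  min_class <- min(n_f, n_nf)
  if (min_class < K) {
    K <- max(2L, min_class)
    warning("class with fewer than K members; K reduced to ", K)
  }
  X <- as.matrix(ft_one[, features])
  set.seed(seed)
  folds <- stratified_folds(y, K)
  fold_metrics <- matrix(NA_real_, K, 3,
                         dimnames = list(NULL, c("accuracy", "f1", "auc")))
  for (k in seq_len(K)) {
    tr <- folds != k; te <- !tr
    std <- fold_standardizer(X[tr, , drop = FALSE])
    fit <- randomForest::randomForest(std(X[tr, , drop = FALSE]),
                                      factor(y[tr], levels = 0:1),
                                      ntree = ntree)
    scores <- stats::predict(fit, std(X[te, , drop = FALSE]), type = "prob")[, "1"]
    fold_metrics[k, ] <- binary_metrics(y[te], as.integer(scores > 0.5), scores)
  }
  res <- data.frame(participant = pid, n_strides = length(y),
                    n_f = n_f, n_nf = n_nf,
                    cv_accuracy = mean(fold_metrics[, "accuracy"]),
                    cv_f1 = mean(fold_metrics[, "f1"]),
                    cv_auc = mean(fold_metrics[, "auc"], na.rm = TRUE))
  structure(res, class = c("personal_supervised_result", "data.frame"))
}

#' Fit a non-fatigued-baseline one-class SVM
#'
#' Learns a boundary around one participant's non-fatigued strides with an
#' RBF one-class SVM; fatigued strides are later flagged as anomalies
#' (deviations from the NF baseline). Features are standardized with
#' NF-only statistics and the scaler travels with the model, so fatigued
#' rows never influence the fit.
#'
#' @param nf_rows Feature rows (matrix or data frame) of the participant's
#'   NF strides only; at least 20 rows.
#' @param nu One-class SVM \eqn{\nu} (upper bound on the training outlier
#'   fraction; default 0.1).
#' @param gamma RBF bandwidth; default \code{1/p} on the standardized
#'   features (p = number of features, unit feature variance).
#' @return Object of class \code{ocsvm_model} carrying the fit, scaler and
#'   feature registry.
#' @export
fit_nf_ocsvm <- function(nf_rows, nu = 0.1, gamma = NULL) {
  X <- as.matrix(nf_rows)
  if (nrow(X) < 20)
    stop("need at least 20 NF strides to fit a baseline model; ",
         "collect more non-fatigued data")
  std <- fold_standardizer(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  fit <- e1071::svm(std(X), y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, standardize = std, nu = nu, gamma = gamma,
                 features = colnames(X)),
            class = "ocsvm_model")
}

#' Evaluate a baseline model on all strides of a participant
#'
#' Scores every stride against the NF-only boundary; strides outside the
#' boundary are anomalies (fatigue candidates, the positive class).
#' Reports recall on F strides, false-positive rate on NF strides,
#' accuracy and F1 with anomaly as the positive class, and rank AUC of the
#' continuous decision score oriented so that more anomalous means more
#' F-like. The binary view uses the fitted boundary's native zero level as
#' the threshold.
#'
#' @param model An \code{ocsvm_model}.
#' @param ft_one Feature table rows of the same participant (both
#'   conditions), sharing the model's feature registry.
#' @return Object of class \code{personal_anomaly_result}: one-row data
#'   frame with participant id, stride counts, accuracy, F1, AUC, recall
#'   on F and FPR on NF.
#' @export
evaluate_anomaly <- function(model, ft_one) {
  stopifnot(inherits(model, "ocsvm_model"))
  if (!all(model$features %in% names(ft_one)))
    stop("feature registry mismatch between model and rows")
  pid <- unique(as.character(ft_one$participant))
  if (length(pid) != 1) stop("ft_one must hold exactly one participant")
  X <- model$standardize(as.matrix(ft_one[, model$features]))
  y <- as.integer(ft_one$condition)
  pred <- stats::predict(model$fit, X, decision.values = TRUE)
  anomaly <- as.integer(!as.logical(pred))        # outside boundary
  score <- -as.numeric(attr(pred, "decision.values"))  # higher = more anomalous
  m <- binary_metrics(y, anomaly, score)
  res <- data.frame(participant = pid, n_strides = length(y),
                    n_f = sum(y == 1), n_nf = sum(y == 0),
                    accuracy = m[["accuracy"]], f1 = m[["f1"]],
                    auc = m[["auc"]],
                    recall_f = mean(anomaly[y == 1] == 1),
                    fpr_nf = mean(anomaly[y == 0] == 1))
  structure(res, class = c("personal_anomaly_result", "data.frame"))
}

#' Aggregate per-participant results to a cohort summary
#'
#' @param results Data frame of per-participant rows (or list of such
#'   rows, which are bound together).
#' @param metrics Metric column names to summarize; defaults to all
#'   numeric columns except stride counts.
#' @return Data frame with one row per statistic (mean, sd, min, max) and
#'   one column per metric; the mean row is the arithmetic mean of the
#'   per-participant column.
#' @export
aggregate_personal <- function(results, metrics = NULL) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, c(results, make.row.names = FALSE))
  if (nrow(results) < 1) stop("need at least one per-participant result")
  if (is.null(metrics)) {
    num <- names(results)[vapply(results, is.numeric, logical(1))]
    metrics <- setdiff(num, c("n_strides", "n_f", "n_nf"))
  }
  stats_fun <- list(mean = mean,
                    sd = function(v) if (length(v) > 1) stats::sd(v) else 0,
                    min = min, max = max)
  out <- data.frame(statistic = names(stats_fun))
  for (m in metrics) {
    v <- results[[m]]
    out[[m]] <- vapply(stats_fun, function(f) f(v[is.finite(v)]), numeric(1))
  }
  out
}
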