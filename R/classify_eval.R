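# Classifier training, confusion-matrix metrics and the multi-run
# comparison protocol. The positive class is OSCC (label 1) throughout.

#' Data-splitting plan
#'
#' @param train_fraction fraction of each class assigned to training
#'   (strictly between 0 and 1).
#' @param cv_folds folds available for cross-validation within the training
#'   partition (>= 2).
#' @param stratified preserve class proportions (always recommended).
#' @param seed integer seed for the split.
#' @return list of class `split_plan`.
#' @export
split_plan <- function(train_fraction = 0.8, cv_folds = 10L,
                       stratified = TRUE, seed = 0L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_plan")
}

# Stratified train/validation index split at train_fraction; per-class
# training count is floor(train_fraction * n_c). Draws from current RNG.
stratified_holdout <- function(labels, train_fraction) {
  train <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < 2L)
      stop("class ", cl, " has fewer than 2 members", call. = FALSE)
    n_tr <- floor(train_fraction * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train <- c(train, sample(idx, n_tr))
  }
  list(train = sort(train), val = setdiff(seq_along(labels), train))
}

#' Stratified train/test split
#'
#' Splits a feature dataset into disjoint, exhaustive train and test
#' partitions, preserving class proportions: each class contributes
#' `floor(train_fraction * n_class)` samples to training and the remainder
#' to test. Seeded and reproducible.
#'
#' @param data a [feature_dataset()] with both classes present.
#' @param plan a [split_plan()].
#' @return list with `train` and `test` feature datasets and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_data <- function(data, plan = split_plan()) {
  stopifnot(inherits(data, "feature_dataset"))
  if (length(unique(data$labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  idx <- with_seed(plan$seed,
                   stratified_holdout(data$labels, plan$train_fraction))
  list(train = data[idx$train, ], test = data[idx$val, ],
       train_idx = idx$train, test_idx = idx$val)
}

#' Train a binary classifier
#'
#' Fits one of three classifier families on a feature dataset: gradient
#' boosted trees (XGBoost), random forest, or a single-hidden-layer neural
#' network. Hyperparameters default to the libraries' standard settings
#' with fixed seeds; anything can be overridden through `hyperparams`.
#'
#' @param train training [feature_dataset()].
#' @param kind one of `"xgboost"`, `"random_forest"`, `"ann"`.
#' @param hyperparams named list of overrides passed to the underlying
#'   fitting function.
#' @param seed integer seed making the fit reproducible.
#' @return object of class `cad_classifier` with a [predict][stats::predict]
#'   method returning 0/1 labels.
#' @export
train_classifier <- function(train, kind = c("xgboost", "random_forest", "ann"),
                             hyperparams = list(), seed = 0L) {
  stopifnot(inherits(train, "feature_dataset"))
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown classifier kind: ",
                                            kind[1], call. = FALSE))
  if (length(unique(train$labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  model <- with_seed(seed, switch(kind,
    xgboost = {
      args <- utils::modifyList(
        list(x = train$x, y = factor(train$labels, levels = c(0, 1)),
             nrounds = 50L, nthreads = 1L, verbosity = 0L),
        hyperparams)
      do.call(xgboost::xgboost, args)
    },
    random_forest = {
      args <- utils::modifyList(
        list(x = train$x, y = factor(train$labels, levels = c(0, 1)),
             ntree = 200L),
        hyperparams)
      do.call(randomForest::randomForest, args)
    },
    ann = {
      args <- utils::modifyList(
        list(x = train$x, y = train$labels, size = 8L, decay = 1e-2,
             maxit = 200L, entropy = TRUE, trace = FALSE,
             MaxNWts = 100000L),
        hyperparams)
      do.call(nnet::nnet, args)
    }))
  structure(list(kind = kind, model = model, seed = as.integer(seed),
                 n_features = ncol(train$x)),
            class = "cad_classifier")
}

#' Predict 0/1 labels from a trained classifier
#'
#' @param object a [train_classifier()] fit.
#' @param newdata a [feature_dataset()] or numeric matrix with the same
#'   feature columns used in training.
#' @param ... unused.
#' @return integer vector of 0/1 predictions.
#' @export
predict.cad_classifier <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_dataset")) newdata$x else as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop("newdata has ", ncol(x), " features; model expects ",
         object$n_features, call. = FALSE)
  switch(object$kind,
    xgboost = {
      p <- stats::predict(object$model, x)
      if (is.matrix(p)) p <- p[, ncol(p)]
      as.integer(p >= 0.5)
    },
    random_forest =
      as.integer(as.character(stats::predict(object$model, x))),
    ann = as.integer(stats::predict(object$model, x) >= 0.5))
}

#' @export
print.cad_classifier <- function(x, ...) {
  cat("cad_classifier:", x$kind, "on", x$n_features, "features (seed",
      paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Confusion counts with OSCC as the positive class
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  cnt <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(lapply(as.list(cnt), as.integer), class = "confusion_counts")
}

#' Evaluate a classifier on a test partition
#'
#' Tallies the 2 x 2 confusion matrix with OSCC (label 1) as the positive
#' class: TP = OSCC predicted OSCC, TN = NEOR predicted NEOR.
#'
#' @param model a trained `cad_classifier` (or any object whose `predict`
#'   returns 0/1 labels).
#' @param test a [feature_dataset()].
#' @return a [confusion_counts()].
#' @export
evaluate <- function(model, test) {
  pred <- stats::predict(model, test)
  tally_confusion(pred, test$labels)
}

#' Tally confusion counts from predictions and truth
#'
#' @param pred 0/1 predicted labels.
#' @param truth 0/1 true labels (1 = OSCC, the positive class).
#' @return a [confusion_counts()].
#' @export
tally_confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("prediction/label length mismatch", call. = FALSE)
  confusion_counts(TP = sum(pred == 1L & truth == 1L),
                   TN = sum(pred == 0L & truth == 0L),
                   FP = sum(pred == 1L & truth == 0L),
                   FN = sum(pred == 0L & truth == 1L))
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TN, x$FP, x$FN, x$TP), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("NEOR", "OSCC"),
                              predicted = c("NEOR", "OSCC")))
  print(m)
  invisible(x)
}

#' Sensitivity, precision and accuracy from confusion counts
#'
#' Computes, as percentages:
#' sensitivity = TP / (TP + FN) x 100,
#' precision   = TP / (TP + FP) x 100,
#' accuracy    = (TP + TN) / (TP + TN + FP + FN) x 100.
#' A metric with a zero denominator is flagged undefined (`NA`), never
#' silently reported as zero.
#'
#' @param counts a [confusion_counts()].
#' @return list of class `metrics_report` with `sensitivity`, `precision`,
#'   `accuracy` (percent, full precision) and `undefined` (character vector
#'   naming any undefined metric). Printing rounds to one decimal.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  undefined <- character(0)
  sens <- if (counts$TP + counts$FN > 0)
    100 * counts$TP / (counts$TP + counts$FN)
  else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  prec <- if (counts$TP + counts$FP > 0)
    100 * counts$TP / (counts$TP + counts$FP)
  else { undefined <- c(undefined, "precision"); NA_real_ }
  acc <- if (n > 0) 100 * (counts$TP + counts$TN) / n
  else { undefined <- c(undefined, "accuracy"); NA_real_ }
  structure(list(sensitivity = sens, precision = prec, accuracy = acc,
                 counts = counts, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  sensitivity %.1f%%  precision %.1f%%\n",
              x$accuracy, x$sensitivity, x$precision))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Compare two sets of per-run accuracies
#'
#' Two-sample Welch t-test on per-run accuracy vectors, the protocol used
#' to decide whether one configuration is significantly better than
#' another over independent runs (significance at p < 0.05).
#'
#' @param acc_a,acc_b numeric vectors of per-run accuracies (length >= 2).
#' @return the [stats::t.test()] result (`htest`).
#' @export
compare_runs <- function(acc_a, acc_b) {
  if (length(acc_a) < 2L || length(acc_b) < 2L)
    stop("need at least 2 runs per group", call. = FALSE)
  if (stats::sd(acc_a) == 0 && stats::sd(acc_b) == 0) {
    # zero within-group variance: the t statistic is 0 (equal means) or
    # infinite, degenerate for t.test(); report the limit directly
    d <- mean(acc_a) - mean(acc_b)
    tstat <- if (d == 0) 0 else sign(d) * Inf
    return(structure(list(statistic = c(t = tstat),
                          p.value = if (d == 0) 1 else 0,
                          estimate = c(`mean of x` = mean(acc_a),
                                       `mean of y` = mean(acc_b)),
                          method = "Welch Two Sample t-test (zero-variance limit)",
                          data.name = "acc_a and acc_b"),
                     class = "htest"))
  }
  stats::t.test(acc_a, acc_b, var.equal = FALSE)
}
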