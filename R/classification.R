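# Classification harness: stratified splits, standard classifiers,
# n-fold cross-validation on descriptor feature matrices.

#' Labeled feature matrix from a descriptor database
#'
#' @param db A [descriptor_db()] whose entries carry group labels.
#' @return List `x` (matrix) and `y` (factor of group labels).
#' @export
labeled_features <- function(db) {
  stopifnot(inherits(db, "descriptor_db"))
  if (anyNA(db$ids$group)) stop_sp("database entries without group labels")
  if (anyNA(db$vectors)) stop_sp("NaN/NA rows in the feature matrix")
  list(x = db$vectors, y = factor(db$ids$group))
}

#' Stratified train/test split
#'
#' Draws `n_train` and `n_test` disjoint rows without replacement,
#' stratifying both sets by class label (per-class counts proportional to
#' class frequencies, largest-remainder apportionment). Reproducible given
#' `seed`.
#'
#' @param x Feature matrix (rows = chains).
#' @param y Class labels, one per row.
#' @param n_train,n_test Set sizes; their sum must not exceed `nrow(x)`.
#' @param seed Integer RNG seed.
#' @return List with `train` and `test` (each `x`, `y`) plus the row
#'   indices `train_idx`, `test_idx`.
#' @export
split_train_test <- function(x, y, n_train, n_test, seed = 1L) {
  y <- factor(y)
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (n_train + n_test > n) stop_sp("n_train + n_test exceeds %d rows", n)
  counts <- table(y)
  n_tr <- apportion(counts, n_train)
  if (any(n_tr == 0L)) {
    stop_sp("training draw leaves class(es) empty: %s",
            paste(names(counts)[n_tr == 0L], collapse = ", "))
  }
  # test allocation is proportional to what the training draw left over,
  # so the two stratified draws can never exceed a class's size
  n_te <- apportion(counts - n_tr, n_test)
  if (any(n_tr + n_te > counts)) {
    stop_sp("stratified draw exceeds the size of class(es): %s",
            paste(names(counts)[n_tr + n_te > counts], collapse = ", "))
  }
  train_idx <- integer(0)
  test_idx <- integer(0)
  set.seed(seed)
  for (cl in names(counts)) {
    rows <- which(y == cl)
    picked <- rows[sample.int(length(rows), n_tr[[cl]] + n_te[[cl]])]
    train_idx <- c(train_idx, picked[seq_len(n_tr[[cl]])])
    test_idx <- c(test_idx, picked[-seq_len(n_tr[[cl]])])
  }
  train_idx <- sort(train_idx)
  test_idx <- sort(test_idx)
  list(train = list(x = x[train_idx, , drop = FALSE], y = y[train_idx]),
       test = list(x = x[test_idx, , drop = FALSE], y = y[test_idx]),
       train_idx = train_idx, test_idx = test_idx)
}

# Largest-remainder apportionment of `total` draws across classes
# proportionally to their sizes; deterministic (alphabetical tie-break).
apportion <- function(counts, total) {
  quota <- total * as.numeric(counts) / sum(counts)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0L) {
    ord <- order(-(quota - base), names(counts))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  stats::setNames(as.integer(base), names(counts))
}

#' Train a standard classifier and score it on a test set
#'
#' Fits one of three standard classifiers on the training descriptors and
#' returns the fraction of test rows labeled correctly. `"naive_bayes"` is
#' Gaussian naive Bayes (e1071), `"logistic"` is multinomial logistic
#' regression (nnet), and `"simple_logistic"` is L2-regularized multinomial
#' logistic regression (glmnet, alpha = 0, lambda = 0.01) — a documented
#' approximation of the boosted simple logistic classifier, not claimed
#' equivalent. Constant feature columns in the training set are dropped
#' from both sets before fitting.
#'
#' @param train,test Lists with `x` (matrix) and `y` (labels), as produced
#'   by [split_train_test()].
#' @param classifier `"logistic"`, `"naive_bayes"` or `"simple_logistic"`.
#' @return Classification rate in `[0, 1]`.
#' @export
train_and_score <- function(train, test,
                            classifier = c("logistic", "naive_bayes",
                                           "simple_logistic")) {
  classifier <- match.arg(classifier)
  y_tr <- factor(train$y)
  if (nlevels(y_tr) < 2L) stop_sp("training set has a single class")
  if (ncol(train$x) != ncol(test$x)) {
    stop_sp("train/test feature length mismatch: %d vs %d",
            ncol(train$x), ncol(test$x))
  }
  keep <- apply(train$x, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop_sp("all training features are constant")
  x_tr <- train$x[, keep, drop = FALSE]
  x_te <- test$x[, keep, drop = FALSE]
  colnames(x_tr) <- colnames(x_te) <- paste0("f", seq_len(ncol(x_tr)))
  pred <- switch(
    classifier,
    naive_bayes = {
      fit <- e1071::naiveBayes(x_tr, y_tr)
      stats::predict(fit, x_te)
    },
    logistic = {
      df_tr <- data.frame(.y = y_tr, x_tr, check.names = FALSE)
      fit <- nnet::multinom(.y ~ ., data = df_tr, trace = FALSE,
                            MaxNWts = 100000L, maxit = 200L)
      stats::predict(fit, newdata = data.frame(x_te, check.names = FALSE))
    },
    simple_logistic = {
      fit <- glmnet::glmnet(x_tr, y_tr, family = "multinomial",
                            alpha = 0, lambda = 0.01)
      drop(stats::predict(fit, x_te, s = 0.01, type = "class"))
    }
  )
  mean(as.character(pred) == as.character(test$y))
}

#' Stratified n-fold cross-validation
#'
#' @param x Feature matrix.
#' @param y Class labels.
#' @param n_folds Number of folds (>= 2, at most the smallest class size).
#' @param classifier See [train_and_score()].
#' @param seed Integer RNG seed for the fold assignment.
#' @return Mean classification rate over folds, with the per-fold rates as
#'   attribute `folds`.
#' @export
cross_validate <- function(x, y, n_folds = 10L,
                           classifier = c("logistic", "naive_bayes",
                                          "simple_logistic"),
                           seed = 1L) {
  classifier <- match.arg(classifier)
  y <- factor(y)
  if (n_folds < 2L) stop_sp("n_folds must be >= 2")
  if (n_folds > min(table(y))) {
    stop_sp("n_folds (%d) exceeds the smallest class size (%d)",
            n_folds, min(table(y)))
  }
  set.seed(seed)
  fold <- integer(nrow(x))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    perm <- rows[sample.int(length(rows), length(rows))]
    fold[perm] <- rep_len(seq_len(n_folds), length(rows))
  }
  rates <- vapply(seq_len(n_folds), function(k) {
    train_and_score(
      train = list(x = x[fold != k, , drop = FALSE], y = y[fold != k]),
      test = list(x = x[fold == k, , drop = FALSE], y = y[fold == k]),
      classifier = classifier
    )
  }, numeric(1))
  structure(mean(rates), folds = rates)
}
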