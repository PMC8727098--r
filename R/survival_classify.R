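## Survival classification under stratified k-fold cross-validation.
##
## AdaBoost is implemented here from its weight-update equations (discrete
## two-class boosting): the round error is the weight-sum over misclassified
## instances, the round's vote is log((1-err)/err), and correctly classified
## instances have their weights multiplied by err/(1-err) before
## renormalization. Weak learners are depth-limited classification trees
## (rpart). Bagging and random forests delegate to randomForest, gradient
## boosting to xgboost, and the statistical baseline to stats::glm.

#' Model specification
#'
#' Hyperparameter defaults mirror the study's experimental settings:
#' bagging over decision trees with up to 139 splits; AdaBoost with at most
#' 20 splits per weak learner and learning rate 0.1; random forest with
#' random seed 0 and unlimited depth; gradient boosting with 100 trees;
#' unpenalized logistic regression.
#'
#' @param method One of "bagging", "adaboost", "random_forest",
#'   "gradient_boosting", "logistic".
#' @param ... Hyperparameter overrides (`max_splits`, `learning_rate`,
#'   `n_estimators`, `seed`).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(method = c("adaboost", "bagging", "random_forest",
                                  "gradient_boosting", "logistic"), ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    bagging = list(max_splits = 139, n_estimators = 100, seed = 0),
    adaboost = list(max_splits = 20, learning_rate = 0.1,
                    n_estimators = 30, seed = 0),
    random_forest = list(n_estimators = 100, seed = 0),
    gradient_boosting = list(n_estimators = 100, seed = 0),
    logistic = list()
  )
  hp <- utils::modifyList(defaults, list(...))
  structure(list(method = method, hyperparameters = hp),
            class = "model_spec")
}

#' The study's model suite
#'
#' @return Named list of [model_spec()]s for bagging, AdaBoost, random
#'   forest, gradient boosting and logistic regression.
#' @export
default_model_specs <- function() {
  list(bagging = model_spec("bagging"),
       boosting = model_spec("adaboost"),
       random_forest = model_spec("random_forest"),
       gradient_boosting = model_spec("gradient_boosting"),
       logistic = model_spec("logistic"))
}

#' One AdaBoost reweighting round
#'
#' Given the current instance weights (positive, summing to 1) and the weak
#' learner's misclassification mask, returns the round error (weight-sum
#' over misclassified instances), the vote weight log((1-err)/err) (error 0
#' is clamped at 1e-10 so the vote stays finite), and the updated,
#' renormalized weights (correct instances scaled by err/(1-err)).
#'
#' @param instance_weights Positive weights summing to 1.
#' @param misclassified_mask Logical vector, TRUE where the weak learner
#'   erred.
#' @return List with `error`, `vote`, `weights`.
#' @export
adaboost_round <- function(instance_weights, misclassified_mask) {
  if (any(instance_weights <= 0) ||
      abs(sum(instance_weights) - 1) > 1e-8) {
    stop("instance_weights must be positive and sum to 1", call. = FALSE)
  }
  error <- sum(instance_weights[misclassified_mask])
  eps <- 1e-10
  err_c <- min(max(error, eps), 1 - eps)
  vote <- log((1 - err_c) / err_c)
  w <- instance_weights
  w[!misclassified_mask] <- w[!misclassified_mask] * (err_c / (1 - err_c))
  w <- w / sum(w)
  list(error = error, vote = vote, weights = w)
}

weak_tree_control <- function(max_splits) {
  ## rpart limits depth, not split count: a depth-d binary tree has at most
  ## 2^d - 1 internal splits, so depth floor(log2(max_splits + 1)) respects
  ## the split budget.
  depth <- max(1L, floor(log2(max_splits + 1)))
  rpart::rpart.control(maxdepth = depth, cp = 0, minsplit = 4, xval = 0,
                       maxsurrogate = 0, maxcompete = 0)
}

fit_adaboost <- function(x, y, max_splits = 20, learning_rate = 0.1,
                         n_estimators = 30, seed = 0) {
  set.seed(seed)
  n <- nrow(x)
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  ctl <- weak_tree_control(max_splits)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  retried <- FALSE
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctl)
    pred <- predict(fit, df, type = "class")
    miscl <- pred != df$.y
    error <- sum(w[miscl])
    if (error >= 0.5) {
      ## degenerate round: discard it, restart once from uniform weights
      if (retried) break
      retried <- TRUE
      w <- rep(1 / n, n)
      next
    }
    rnd <- adaboost_round(w, miscl)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, learning_rate * rnd$vote)
    if (error == 0) break
    w <- rnd$weights
  }
  structure(list(trees = trees, alphas = alphas), class = "ov_adaboost")
}

predict_adaboost <- function(model, x) {
  df <- as.data.frame(x)
  margin <- rep(0, nrow(df))
  for (m in seq_along(model$trees)) {
    pred <- predict(model$trees[[m]], df, type = "class")
    margin <- margin + model$alphas[m] * (2 * (pred == "1") - 1)
  }
  stats::plogis(margin)
}

#' Fit a model and score a test set
#'
#' Dispatches on the model method; every route returns class-1 (survived)
#' probabilities — AdaBoost margins are mapped through the logistic
#' function — and hard predictions at the 0.5 threshold.
#'
#' @param spec A [model_spec()].
#' @param train_x,train_y Training feature matrix and binary labels.
#' @param test_x Test feature matrix with the same columns.
#' @return List with numeric `scores` and integer `predictions`.
#' @export
fit_predict <- function(spec, train_x, train_y, test_x) {
  if (!identical(colnames(train_x), colnames(test_x))) {
    stop("train and test matrices must share feature names", call. = FALSE)
  }
  if (length(unique(train_y)) < 2) {
    stop("training data contains a single class; use stratified folds",
         call. = FALSE)
  }
  hp <- spec$hyperparameters
  scores <- switch(spec$method,
    adaboost = {
      model <- fit_adaboost(train_x, train_y, max_splits = hp$max_splits,
                            learning_rate = hp$learning_rate,
                            n_estimators = hp$n_estimators, seed = hp$seed)
      predict_adaboost(model, test_x)
    },
    bagging = {
      set.seed(hp$seed)
      fit <- randomForest::randomForest(
        x = as.data.frame(train_x), y = factor(train_y, levels = c(0, 1)),
        ntree = hp$n_estimators, mtry = max(1, ncol(train_x)),
        maxnodes = min(hp$max_splits + 1, nrow(train_x)))
      predict(fit, as.data.frame(test_x), type = "prob")[, "1"]
    },
    random_forest = {
      set.seed(hp$seed)
      fit <- randomForest::randomForest(
        x = as.data.frame(train_x), y = factor(train_y, levels = c(0, 1)),
        ntree = hp$n_estimators)
      predict(fit, as.data.frame(test_x), type = "prob")[, "1"]
    },
    gradient_boosting = {
      set.seed(hp$seed)
      dtrain <- xgboost::xgb.DMatrix(as.matrix(train_x), label = train_y,
                                     nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1,
                      seed = hp$seed),
        data = dtrain, nrounds = hp$n_estimators, verbose = 0)
      predict(fit, xgboost::xgb.DMatrix(as.matrix(test_x), nthread = 1))
    },
    logistic = {
      df <- as.data.frame(train_x)
      names(df) <- make.names(names(df))
      df$.y <- train_y
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      nd <- as.data.frame(test_x)
      names(nd) <- make.names(names(nd))
      suppressWarnings(as.numeric(predict(fit, nd, type = "response")))
    }
  )
  list(scores = as.numeric(scores),
       predictions = as.integer(scores > 0.5))
}

#' Stratified fold assignment
#'
#' Shuffles each class separately (fixed seed) and deals patients
#' round-robin into k folds, preserving class proportions to within one
#' patient per fold.
#'
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment in 1..k per patient.
#' @export
stratified_folds <- function(labels, k, seed) {
  counts <- table(labels)
  if (any(counts < k)) {
    stop(sprintf("smallest class has %d members; choose k <= %d",
                 min(counts), min(counts)), call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(labels))
  start <- 0L   # rotate the deal across classes so fold sizes differ by <= 1
  for (cl in names(counts)) {
    idx <- which(as.character(labels) == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + start) %% k) + 1L
    start <- (start + length(idx)) %% k
  }
  fold
}

#' Classification metrics
#'
#' Accuracy in percent, sensitivity (true positive rate, positive class =
#' survived = 1), specificity, and AUC via the Mann-Whitney rank statistic
#' (ties receive half credit), which equals the trapezoidal ROC area.
#'
#' @param predictions Integer 0/1 predictions.
#' @param scores Numeric class-1 scores.
#' @param labels Integer 0/1 truth.
#' @return List with `accuracy` (percent), `sensitivity`, `specificity`,
#'   `auc`.
#' @export
metrics_binary <- function(predictions, scores, labels) {
  stopifnot(length(predictions) == length(labels),
            length(scores) == length(labels))
  tp <- sum(predictions == 1 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  npos <- tp + fn
  nneg <- tn + fp
  if (npos == 0 || nneg == 0) {
    stop("AUC undefined: need both positive and negative labels",
         call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  list(accuracy = 100 * (tp + tn) / length(labels),
       sensitivity = tp / npos,
       specificity = tn / nneg,
       auc = auc)
}

#' Stratified k-fold cross-validation
#'
#' Each patient is predicted exactly once out-of-fold; pooled out-of-fold
#' predictions yield the headline metrics, and per-fold accuracies are
#' retained for paired significance testing.
#'
#' @param fm An `ov_features` with labels.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return Object of class `ov_cv`: fold assignment, per-fold accuracies,
#'   pooled predictions/scores and `metrics`.
#' @export
cross_validate <- function(fm, spec, k = 10, seed = 0) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  y <- fm$labels
  if (is.null(y)) stop("feature matrix carries no labels", call. = FALSE)
  fold <- stratified_folds(y, k, seed)
  n <- length(y)
  scores <- numeric(n)
  preds <- integer(n)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    out <- fit_predict(spec, fm$x[!te, , drop = FALSE], y[!te],
                       fm$x[te, , drop = FALSE])
    scores[te] <- out$scores
    preds[te] <- out$predictions
    fold_acc[f] <- mean(out$predictions == y[te])
  }
  structure(list(fold = fold, fold_accuracy = fold_acc,
                 predictions = preds, scores = scores, labels = y,
                 metrics = metrics_binary(preds, scores, y)),
            class = "ov_cv")
}

#' @export
print.ov_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("ov_cv: %d folds | accuracy %.1f%% | sensitivity %.3f",
                     " | specificity %.3f | AUC %.3f\n"),
              length(x$fold_accuracy), m$accuracy, m$sensitivity,
              m$specificity, m$auc))
  invisible(x)
}
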