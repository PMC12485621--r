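#' Specify a base binary classifier
#'
#' Three algorithm families are supported, each through its established
#' implementation: `"logistic"` (ridge-penalized logistic regression via
#' glmnet), `"random_forest"` (probability forest via ranger) and
#' `"xgboost"` (gradient-boosted trees). Hyperparameters not given fall back
#' to family defaults.
#'
#' @param algorithm one of `"logistic"`, `"random_forest"`, `"xgboost"`.
#' @param hyperparameters named list; see [default_search_space()] for the
#'   tunable names per family.
#' @param seed integer seed used by stochastic learners.
#' @return an object of class `binary_classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("logistic", "random_forest", "xgboost"),
                            hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  structure(
    list(algorithm = algorithm, hyperparameters = hyperparameters,
         seed = as.integer(seed)),
    class = "binary_classifier_spec"
  )
}

default_hyperparameters <- function(algorithm) {
  switch(algorithm,
    logistic      = list(lambda = 1e-2),
    random_forest = list(num_trees = 300, mtry_frac = 0.3, min_node_size = 2),
    xgboost       = list(eta = 0.1, max_depth = 4, nrounds = 150,
                         subsample = 0.9)
  )
}

# Fit one binary model. X: numeric matrix; y: 0/1 integer vector.
fit_binary <- function(X, y, spec) {
  if (length(unique(y)) < 2L) stop("both classes must be present to fit a binary classifier")
  hp <- utils::modifyList(default_hyperparameters(spec$algorithm),
                          spec$hyperparameters)
  model <- switch(spec$algorithm,
    logistic = {
      glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = 0, lambda = hp$lambda, standardize = TRUE)
    },
    random_forest = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = as.integer(hp$num_trees),
        mtry = max(1L, floor(hp$mtry_frac * ncol(X))),
        min.node.size = as.integer(hp$min_node_size),
        probability = TRUE, importance = "impurity",
        seed = spec$seed, num.threads = 1L
      )
    },
    xgboost = {
      withr::with_seed(spec$seed, {
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = hp$eta,
                        max_depth = as.integer(hp$max_depth),
                        subsample = hp$subsample, nthread = 1L,
                        seed = spec$seed),
          data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
          nrounds = as.integer(hp$nrounds), verbose = 0
        )
      })
    }
  )
  structure(list(algorithm = spec$algorithm, model = model, spec = spec,
                 feature_names = colnames(X)),
            class = "binary_model")
}

# Raw positive-class score in [0, 1] for each row of X.
predict_score <- function(model, X) {
  X <- X[, model$feature_names, drop = FALSE]
  switch(model$algorithm,
    linear_coef = as.numeric(   # JSON-restored logistic model
      stats::plogis(model$a0 + X %*% model$beta)),
    logistic = as.numeric(
      stats::predict(model$model, newx = X, type = "response")[, 1L]),
    random_forest = {
      p <- stats::predict(model$model, data = data.frame(X, check.names = FALSE),
                          num.threads = 1L)$predictions
      as.numeric(p[, "1"])
    },
    xgboost = as.numeric(
      stats::predict(model$model, xgboost::xgb.DMatrix(X, nthread = 1L)))
  )
}

# Native feature importance, named by feature. Linear models report
# |coefficient| on the standardized scale (|beta_j| * sd(x_j), sds from the
# training matrix); tree models report impurity / gain importance. Missing
# features score 0.
importance_scores <- function(model, feature_sds = NULL) {
  feats <- model$feature_names
  out <- stats::setNames(rep(0, length(feats)), feats)
  if (model$algorithm %in% c("logistic", "linear_coef")) {
    beta <- if (model$algorithm == "logistic") as.numeric(model$model$beta[, 1L])
            else as.numeric(model$beta)
    sds <- if (is.null(feature_sds)) rep(1, length(feats)) else feature_sds[feats]
    out[] <- abs(beta) * sds
  } else if (model$algorithm == "random_forest") {
    imp <- model$model$variable.importance
    out[names(imp)] <- pmax(imp, 0)
  } else if (model$algorithm == "xgboost") {
    imp <- xgboost::xgb.importance(model = model$model)
    if (nrow(imp)) out[imp$Feature] <- imp$Gain
  } else {
    stop("no feature-importance notion for algorithm '", model$algorithm, "'")
  }
  out
}

# Stratified fold assignment (1..k) keeping class proportions per fold.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Balanced accuracy of hard predictions.
balanced_accuracy <- function(y_true, y_pred) {
  mean(vapply(unique(y_true), function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1)))
}

# Out-of-fold raw scores from k-fold refits; returns list(scores, folds).
oof_scores <- function(X, y, spec, n_folds, seed) {
  folds <- stratified_folds(y, n_folds, seed)
  scores <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    hold <- folds == f
    if (!any(hold)) next
    m <- fit_binary(X[!hold, , drop = FALSE], y[!hold], spec)
    scores[hold] <- predict_score(m, X[hold, , drop = FALSE])
  }
  list(scores = scores, folds = folds)
}

#' Number of base classifiers per multiclass strategy
#'
#' One-vs-rest trains `k` binary classifiers for `k` classes; one-vs-one
#' trains one per unordered class pair, `k (k - 1) / 2`.
#'
#' @param k number of classes (>= 2).
#' @param strategy `"ovr"` or `"ovo"`.
#' @return integer classifier count.
#' @examples
#' count_classifiers(7, "ovr")  # 7
#' count_classifiers(7, "ovo")  # 21
#' @export
count_classifiers <- function(k, strategy = c("ovr", "ovo")) {
  strategy <- match.arg(strategy)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (strategy == "ovr") k else (k * (k - 1L)) %/% 2L
}
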