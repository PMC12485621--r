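#' Fit the calibrated one-vs-rest ensemble
#'
#' Trains one binary expert per population — that population as the
#' positive class against all others pooled — each wrapped with Platt
#' calibration fit on out-of-fold scores from a stratified k-fold refit.
#' Out-of-fold balanced accuracy and a mean mutual-information ingredient
#' are recorded per expert for the attention weighting.
#'
#' @param X one-hot feature matrix (training rows).
#' @param labels integer class codes `0 .. k-1`; every class must be
#'   present.
#' @param specs a single [classifier_spec()] recycled over populations, or
#'   a list of `k` specs; `"auto"` (a character scalar) tunes nothing but
#'   picks, per expert, the family with the best CV balanced accuracy among
#'   the three defaults.
#' @param classes character names of the classes, index order.
#' @param calibration_folds stratified folds for out-of-fold calibration
#'   scores (default 5).
#' @param seed integer seed.
#' @return an object of class `ovr_ensemble`: per-expert models,
#'   calibration parameters, out-of-fold metrics and probabilities, and the
#'   class order.
#' @export
fit_ovr <- function(X, labels, specs = classifier_spec("logistic"),
                    classes = NULL, calibration_folds = 5L, seed = 1L) {
  labels <- as.integer(labels)
  k <- if (is.null(classes)) max(labels) + 1L else length(classes)
  if (k < 2L) stop("need at least 2 classes")
  if (is.null(classes)) classes <- paste0("class", seq_len(k) - 1L)
  absent <- setdiff(seq_len(k) - 1L, unique(labels))
  if (length(absent)) {
    stop("class absent from training data: ",
         paste(classes[absent + 1L], collapse = ", "))
  }
  if (inherits(specs, "binary_classifier_spec")) {
    specs <- rep(list(specs), k)
  } else if (identical(specs, "auto")) {
    specs <- "auto"
  } else if (length(specs) != k) {
    stop("specs must be one spec, a list of k specs, or \"auto\"")
  }

  experts <- vector("list", k)
  oof_probs <- matrix(NA_real_, nrow(X), k, dimnames = list(rownames(X), classes))
  for (c in seq_len(k)) {
    y <- as.integer(labels == (c - 1L))
    spec_c <- if (identical(specs, "auto")) {
      pick_best_family(X, y, calibration_folds, seed + c)
    } else specs[[c]]
    oo <- oof_scores(X, y, spec_c, calibration_folds, seed + c)
    calib <- platt_fit(oo$scores, y, n_folds = 3L)
    p_oof <- platt_apply(calib, oo$scores)
    bal <- balanced_accuracy(y, as.integer(p_oof >= 0.5))
    final <- fit_binary(X, y, spec_c)
    experts[[c]] <- list(
      class = classes[c], spec = spec_c, model = final, calibration = calib,
      oof_balanced_accuracy = bal,
      mean_mi = mean(mi_binary_columns(X, y))
    )
    oof_probs[, c] <- p_oof
  }
  mi_raw <- vapply(experts, `[[`, numeric(1), "mean_mi")
  mi_norm <- if (max(mi_raw) > 0) mi_raw / max(mi_raw) else mi_raw
  structure(
    list(experts = experts, classes = classes, k = k,
         feature_names = colnames(X),
         feature_sds = apply(X, 2L, stats::sd),
         oof_probs = oof_probs,
         metrics = vapply(experts, `[[`, numeric(1), "oof_balanced_accuracy"),
         mi_scores = mi_norm,
         seed = as.integer(seed)),
    class = "ovr_ensemble"
  )
}

# Default-spec CV comparison of the three families; returns the winner.
pick_best_family <- function(X, y, n_folds, seed) {
  families <- c("logistic", "random_forest", "xgboost")
  folds <- stratified_folds(y, n_folds, seed)
  score <- vapply(families, function(fam) {
    spec <- classifier_spec(fam, seed = seed)
    accs <- vapply(seq_len(n_folds), function(f) {
      hold <- folds == f
      if (!any(hold) || length(unique(y[!hold])) < 2L) return(NA_real_)
      m <- fit_binary(X[!hold, , drop = FALSE], y[!hold], spec)
      balanced_accuracy(y[hold],
                        as.integer(predict_score(m, X[hold, , drop = FALSE]) >= 0.5))
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  classifier_spec(families[which.max(score)], seed = seed)
}

#' Calibrated one-vs-rest probabilities for new samples
#'
#' @param ensemble a [fit_ovr()] result.
#' @param X one-hot matrix over the ensemble's feature space.
#' @return numeric matrix `n x k` of calibrated positive-class
#'   probabilities (one column per population, ensemble class order).
#' @export
ovr_probabilities <- function(ensemble, X) {
  probs <- vapply(ensemble$experts, function(e) {
    platt_apply(e$calibration, predict_score(e$model, X))
  }, numeric(nrow(X)))
  probs <- matrix(probs, nrow = nrow(X),
                  dimnames = list(rownames(X), ensemble$classes))
  probs
}

#' Train the full OvR-attention classifier on a haplotype table
#'
#' End-to-end trainer for the package's core method: encodes the labels,
#' fits the allele vocabulary and one-hot matrix on the training table,
#' fits the calibrated one-vs-rest ensemble, computes attention weights
#' from each expert's out-of-fold balanced accuracy and mutual-information
#' ingredient, and trains the fully connected meta-network on the fused
#' out-of-fold probabilities (out-of-fold, so the meta-learner never sees
#' its own training optimism).
#'
#' @param train a complete, labeled [haplotype_table()].
#' @param specs per-expert classifier specification (see [fit_ovr()]).
#' @param feature_mode `"full"` (all one-hot features, the default) or
#'   `"one_per_marker"` (the mutual-information selector of
#'   [select_one_per_marker()], for sensitivity analyses).
#' @param calibration_folds folds for out-of-fold calibration.
#' @param temperature attention softmax temperature.
#' @param meta a [meta_network_config()].
#' @param seed integer seed.
#' @return an object of class `ovr_attention_model`.
#' @export
train_ovr_attention <- function(train,
                                specs = classifier_spec("logistic"),
                                feature_mode = c("full", "one_per_marker"),
                                calibration_folds = 5L,
                                temperature = 1,
                                meta = meta_network_config(),
                                seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  encoding <- encode_labels(train)
  labels <- encode(encoding, train$data$Population)
  vocab <- build_vocabulary(train)
  X <- one_hot_encode(train, vocab)
  selected <- NULL
  if (feature_mode == "one_per_marker") {
    X <- select_one_per_marker(X, labels, vocab)
    selected <- attr(X, "selected")
  }
  ensemble <- fit_ovr(X, labels, specs = specs, classes = encoding$classes,
                      calibration_folds = calibration_folds, seed = seed)
  weights <- compute_attention_weights(ensemble$metrics, ensemble$mi_scores,
                                       temperature = temperature)
  fused <- fuse(ensemble$oof_probs, weights)
  meta$seed <- as.integer(seed)
  meta_model <- train_meta_network(fused, labels, meta)
  structure(
    list(panel = train$panel, encoding = encoding, vocab = vocab,
         feature_mode = feature_mode, selected_features = selected,
         ensemble = ensemble, attention = weights, meta = meta_model,
         seed = as.integer(seed)),
    class = "ovr_attention_model"
  )
}

# Shared encoding step for trained models.
model_design_matrix <- function(model, table, unseen = "error") {
  X <- one_hot_encode(table, model$vocab, unseen = unseen)
  if (!is.null(model$selected_features)) {
    X <- X[, model$selected_features, drop = FALSE]
  }
  X
}

#' Predict population of origin
#'
#' Runs a trained OvR-attention model on a complete haplotype table:
#' calibrated expert probabilities, attention fusion, meta-network forward
#' pass. The predicted name is the argmax of the meta-network probability
#' vector, ties broken toward the lowest class index.
#'
#' @param model an [train_ovr_attention()] result.
#' @param table a complete [haplotype_table()] on the model's panel.
#' @param unseen unseen-allele policy passed to [one_hot_encode()].
#' @return a list with `probs` (n x k matrix, rows summing to 1),
#'   `predicted` (character vector) and `table` (a data.frame: `SampleID`,
#'   `Predicted`, `P_<class>` columns — probabilistic guidance per sample).
#' @export
predict_population <- function(model, table, unseen = "error") {
  X <- model_design_matrix(model, table, unseen)
  ovr_p <- ovr_probabilities(model$ensemble, X)
  fused <- fuse(ovr_p, model$attention)
  probs <- predict(model$meta, fused)
  colnames(probs) <- model$encoding$classes
  rownames(probs) <- table$data$SampleID
  pred_idx <- apply(probs, 1L, which.max)  # first max = lowest class index
  predicted <- model$encoding$classes[pred_idx]
  out <- data.frame(SampleID = table$data$SampleID, Predicted = predicted,
                    stringsAsFactors = FALSE)
  for (cl in model$encoding$classes) out[[paste0("P_", cl)]] <- probs[, cl]
  list(probs = probs, predicted = predicted, table = out,
       ovr_probs = ovr_p)
}

#' @export
print.ovr_attention_model <- function(x, ...) {
  cat("<ovr_attention_model> ", x$ensemble$k, " population experts (",
      paste(x$encoding$classes, collapse = ", "), ")\n", sep = "")
  cat("  attention weights: ",
      paste(sprintf("%.3f", as.numeric(x$attention)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
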