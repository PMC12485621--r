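#' Fit the one-vs-one pairwise ensemble
#'
#' One Platt-calibrated binary classifier per unordered class pair —
#' `k (k - 1) / 2` in total — each trained only on the samples of its two
#' classes, with the lower-indexed class as the positive class.
#'
#' @param X one-hot feature matrix.
#' @param labels integer class codes `0 .. k-1`.
#' @param specs a single [classifier_spec()] recycled over pairs, or a list
#'   keyed by `"i_j"` pair names.
#' @param classes character class names, index order.
#' @param calibration_folds folds for out-of-fold calibration scores.
#' @param seed integer seed.
#' @return an object of class `ovo_ensemble` with one entry per pair.
#' @export
fit_ovo <- function(X, labels, specs = classifier_spec("logistic"),
                    classes = NULL, calibration_folds = 3L, seed = 1L) {
  labels <- as.integer(labels)
  k <- if (is.null(classes)) max(labels) + 1L else length(classes)
  if (k < 2L) stop("need at least 2 classes")
  if (is.null(classes)) classes <- paste0("class", seq_len(k) - 1L)
  pairs <- utils::combn(seq_len(k) - 1L, 2L)
  models <- list()
  for (col in seq_len(ncol(pairs))) {
    i <- pairs[1L, col]; j <- pairs[2L, col]
    sel <- labels %in% c(i, j)
    yij <- as.integer(labels[sel] == i)
    if (length(unique(yij)) < 2L) {
      stop("class pair (", classes[i + 1L], ", ", classes[j + 1L],
           ") lacks training samples")
    }
    spec_ij <- if (inherits(specs, "binary_classifier_spec")) specs
               else specs[[paste0(i, "_", j)]]
    Xij <- X[sel, , drop = FALSE]
    oo <- oof_scores(Xij, yij, spec_ij, calibration_folds, seed + col)
    calib <- platt_fit(oo$scores, yij, n_folds = 3L)
    models[[paste0(i, "_", j)]] <- list(
      i = i, j = j, model = fit_binary(Xij, yij, spec_ij),
      calibration = calib, n_train = sum(sel)
    )
  }
  structure(list(models = models, classes = classes, k = k,
                 feature_names = colnames(X), seed = as.integer(seed)),
            class = "ovo_ensemble")
}

# Calibrated P(class i | i-vs-j) for every pair; n x k(k-1)/2 matrix.
ovo_meta_features <- function(ensemble, X) {
  probs <- vapply(ensemble$models, function(m) {
    platt_apply(m$calibration, predict_score(m$model, X))
  }, numeric(nrow(X)))
  matrix(probs, nrow = nrow(X),
         dimnames = list(rownames(X), names(ensemble$models)))
}

#' Pairwise held-out accuracy matrix
#'
#' Scores each pair classifier on the test samples of its own two classes
#' only. The matrix is symmetric by construction, the diagonal undefined
#' (`NA`); a pair with no test samples of either class is also `NA`.
#' Structurally, the lowest off-diagonal cells mark the population pairs
#' hardest to tell apart (e.g. admixed pairs).
#'
#' @param ensemble an [fit_ovo()] result.
#' @param X test one-hot matrix.
#' @param labels integer test class codes.
#' @return an object of class `pairwise_accuracy_matrix`: a `k x k` numeric
#'   matrix with class dimnames.
#' @export
pairwise_accuracy <- function(ensemble, X, labels) {
  labels <- as.integer(labels)
  k <- ensemble$k
  M <- matrix(NA_real_, k, k, dimnames = list(ensemble$classes, ensemble$classes))
  for (m in ensemble$models) {
    sel <- labels %in% c(m$i, m$j)
    if (!any(sel)) next
    y <- as.integer(labels[sel] == m$i)
    p <- platt_apply(m$calibration,
                     predict_score(m$model, X[sel, , drop = FALSE]))
    acc <- mean(as.integer(p >= 0.5) == y)
    M[m$i + 1L, m$j + 1L] <- acc
    M[m$j + 1L, m$i + 1L] <- acc
  }
  structure(M, class = c("pairwise_accuracy_matrix", "matrix", "array"))
}

#' Train the one-vs-one stacking classifier on a haplotype table
#'
#' The comparator architecture: the `k (k - 1) / 2` calibrated pairwise
#' probabilities form the meta-feature vector of every sample, and a
#' stacking combiner with the same fully connected design as the
#' one-vs-rest meta-network maps them to `k`-class probabilities.
#'
#' @inheritParams train_ovr_attention
#' @return an object of class `ovo_stacking_model`.
#' @export
train_ovo_stacking <- function(train,
                               specs = classifier_spec("logistic"),
                               feature_mode = c("full", "one_per_marker"),
                               calibration_folds = 3L,
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
  ensemble <- fit_ovo(X, labels, specs = specs, classes = encoding$classes,
                      calibration_folds = calibration_folds, seed = seed)
  meta_X <- ovo_meta_features(ensemble, X)
  meta$seed <- as.integer(seed)
  meta_model <- train_meta_network(meta_X, labels, meta)
  structure(
    list(panel = train$panel, encoding = encoding, vocab = vocab,
         feature_mode = feature_mode, selected_features = selected,
         ensemble = ensemble, meta = meta_model, seed = as.integer(seed)),
    class = "ovo_stacking_model"
  )
}

#' Predict population of origin with the OvO stacking model
#'
#' @param model an [train_ovo_stacking()] result.
#' @param table a complete [haplotype_table()] on the model's panel.
#' @param unseen unseen-allele policy passed to [one_hot_encode()].
#' @return as [predict_population()]: `probs`, `predicted`, `table`.
#' @export
stack_predict <- function(model, table, unseen = "error") {
  X <- model_design_matrix(model, table, unseen)
  meta_X <- ovo_meta_features(model$ensemble, X)
  probs <- predict(model$meta, meta_X)
  colnames(probs) <- model$encoding$classes
  rownames(probs) <- table$data$SampleID
  pred_idx <- apply(probs, 1L, which.max)
  predicted <- model$encoding$classes[pred_idx]
  out <- data.frame(SampleID = table$data$SampleID, Predicted = predicted,
                    stringsAsFactors = FALSE)
  for (cl in model$encoding$classes) out[[paste0("P_", cl)]] <- probs[, cl]
  list(probs = probs, predicted = predicted, table = out,
       pairwise_probs = meta_X)
}

#' @export
print.ovo_stacking_model <- function(x, ...) {
  cat("<ovo_stacking_model> ", length(x$ensemble$models),
      " pairwise classifiers over ", x$ensemble$k, " populations\n", sep = "")
  invisible(x)
}
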