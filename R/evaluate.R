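#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the encoding's
#' class order; `counts[i, j]` is the number of samples of true class `i`
#' predicted as class `j`.
#'
#' @param true_labels,predicted_labels class names (character) or integer
#'   codes, equal length.
#' @param encoding a [label_encoding()] fixing the class order.
#' @return an integer `k x k` matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels, encoding) {
  to_name <- function(x) {
    if (is.numeric(x)) decode(encoding, x) else {
      x <- as.character(x)
      if (!all(x %in% encoding$classes)) {
        stop("label outside encoding: ", setdiff(x, encoding$classes)[1L])
      }
      x
    }
  }
  t_ <- factor(to_name(true_labels), levels = encoding$classes)
  p_ <- factor(to_name(predicted_labels), levels = encoding$classes)
  if (length(t_) != length(p_)) stop("label vectors differ in length")
  M <- table(t_, p_)
  M <- matrix(as.integer(M), nrow = length(encoding$classes),
              dimnames = list(true = encoding$classes,
                              predicted = encoding$classes))
  structure(M, class = c("confusion_matrix", "matrix", "array"))
}

#' Per-class and overall classification report
#'
#' Precision, recall and F1 per class (0 when the denominator vanishes,
#' with a warning), supports, overall accuracy, and macro / support-weighted
#' averages. The support-weighted recall equals the overall accuracy — the
#' usual identity for total reports.
#'
#' @param matrix a [confusion()] result.
#' @return an object of class `class_report`: list with `per_class`
#'   (data.frame), `accuracy`, `macro` and `weighted` (named vectors of
#'   precision/recall/f1).
#' @export
report <- function(matrix) {
  M <- unclass(matrix)
  total <- sum(M)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(M)
  support <- rowSums(M)
  pred_n <- colSums(M)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  if (any(pred_n == 0) || any(support == 0)) {
    warning("zero denominator in precision/recall; reported as 0")
  }
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / total
  per_class <- data.frame(
    class = rownames(M), precision = precision, recall = recall, f1 = f1,
    support = as.integer(support), row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(per_class = per_class,
         accuracy = sum(tp) / total,
         macro = c(precision = mean(precision), recall = mean(recall),
                   f1 = mean(f1)),
         weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                      f1 = sum(w * f1))),
    class = "class_report"
  )
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f\n", x$accuracy))
  df <- x$per_class
  df$precision <- sprintf("%.4f", df$precision)
  df$recall <- sprintf("%.4f", df$recall)
  df$f1 <- sprintf("%.4f", df$f1)
  print(df, row.names = FALSE)
  cat(sprintf("weighted: precision %.4f, recall %.4f, F1 %.4f\n",
              x$weighted["precision"], x$weighted["recall"], x$weighted["f1"]))
  invisible(x)
}

#' Largest misclassification cells
#'
#' Off-diagonal confusion cells sorted by count (descending), ties broken
#' by true then predicted class name; the top `top_n` are returned.
#' Zero-count cells are omitted.
#'
#' @param matrix a [confusion()] result.
#' @param top_n maximum rows returned (>= 1).
#' @return data.frame with `true`, `predicted`, `count`.
#' @export
misclassification_summary <- function(matrix, top_n = 5L) {
  if (top_n < 1L) stop("top_n must be >= 1")
  M <- unclass(matrix)
  idx <- which(row(M) != col(M) & M > 0, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(true = character(), predicted = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    true = rownames(M)[idx[, 1L]],
    predicted = colnames(M)[idx[, 2L]],
    count = M[idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$true, out$predicted, method = "radix"), ]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Per-population discriminative-allele ranking
#'
#' For each population expert of a one-vs-rest ensemble, extracts the
#' native feature importances (impurity/gain for tree families,
#' |standardized coefficient| for the linear family), normalizes them to a
#' maximum of 1 and returns them sorted descending under the
#' `"LOCUSCOPY_ALLELE"` naming. The top entry per population is its most
#' discriminative allele.
#'
#' @param ensemble an [fit_ovr()] result (or the `$ensemble` of a trained
#'   OvR-attention model).
#' @param vocab the [build_vocabulary()] used for encoding (names only;
#'   may be `NULL` when feature names are already attached to the models).
#' @return an object of class `importance_ranking`: a named list (one
#'   data.frame per population with `feature`, `score`, nonincreasing,
#'   scores in `[0, 1]`).
#' @export
importance_ranking <- function(ensemble, vocab = NULL) {
  out <- lapply(ensemble$experts, function(e) {
    raw <- importance_scores(e$model, ensemble$feature_sds)
    top <- max(raw)
    score <- if (top > 0) raw / top else raw
    df <- data.frame(feature = names(score), score = as.numeric(score),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$score, df$feature, method = "radix"), ]
    rownames(df) <- NULL
    df
  })
  names(out) <- ensemble$classes
  structure(out, class = "importance_ranking")
}

#' Calibration diagnostics (expected calibration error)
#'
#' Bins predicted probabilities into `n_bins` equal-width bins over
#' `[0, 1]` and compares, per bin, the mean predicted confidence with the
#' empirical event rate. The expected calibration error (ECE) is the
#' support-weighted mean absolute gap — 0 for perfect calibration, up to 1.
#'
#' @param probs predicted probabilities of the positive event.
#' @param labels observed binary outcomes (0/1), same length.
#' @param n_bins number of equal-width bins (>= 1).
#' @return list with `ece` (scalar) and `bins` (data.frame with `lower`,
#'   `upper`, `n`, `confidence`, `accuracy`).
#' @export
calibration_diagnostics <- function(probs, labels, n_bins = 10L) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (length(probs) != length(labels)) stop("probs and labels differ in length")
  labels <- as.numeric(labels)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(probs, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  conf <- acc <- n <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    n[b] <- sum(sel)
    if (n[b] > 0) {
      conf[b] <- mean(probs[sel])
      acc[b] <- mean(labels[sel])
    }
  }
  ece <- sum(n / length(probs) * abs(conf - acc))
  list(ece = ece,
       bins = data.frame(lower = edges[-(n_bins + 1L)], upper = edges[-1L],
                         n = as.integer(n), confidence = conf, accuracy = acc))
}
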