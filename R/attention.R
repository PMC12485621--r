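#' Attention weights over the population experts
#'
#' Each one-vs-rest expert receives a nonnegative weight reflecting how
#' reliable it is: a softmax over the sum of its validation performance
#' metric (balanced accuracy on out-of-fold predictions) and its
#' mutual-information ingredient (mean feature MI against its binary
#' target, normalized across experts), divided by a temperature. Weights
#' are nonnegative and sum to 1; temperature 1 is the default, small
#' temperatures sharpen toward the best expert.
#'
#' @param per_expert_metrics numeric vector, one validation score per expert.
#' @param mi_scores numeric vector of the same length (use 0 to weight on
#'   metrics alone).
#' @param temperature positive softmax temperature.
#' @return an object of class `attention_weights`: a named numeric vector
#'   summing to 1, with the inputs attached as attributes.
#' @export
compute_attention_weights <- function(per_expert_metrics, mi_scores = 0,
                                      temperature = 1) {
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be a positive real")
  }
  m <- as.numeric(per_expert_metrics)
  mi <- rep(as.numeric(mi_scores), length.out = length(m))
  if (any(!is.finite(m)) || any(!is.finite(mi))) stop("non-finite attention inputs")
  z <- (m + mi) / temperature
  z <- z - max(z)
  w <- exp(z) / sum(exp(z))
  names(w) <- names(per_expert_metrics)
  structure(w, class = "attention_weights",
            metrics = m, mi = mi, temperature = temperature)
}

#' Fuse calibrated expert probabilities under attention weights
#'
#' Builds the meta-network input from a matrix of calibrated one-vs-rest
#' probabilities: per sample, the `k` attention-weighted terms
#' `w_i * p_i` are retained individually and their sum (the scalar
#' attention-weighted prediction) is appended as a final `fused` column.
#' With uniform weights the `fused` column is the arithmetic mean of the
#' expert probabilities; a one-hot weight vector selects a single expert.
#'
#' @param prediction numeric matrix, `n` samples x `k` experts, of
#'   calibrated positive-class probabilities (column order = class order).
#' @param weights an [compute_attention_weights()] result (or any
#'   nonnegative vector of length `k` summing to 1).
#' @return numeric matrix `n x (k + 1)`: weighted terms plus their sum.
#' @export
fuse <- function(prediction, weights) {
  prediction <- as.matrix(prediction)
  w <- as.numeric(weights)
  if (length(w) != ncol(prediction)) {
    stop("got ", length(w), " weights for ", ncol(prediction), " expert columns")
  }
  terms <- sweep(prediction, 2L, w, `*`)
  out <- cbind(terms, rowSums(terms))
  colnames(out) <- c(paste0("w_", seq_len(ncol(prediction))), "fused")
  if (!is.null(colnames(prediction))) {
    colnames(out) <- c(paste0("w_", colnames(prediction)), "fused")
  }
  out
}
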