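#' Meta-network configuration
#'
#' The meta-learner is a streamlined fully connected network: ReLU hidden
#' layers, a softmax output over the `k` populations, cross-entropy loss,
#' full-batch Adam. Defaults: hidden sizes (64, 32), 300 epochs, learning
#' rate 1e-3. `hidden_sizes = integer(0)` gives a single linear
#' (softmax-regression) layer.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param epochs positive integer.
#' @param learning_rate positive real.
#' @param seed integer seed for weight initialization.
#' @return an object of class `meta_network_config`.
#' @export
meta_network_config <- function(hidden_sizes = c(64L, 32L), epochs = 300L,
                                learning_rate = 1e-3, seed = 1L) {
  hidden_sizes <- as.integer(hidden_sizes)
  if (any(hidden_sizes <= 0L)) stop("hidden sizes must be positive")
  if (epochs < 1L) stop("epochs must be positive")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(hidden_sizes = hidden_sizes, epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "meta_network_config")
}

# stable row-wise softmax
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train the fully connected meta-network
#'
#' Maps fused attention features to `k`-class probabilities. He-initialized
#' weights (seeded), full-batch Adam on the mean cross-entropy. Training is
#' deterministic given the config seed.
#'
#' @param fused numeric matrix of meta-features (e.g. a [fuse()] output).
#' @param labels integer class codes `0 .. k-1`, one per row; every class
#'   must appear at least once.
#' @param config a [meta_network_config()].
#' @return an object of class `meta_network` (layer weights, config, class
#'   count); predict with [predict.meta_network()].
#' @export
train_meta_network <- function(fused, labels, config = meta_network_config()) {
  X <- as.matrix(fused)
  y <- as.integer(labels)
  k <- max(y) + 1L
  if (!all((seq_len(k) - 1L) %in% y)) {
    stop("every class 0..", k - 1L, " must appear in the training labels")
  }
  sizes <- c(ncol(X), config$hidden_sizes, k)
  L <- length(sizes) - 1L
  Y <- matrix(0, nrow(X), k)
  Y[cbind(seq_len(nrow(X)), y + 1L)] <- 1

  params <- withr::with_seed(config$seed, {
    lapply(seq_len(L), function(l) {
      list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                   sd = sqrt(2 / sizes[l])),
                      sizes[l], sizes[l + 1L]),
           b = rep(0, sizes[l + 1L]))
    })
  })
  mW <- lapply(params, function(p) p$W * 0); vW <- mW
  mb <- lapply(params, function(p) p$b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  n <- nrow(X)

  for (epoch in seq_len(config$epochs)) {
    # forward
    acts <- vector("list", L + 1L)
    acts[[1L]] <- X
    for (l in seq_len(L)) {
      Z <- sweep(acts[[l]] %*% params[[l]]$W, 2L, params[[l]]$b, `+`)
      acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
    }
    P <- softmax_rows(acts[[L + 1L]])
    # backward
    delta <- (P - Y) / n
    for (l in rev(seq_len(L))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
      }
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      c1 <- 1 - b1^epoch; c2 <- 1 - b2^epoch
      params[[l]]$W <- params[[l]]$W - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
      params[[l]]$b <- params[[l]]$b - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
    }
  }
  structure(list(params = params, sizes = sizes, k = k, config = config,
                 feature_names = colnames(X)),
            class = "meta_network")
}

#' Predict class probabilities from a meta-network
#'
#' @param object a [train_meta_network()] result.
#' @param newdata numeric matrix of meta-features.
#' @param ... unused.
#' @return numeric matrix `n x k` of probabilities; rows sum to 1.
#' @export
predict.meta_network <- function(object, newdata, ...) {
  A <- as.matrix(newdata)
  L <- length(object$params)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% object$params[[l]]$W, 2L, object$params[[l]]$b, `+`)
    A <- if (l < L) pmax(Z, 0) else Z
  }
  softmax_rows(A)
}
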