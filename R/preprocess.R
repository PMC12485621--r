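#' Drop profiles with any missing call
#'
#' Quality control ahead of encoding: a profile with an empty value at any
#' marker is excluded outright (no imputation), preserving the original
#' order of the survivors.
#'
#' @param table a [haplotype_table()].
#' @return a [haplotype_table()] containing exactly the complete profiles.
#' @export
filter_complete <- function(table) {
  calls <- table$data[, table$panel$locus_copies, drop = FALSE]
  keep <- !apply(is.na(calls), 1L, any)
  subset_table(table, keep)
}

#' Integer encoding of population labels
#'
#' Classes are ordered lexicographically (C locale) for determinism and
#' mapped to indices `0 .. k-1`.
#'
#' @param table a labeled [haplotype_table()] (every profile must carry a
#'   population label).
#' @return an object of class `label_encoding` with fields `classes`
#'   (ordered character vector), and methods via [encode()] / [decode()].
#' @export
encode_labels <- function(table) {
  pops <- table$data$Population
  if (anyNA(pops)) {
    stop("unlabeled profile(s): ",
         paste(utils::head(table$data$SampleID[is.na(pops)], 3L), collapse = ", "))
  }
  label_encoding(sort(unique(pops), method = "radix"))
}

#' @rdname encode_labels
#' @param classes ordered character vector of class names.
#' @export
label_encoding <- function(classes) {
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop("class names must be unique")
  structure(list(classes = classes), class = "label_encoding")
}

#' Map population names to integer codes and back
#' @param encoding a `label_encoding`.
#' @param x character names (for `encode`) or integer codes in `0..k-1`
#'   (for `decode`).
#' @return integer codes, or character names.
#' @export
encode <- function(encoding, x) {
  idx <- match(as.character(x), encoding$classes)
  if (anyNA(idx)) stop("unknown class label: ", x[is.na(idx)][1L])
  idx - 1L
}

#' @rdname encode
#' @export
decode <- function(encoding, x) {
  x <- as.integer(x)
  if (any(x < 0L | x >= length(encoding$classes))) stop("class index out of range")
  encoding$classes[x + 1L]
}

#' Stratified train/test split
#'
#' Per-class training counts follow the largest-remainder rule: the global
#' training size is `round(train_fraction * n)` (half away from zero), each
#' class gets `floor(train_fraction * n_c)` and the remainder is assigned to
#' the classes with the largest fractional parts (ties broken by class
#' name). Membership within a class is a uniform random draw, deterministic
#' given `seed`. The split is disjoint and exhaustive by sample id.
#'
#' @param table a labeled [haplotype_table()].
#' @param train_fraction fraction in `(0, 1)` (default 0.8).
#' @param seed integer seed.
#' @return an object of class `split_result` with fields `train`, `test`
#'   (both [haplotype_table()]s) and `seed`.
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  pops <- table$data$Population
  if (anyNA(pops)) stop("stratified_split requires fully labeled profiles")
  counts <- table(pops)
  if (any(counts < 2L)) {
    stop("class(es) with fewer than 2 members: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  classes <- sort(names(counts), method = "radix")
  n <- length(pops)
  total_train <- floor(train_fraction * n + 0.5)
  ideal <- train_fraction * as.numeric(counts[classes])
  base <- floor(ideal)
  frac <- ideal - base
  rem <- total_train - sum(base)
  take <- base
  if (rem > 0) {
    ord <- order(-frac, classes, method = "radix")
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(frac, classes, method = "radix")
    take[ord[seq_len(-rem)]] <- take[ord[seq_len(-rem)]] - 1L
  }
  names(take) <- classes
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(classes, function(cl) {
      idx <- which(pops == cl)
      idx[sample.int(length(idx), min(take[[cl]], length(idx)))]
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(
    list(train = subset_table(table, train_idx),
         test = subset_table(table, test_idx),
         seed = as.integer(seed)),
    class = "split_result"
  )
}

#' Downsample every class to the smallest class size
#'
#' Mitigates class imbalance before training: each class is reduced to
#' `m = min` class size by uniform sampling without replacement,
#' deterministic given `seed`. Intended for the training partition only, so
#' held-out evaluation keeps natural class proportions.
#'
#' @param table a labeled [haplotype_table()].
#' @param seed integer seed.
#' @return a [haplotype_table()] with equal class counts.
#' @export
downsample_to_min <- function(table, seed = 1L) {
  pops <- table$data$Population
  if (anyNA(pops)) stop("downsample_to_min requires fully labeled profiles")
  if (!length(pops)) return(table)
  m <- min(table(pops))
  keep <- withr::with_seed(as.integer(seed), {
    unlist(lapply(sort(unique(pops), method = "radix"), function(cl) {
      idx <- which(pops == cl)
      idx[sample.int(length(idx), m)]
    }), use.names = FALSE)
  })
  subset_table(table, sort(keep))
}
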