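#' Build the allele vocabulary of a haplotype table
#'
#' The vocabulary is the ordered set of observed (locus-copy, allele) pairs
#' defining the binary feature space: one column per pair, named
#' `"LOCUSCOPY_ALLELE"` (e.g. `DYS439_10`, `DYS385a_11`). Ordering is
#' deterministic — panel locus-copy order, then numeric allele order — and
#' invariant to profile order. Fit the vocabulary on training data only;
#' test-time handling of unseen alleles is controlled in [one_hot_encode()].
#'
#' @param table a complete [haplotype_table()] (run [filter_complete()]
#'   first; a missing call is an error here).
#' @return an object of class `allele_vocabulary` with fields `locus_copy`,
#'   `allele`, `feature` (parallel character vectors) and `panel`.
#' @export
build_vocabulary <- function(table) {
  calls <- table$data[, table$panel$locus_copies, drop = FALSE]
  if (anyNA(calls)) {
    stop("table contains missing calls; run filter_complete() before building a vocabulary")
  }
  lcs <- character()
  als <- character()
  for (lc in table$panel$locus_copies) {
    alleles <- unique(calls[[lc]])
    alleles <- alleles[order_alleles(alleles)]
    lcs <- c(lcs, rep(lc, length(alleles)))
    als <- c(als, alleles)
  }
  structure(
    list(locus_copy = lcs, allele = als,
         feature = paste0(lcs, "_", als), panel = table$panel),
    class = "allele_vocabulary"
  )
}

#' @export
print.allele_vocabulary <- function(x, ...) {
  cat("<allele_vocabulary> ", length(x$feature), " binary features over ",
      length(unique(x$locus_copy)), " locus-copies\n", sep = "")
  invisible(x)
}

#' Number of features in a vocabulary
#' @param vocab an `allele_vocabulary`.
#' @return integer.
#' @export
n_features <- function(vocab) length(vocab$feature)

#' One-hot encode a haplotype table
#'
#' Produces the binary presence/absence design matrix: cell `(i, j)` is 1
#' iff profile `i` carries vocabulary entry `j`. For complete profiles each
#' locus-copy contributes exactly one 1 per row, so row sums equal the
#' panel's locus-copy count.
#'
#' @param table a complete [haplotype_table()].
#' @param vocab an [build_vocabulary()] result.
#' @param unseen what to do with an allele absent from the vocabulary:
#'   `"error"` (default; encoding integrity preserved) or `"zero"` (encode
#'   that locus-copy as all zeros, with a warning naming the samples —
#'   screening use only, since it breaks the row-sum invariant).
#' @return a numeric matrix with `rownames` = sample ids and `colnames` =
#'   vocabulary feature names.
#' @export
one_hot_encode <- function(table, vocab, unseen = c("error", "zero")) {
  unseen <- match.arg(unseen)
  calls <- table$data[, table$panel$locus_copies, drop = FALSE]
  if (anyNA(calls)) stop("table contains missing calls; run filter_complete() first")
  n <- nrow(calls)
  X <- matrix(0, nrow = n, ncol = length(vocab$feature),
              dimnames = list(table$data$SampleID, vocab$feature))
  unseen_samples <- character()
  for (lc in unique(vocab$locus_copy)) {
    cols <- which(vocab$locus_copy == lc)
    hit <- match(calls[[lc]], vocab$allele[cols])
    miss <- is.na(hit)
    if (any(miss)) {
      if (unseen == "error") {
        stop("allele '", calls[[lc]][miss][1L], "' at ", lc,
             " (sample '", table$data$SampleID[miss][1L],
             "') is not in the vocabulary")
      }
      unseen_samples <- c(unseen_samples, table$data$SampleID[miss])
    }
    ok <- which(!miss)
    X[cbind(ok, cols[hit[ok]])] <- 1
  }
  if (length(unseen_samples)) {
    warning("unseen allele(s) encoded as all-zero locus blocks for sample(s): ",
            paste(unique(unseen_samples), collapse = ", "))
  }
  X
}

#' Plug-in mutual information between a feature and the labels
#'
#' The empirical mutual information, in nats, between a discrete feature
#' (here a 0/1 allele indicator) and the integer class labels:
#' `sum over cells of p(x,y) * log(p(x,y) / (p(x) p(y)))` with the
#' convention `0 * log 0 = 0`. No bias correction is applied (plug-in
#' estimator). The result is nonnegative and bounded by the label entropy.
#'
#' @param feature_column vector (any discrete values; typically 0/1).
#' @param labels vector of the same length (class codes).
#' @return a single nonnegative number (nats).
#' @export
mutual_information <- function(feature_column, labels) {
  if (length(feature_column) != length(labels)) {
    stop("feature and labels differ in length (", length(feature_column),
         " vs ", length(labels), ")")
  }
  if (!length(labels)) stop("at least one sample required")
  tab <- table(feature_column, labels)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

# Vectorized plug-in MI of every binary column of X against binary y.
# Returns a vector over columns; same value as mutual_information() per column.
mi_binary_columns <- function(X, y) {
  n <- nrow(X)
  y1 <- as.numeric(y)
  n11 <- as.numeric(crossprod(X, y1))        # x=1, y=1
  n10 <- colSums(X) - n11                    # x=1, y=0
  n01 <- sum(y1) - n11                       # x=0, y=1
  n00 <- n - n11 - n10 - n01
  plogp <- function(num, rowm, colm) {
    p <- num / n
    out <- rep(0, length(p))
    nz <- p > 0
    out[nz] <- p[nz] * log(p[nz] / (rowm[nz] * colm[nz]))
    out
  }
  px1 <- colSums(X) / n
  px0 <- 1 - px1
  py1 <- sum(y1) / n
  py0 <- 1 - py1
  plogp(n11, px1, rep(py1, ncol(X))) + plogp(n10, px1, rep(py0, ncol(X))) +
    plogp(n01, px0, rep(py1, ncol(X))) + plogp(n00, px0, rep(py0, ncol(X)))
}

#' Keep one allele feature per marker (highest mutual information)
#'
#' Dimensionality-reduction transformer for sensitivity analyses: for every
#' locus-copy it retains exactly the allele indicator with the highest
#' plug-in mutual information against the class labels (ties broken toward
#' the lowest numeric allele), reducing the one-hot matrix to one column per
#' locus-copy. The full one-hot matrix remains the default representation
#' for primary analyses; selection discards within-locus allelic diversity.
#'
#' @param matrix one-hot feature matrix (columns named as in the vocabulary).
#' @param labels integer class codes, one per row.
#' @param vocab the [build_vocabulary()] the matrix was encoded with.
#' @return the column subset of `matrix` (one column per locus-copy, in
#'   panel order), with attribute `"selected"` naming the kept features.
#' @export
select_one_per_marker <- function(matrix, labels, vocab) {
  if (nrow(matrix) != length(labels)) stop("labels must match matrix rows")
  keep <- character()
  for (lc in unique(vocab$locus_copy)) {
    cols <- which(vocab$locus_copy == lc)
    mi <- vapply(cols, function(j) {
      mutual_information(matrix[, vocab$feature[j]], labels)
    }, numeric(1))
    best <- cols[mi == max(mi)]
    if (length(best) > 1L) {
      best <- best[order_alleles(vocab$allele[best])[1L]]
    }
    keep <- c(keep, vocab$feature[best])
  }
  out <- matrix[, keep, drop = FALSE]
  attr(out, "selected") <- keep
  out
}
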