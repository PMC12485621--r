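#' Canonicalize Y-STR allele strings
#'
#' Y-STR alleles are repeat counts reported as decimal strings, possibly with
#' a partial-repeat microvariant suffix (e.g. \code{"13.2"}). Alleles are
#' modeled as categories, never as floating-point numbers, so a single
#' canonical spelling per category matters: leading zeros are stripped from
#' the integer part and trailing zeros from the fractional part
#' (\code{"013.20"} becomes \code{"13.2"}, \code{"14.0"} becomes \code{"14"}).
#'
#' @param x character vector of allele strings.
#' @return character vector of canonical allele strings; invalid entries
#'   (anything not parsing as a nonnegative decimal number) become `NA`.
#' @examples
#' canonical_allele(c("14", "013.20", "13.2", "bad"))
#' @export
canonical_allele <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^[0-9]+(\\.[0-9]+)?$", x)
  out <- rep(NA_character_, length(x))
  if (any(ok)) {
    v <- x[ok]
    intpart <- sub("\\..*$", "", v)
    frac <- ifelse(grepl("\\.", v), sub("^[^.]*\\.", "", v), "")
    intpart <- sub("^0+(?=[0-9])", "", intpart, perl = TRUE)
    frac <- sub("0+$", "", frac)
    out[ok] <- ifelse(frac == "", intpart, paste0(intpart, ".", frac))
  }
  out
}

#' Numeric value of an allele string (for ordering only)
#'
#' Used to order alleles (13 < 13.2 < 14) and to sort multi-copy calls; the
#' categorical identity of an allele is always its canonical string.
#'
#' @param x character vector of allele strings.
#' @return numeric vector (`NA` where unparseable).
#' @export
allele_numeric <- function(x) {
  suppressWarnings(as.numeric(x))
}

# Order allele strings numerically, ties broken by string (stable).
order_alleles <- function(x) {
  order(allele_numeric(x), x, method = "radix")
}
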