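#' Define a Y-STR marker panel
#'
#' A panel is the ordered list of loci an assay types, with the copy count of
#' each locus. Multi-copy markers such as DYS385ab are amplified at two sites
#' and contribute two allele calls per sample; all other loci contribute one.
#'
#' @param loci character vector of unique locus names, in panel order.
#' @param multicopy named integer vector (or list) mapping locus names to copy
#'   counts greater than 1; loci not named here have one copy.
#' @return an object of class `marker_panel` with fields `loci`, `copies`
#'   (named integer vector) and `locus_copies` (ordered character vector of
#'   locus-copy identifiers, e.g. `"DYS385a"`, `"DYS385b"`).
#' @examples
#' marker_panel(c("DYS19", "DYS385ab", "DYS390"), multicopy = c(DYS385ab = 2))
#' @export
marker_panel <- function(loci, multicopy = NULL) {
  loci <- as.character(loci)
  if (length(loci) == 0L) stop("panel must contain at least one locus")
  if (anyDuplicated(loci)) stop("locus names must be unique")
  copies <- stats::setNames(rep(1L, length(loci)), loci)
  if (length(multicopy)) {
    multicopy <- unlist(multicopy)
    bad <- setdiff(names(multicopy), loci)
    if (length(bad)) stop("multicopy names not in panel: ", paste(bad, collapse = ", "))
    if (any(multicopy < 1)) stop("copy counts must be >= 1")
    copies[names(multicopy)] <- as.integer(multicopy)
  }
  structure(
    list(loci = loci, copies = copies, locus_copies = locus_copy_ids(loci, copies)),
    class = "marker_panel"
  )
}

# Locus-copy identifiers: single-copy loci keep their name; multi-copy loci
# get letter suffixes, with a trailing "ab" in the locus name (the DYS385ab
# convention) replaced rather than doubled: DYS385ab -> DYS385a, DYS385b.
locus_copy_ids <- function(loci, copies) {
  unlist(lapply(loci, function(l) {
    k <- copies[[l]]
    if (k == 1L) return(l)
    base <- if (grepl("ab$", l) && k == 2L) sub("ab$", "", l) else l
    paste0(base, letters[seq_len(k)])
  }), use.names = FALSE)
}

# Map each locus-copy id back to its parent locus.
locus_of_copy <- function(panel) {
  stats::setNames(
    rep(panel$loci, panel$copies[panel$loci]),
    panel$locus_copies
  )
}

#' The built-in 20-marker forensic screening panel
#'
#' The locus set of the PowerPlex Y-type core used throughout the package's
#' examples: DYS19, the multi-copy DYS385ab, DYS389I/II, the DYS390--DYS393
#' block, DYS437, DYS438, DYS439, DYS448, DYS487, DYS533, DYS570, DYS576,
#' DYS635 and YGATAH4. With DYS385ab split into its two copies the panel has
#' 19 locus-copies.
#'
#' @return a `marker_panel`.
#' @export
default_panel <- function() {
  marker_panel(
    c(
      "DYS19", "DYS385ab", "DYS389I", "DYS389II", "DYS390", "DYS391",
      "DYS392", "DYS393", "DYS437", "DYS438", "DYS439", "DYS448",
      "DYS487", "DYS533", "DYS570", "DYS576", "DYS635", "YGATAH4"
    ),
    multicopy = c(DYS385ab = 2)
  )
}

#' Read / write a panel definition as JSON
#'
#' The JSON carries `loci` (ordered array) and `multicopy` (object mapping
#' locus name to copy count).
#'
#' @param path file path.
#' @return `read_panel` returns a `marker_panel`; `write_panel` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$loci)) stop("panel JSON must contain 'loci'")
  mc <- spec$multicopy
  if (length(mc)) mc <- unlist(mc)
  marker_panel(spec$loci, multicopy = mc)
}

#' @rdname read_panel
#' @param panel a `marker_panel`.
#' @export
write_panel <- function(panel, path) {
  mc <- panel$copies[panel$copies > 1L]
  jsonlite::write_json(
    list(loci = panel$loci, multicopy = as.list(mc)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", length(x$loci), " loci, ",
      length(x$locus_copies), " locus-copies\n", sep = "")
  cat("  ", paste(x$loci, collapse = ", "), "\n", sep = "")
  invisible(x)
}
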