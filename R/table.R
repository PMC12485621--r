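#' Construct a haplotype table
#'
#' The central container: one row per male sample, one character column per
#' locus-copy of the panel, plus `SampleID` and an optional `Population`
#' label. Allele calls are canonical strings (see [canonical_allele()]);
#' missing calls are `NA`. Within a multi-copy locus the copies are stored in
#' nondecreasing numeric order.
#'
#' @param panel a [marker_panel()].
#' @param data a data.frame with columns `SampleID`, optionally `Population`,
#'   and one character column per locus-copy of the panel.
#' @param canonicalize canonicalize allele strings and sort multi-copy calls
#'   (default `TRUE`; set `FALSE` only when `data` is already canonical).
#' @return an object of class `haplotype_table` with fields `panel` and
#'   `data`.
#' @export
haplotype_table <- function(panel, data, canonicalize = TRUE) {
  stopifnot(inherits(panel, "marker_panel"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"SampleID" %in% names(data)) stop("data must contain a SampleID column")
  missing_cols <- setdiff(panel$locus_copies, names(data))
  if (length(missing_cols)) {
    stop("data lacks locus-copy columns: ", paste(missing_cols, collapse = ", "))
  }
  data$SampleID <- as.character(data$SampleID)
  if (anyDuplicated(data$SampleID)) {
    warning("duplicate SampleID values present; validate_table() will flag them")
  }
  if (!"Population" %in% names(data)) data$Population <- NA_character_
  data$Population <- as.character(data$Population)
  for (lc in panel$locus_copies) {
    v <- as.character(data[[lc]])
    v[!is.na(v) & trimws(v) == ""] <- NA_character_
    if (canonicalize) {
      canon <- canonical_allele(v)
      bad <- !is.na(v) & is.na(canon)
      if (any(bad)) {
        stop("unparseable allele at ", lc, ", row ", which(bad)[1L],
             ": '", v[which(bad)[1L]], "'")
      }
      v <- canon
    }
    data[[lc]] <- v
  }
  data <- data[, c("SampleID", "Population", panel$locus_copies), drop = FALSE]
  rownames(data) <- NULL
  tab <- structure(list(panel = panel, data = data), class = "haplotype_table")
  if (canonicalize) tab <- sort_multicopy(tab)
  tab
}

# Enforce nondecreasing numeric order within each multi-copy locus.
sort_multicopy <- function(table) {
  panel <- table$panel
  multi <- panel$loci[panel$copies[panel$loci] > 1L]
  if (!length(multi) || nrow(table$data) == 0L) return(table)
  lom <- locus_of_copy(panel)
  for (locus in multi) {
    ids <- names(lom)[lom == locus]
    block <- as.matrix(table$data[, ids, drop = FALSE])
    sorted <- t(apply(block, 1L, function(r) {
      known <- !is.na(r)
      r[known] <- r[known][order_alleles(r[known])]
      r
    }))
    table$data[, ids] <- sorted
  }
  table
}

#' @export
print.haplotype_table <- function(x, ...) {
  pops <- x$data$Population
  cat("<haplotype_table> ", nrow(x$data), " profiles, ",
      length(x$panel$locus_copies), " locus-copies\n", sep = "")
  if (any(!is.na(pops))) {
    tab <- table(pops, useNA = "no")
    cat("  populations: ",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of profiles in a haplotype table
#' @param table a `haplotype_table`.
#' @return integer.
#' @export
n_profiles <- function(table) nrow(table$data)

# Default strings interpreted as a missing call when reading tables.
DEFAULT_NA_TOKENS <- c("", "NA", "na", "N/A", "-", ".")

#' Read a YHRD-style haplotype table from CSV/TSV
#'
#' Expects a header with `SampleID`, optionally `Population`, and one column
#' per locus-copy. Multi-copy markers are accepted either as split columns
#' (`DYS385a` / `DYS385b`) or as a single comma-joined column under the locus
#' name (`DYS385ab` holding `"11,14"`). Calls are canonicalized and
#' multi-copy calls sorted into nondecreasing numeric order on read.
#'
#' @param path file path (UTF-8 text).
#' @param panel a [marker_panel()]; defaults to [default_panel()].
#' @param delim field delimiter; `NULL` (default) auto-detects `\t` vs `,`
#'   from the header line.
#' @param na_tokens strings mapped to a missing call.
#' @return a [haplotype_table()].
#' @export
read_haplotype_table <- function(path, panel = default_panel(), delim = NULL,
                                 na_tokens = DEFAULT_NA_TOKENS) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(
    path, header = TRUE, sep = delim, colClasses = "character",
    check.names = FALSE, quote = "\"", comment.char = "", encoding = "UTF-8",
    stringsAsFactors = FALSE
  )
  if (!"SampleID" %in% names(raw)) stop("missing required column: SampleID")

  lom <- locus_of_copy(panel)
  out <- data.frame(SampleID = raw$SampleID, stringsAsFactors = FALSE)
  if ("Population" %in% names(raw)) out$Population <- raw$Population

  for (locus in panel$loci) {
    ids <- names(lom)[lom == locus]
    if (all(ids %in% names(raw))) {
      for (id in ids) out[[id]] <- raw[[id]]
    } else if (length(ids) > 1L && locus %in% names(raw)) {
      # single comma-joined column for a multi-copy marker
      parts <- strsplit(raw[[locus]], "[,/; ]+")
      for (j in seq_along(ids)) {
        out[[ids[j]]] <- vapply(parts, function(p) {
          p <- p[p != ""]
          if (length(p) >= j) p[j] else NA_character_
        }, character(1))
      }
    } else {
      stop("missing required column for locus: ", locus)
    }
  }
  for (lc in panel$locus_copies) {
    v <- trimws(out[[lc]])
    v[v %in% na_tokens | is.na(v)] <- NA_character_
    keep <- !is.na(v)
    if (any(keep)) {
      canon <- canonical_allele(v[keep])
      if (anyNA(canon)) {
        row <- which(keep)[which(is.na(canon))[1L]]
        stop("unparseable allele '", v[keep][is.na(canon)][1L], "' at ",
             lc, ", data row ", row)
      }
      v[keep] <- canon
    }
    out[[lc]] <- v
  }
  haplotype_table(panel, out, canonicalize = FALSE) |> sort_multicopy()
}

#' Write a haplotype table to CSV/TSV
#'
#' Emits split columns for multi-copy markers (`DYS385a`, `DYS385b`) and an
#' empty cell for each missing call, so that
#' `read_haplotype_table(write_haplotype_table(t))` reproduces `t`
#' field-for-field.
#'
#' @param table a [haplotype_table()].
#' @param path output path.
#' @param delim field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path, delim = ",") {
  df <- table$data
  if (all(is.na(df$Population))) df$Population <- NULL
  df[is.na(df)] <- ""
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a haplotype table
#'
#' Scans for anomalies without mutating the table: missing calls, duplicated
#' sample identifiers and unlabeled profiles. Structural conformance to the
#' panel and allele parseability are already enforced by the constructors, so
#' a clean table yields zero findings.
#'
#' @param table a [haplotype_table()].
#' @param require_population also flag profiles with no population label
#'   (default `FALSE`).
#' @return a data.frame of findings with columns `type`, `sample_id`,
#'   `locus`, `message` (zero rows when the table is clean).
#' @export
validate_table <- function(table, require_population = FALSE) {
  df <- table$data
  findings <- list()
  add <- function(type, sample_id, locus, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      type = type, sample_id = sample_id, locus = locus, message = message,
      stringsAsFactors = FALSE
    )
  }
  dup <- unique(df$SampleID[duplicated(df$SampleID)])
  for (id in dup) {
    add("duplicate_id", id, NA_character_,
        sprintf("sample id '%s' occurs %d times", id, sum(df$SampleID == id)))
  }
  for (lc in table$panel$locus_copies) {
    miss <- which(is.na(df[[lc]]))
    for (i in miss) {
      add("missing_call", df$SampleID[i], lc,
          sprintf("missing call at %s for sample '%s'", lc, df$SampleID[i]))
    }
  }
  if (require_population) {
    for (i in which(is.na(df$Population))) {
      add("unlabeled", df$SampleID[i], NA_character_,
          sprintf("sample '%s' has no population label", df$SampleID[i]))
    }
  }
  if (!length(findings)) {
    return(data.frame(type = character(), sample_id = character(),
                      locus = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Bind haplotype tables sharing one panel
#' @param ... `haplotype_table` objects on the same panel.
#' @return a combined `haplotype_table`.
#' @export
bind_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  panel <- tabs[[1L]]$panel
  for (t in tabs) {
    if (!identical(t$panel$locus_copies, panel$locus_copies)) {
      stop("tables use different panels")
    }
  }
  haplotype_table(panel, do.call(rbind, lapply(tabs, `[[`, "data")),
                  canonicalize = FALSE)
}

# Row subset preserving class and panel.
subset_table <- function(table, idx) {
  haplotype_table(table$panel, table$data[idx, , drop = FALSE],
                  canonicalize = FALSE)
}
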