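#' @include AllClasses.R
NULL

## Numeric parsing is deliberately strict: the decimal separator is always
## ".", so a comma-decimal export fails loudly instead of being misread.
.parse_abundance <- function(x, column, zero_is_missing = FALSE) {
  x <- trimws(x)
  missing_tok <- is.na(x) | x == "" | toupper(x) %in% c("NA", "NAN")
  out <- rep(NA_real_, length(x))
  if (any(!missing_tok)) {
    val <- suppressWarnings(as.numeric(x[!missing_tok]))
    bad <- is.na(val)
    if (any(bad))
      prn_stop("prn_value_error",
               "column '%s': non-numeric value '%s' (comma decimals are not accepted)",
               column, x[!missing_tok][bad][1L])
    if (any(val < 0))
      prn_stop("prn_value_error", "column '%s': negative abundance %g",
               column, val[val < 0][1L])
    out[!missing_tok] <- val
  }
  if (zero_is_missing) out[!is.na(out) & out == 0] <- NA_real_
  out
}

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(header) == 0L)
    prn_stop("prn_format_error", "'%s' is empty", path)
  if (grepl("\t", header)) "\t" else ","
}

#' Sample design for a three-condition experiment
#'
#' @param roles named character vector, `sample_id -> role`, roles drawn from
#'   `reference`, `disease`, `treated`.
#' @param replicate_groups named character vector `sample_id -> group`;
#'   defaults to the role, i.e. all samples of a role are technical
#'   replicates of one pool.
#' @return a data.frame with columns `sample_id`, `role`, `replicate_group`.
#' @export
sampleDesign <- function(roles, replicate_groups = NULL) {
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    prn_stop("prn_design_error", "roles must be named by sample id")
  if (!all(roles %in% .SAMPLE_ROLES))
    prn_stop("prn_design_error", "roles must be in {%s}",
             paste(.SAMPLE_ROLES, collapse = ", "))
  if (!all(.SAMPLE_ROLES %in% roles))
    prn_stop("prn_design_error", "need at least one sample per role")
  if (is.null(replicate_groups)) replicate_groups <- stats::setNames(unname(roles), names(roles))
  if (!all(names(roles) %in% names(replicate_groups)))
    prn_stop("prn_design_error", "every sample in roles needs a replicate group")
  data.frame(sample_id = names(roles), role = unname(roles),
             replicate_group = unname(replicate_groups[names(roles)]),
             stringsAsFactors = FALSE)
}

#' Read a wide protein quantification table
#'
#' Reads a search-engine style export (one row per protein, one abundance
#' column per sample) into a [ProteinQuantExperiment-class]. The field
#' separator (tab or comma) is sniffed from the header line. A `column_map`
#' decouples the pipeline from any particular vendor layout.
#'
#' @param path path to a TSV/CSV file (UTF-8).
#' @param column_map list with entries `accession`, `unique_peptides`,
#'   `abundance` (character vector of abundance column headers, optionally
#'   named by sample id) and optionally `gene_symbol`.
#' @param design a [sampleDesign()] data.frame covering the abundance
#'   samples.
#' @param zero_is_missing treat literal zeros as "not detected"
#'   (default `FALSE`).
#' @return a [ProteinQuantExperiment-class].
#' @export
readQuantTable <- function(path, column_map, design, zero_is_missing = FALSE) {
  if (!file.exists(path))
    prn_stop("prn_io_error", "file '%s' does not exist", path)
  for (key in c("accession", "unique_peptides", "abundance"))
    if (is.null(column_map[[key]]))
      prn_stop("prn_schema_error", "column_map is missing the '%s' role", key)
  sep <- .sniff_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  ab_cols <- column_map$abundance
  sample_ids <- if (is.null(names(ab_cols))) ab_cols else names(ab_cols)
  mapped <- c(column_map$accession, column_map$unique_peptides,
              column_map$gene_symbol, unname(ab_cols))
  missing_cols <- setdiff(mapped, colnames(tab))
  if (length(missing_cols))
    prn_stop("prn_schema_error", "mapped column(s) not in file: %s",
             paste(missing_cols, collapse = ", "))

  acc <- trimws(tab[[column_map$accession]])
  if (any(!nzchar(acc)))
    prn_stop("prn_integrity_error", "empty accession at row %d",
             which(!nzchar(acc))[1L])
  if (anyDuplicated(acc))
    prn_stop("prn_integrity_error", "duplicate accession '%s'",
             acc[duplicated(acc)][1L])
  up <- suppressWarnings(as.numeric(trimws(tab[[column_map$unique_peptides]])))
  if (any(is.na(up)) || any(up < 0) || any(up != round(up)))
    prn_stop("prn_value_error",
             "unique peptide counts must be non-negative integers")
  gs <- if (is.null(column_map$gene_symbol)) rep("", nrow(tab)) else
    trimws(tab[[column_map$gene_symbol]])
  gs[is.na(gs)] <- ""

  m <- vapply(unname(ab_cols), function(col)
    .parse_abundance(tab[[col]], col, zero_is_missing),
    numeric(nrow(tab)))
  if (nrow(tab) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(acc, sample_ids)

  extra <- setdiff(sample_ids, design$sample_id)
  if (length(extra))
    prn_stop("prn_design_error", "sample(s) not covered by design: %s",
             paste(extra, collapse = ", "))
  d <- design[match(sample_ids, design$sample_id), ]
  ProteinQuantExperiment(m, role = d$role,
                         replicate_group = d$replicate_group,
                         gene_symbol = gs, unique_peptides = as.integer(up))
}

#' Read gene sets from a GMT file
#'
#' One set per line: `id<TAB>description<TAB>member1<TAB>member2...`.
#' Member order is discarded and duplicate members collapse to one.
#'
#' @param path path to a GMT file (UTF-8, Unix newlines).
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  if (!file.exists(path))
    prn_stop("prn_io_error", "file '%s' does not exist", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    prn_stop("prn_format_error",
             "GMT line %d has fewer than 3 tab-separated fields", short[1L])
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    prn_stop("prn_integrity_error", "duplicate set id '%s'",
             ids[duplicated(ids)][1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  geneSetCollection(sets, descriptions = vapply(fields, `[[`, "", 2L))
}

#' Write and re-read pipeline result tables
#'
#' `writeResults` writes any result data.frame (classified table, enrichment
#' table, candidate table) as a UTF-8, Unix-newline TSV with a stable column
#' order; numeric columns round-trip through `readResults` to at least 12
#' significant digits and `NA` cells are written empty.
#'
#' @param records a data.frame.
#' @param path output path.
#' @return `writeResults` returns `path` invisibly; `readResults` returns the
#'   data.frame.
#' @export
writeResults <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      x <- out[[j]]
      s <- vapply(x, function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 15L,
                                               scientific = FALSE), "")
      out[[j]] <- s
    }
  }
  con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                  error = function(e)
    prn_stop("prn_io_error", "cannot open '%s' for writing", path))
  on.exit(close(con))
  tryCatch(
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", eol = "\n",
                       fileEncoding = "UTF-8"),
    error = function(e) prn_stop("prn_io_error", "cannot write '%s': %s",
                                 path, conditionMessage(e)))
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  if (!file.exists(path))
    prn_stop("prn_io_error", "file '%s' does not exist", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           comment.char = "", na.strings = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           colClasses = "character")
  for (j in seq_along(tab)) {
    x <- tab[[j]]
    if (all(is.na(x) | x %in% c("TRUE", "FALSE"))) {
      tab[[j]] <- as.logical(x)
      next
    }
    conv <- suppressWarnings(as.numeric(x))
    if (all(is.na(x) == is.na(conv))) tab[[j]] <- conv
  }
  tab
}
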