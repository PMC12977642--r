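#' @include AllClasses.R
NULL

.match_categories <- function(classified, sets, categories,
                              match_on = c("accession", "gene_symbol")) {
  match_on <- match.arg(match_on)
  members <- geneSetMembers(sets)[intersect(categories, geneSetIds(sets))]
  missing_sets <- setdiff(categories, geneSetIds(sets))
  if (length(missing_sets))
    prn_stop("prn_lookup_error", "unknown gene set id(s): %s",
             paste(missing_sets, collapse = ", "))
  vapply(seq_len(nrow(classified)), function(i) {
    id1 <- classified$accession[i]
    id2 <- classified$gene_symbol[i]
    hit <- vapply(members, function(m) {
      if (match_on == "accession")
        id1 %in% m || (nzchar(id2) && id2 %in% m)
      else
        (nzchar(id2) && id2 %in% m) || id1 %in% m
    }, TRUE)
    paste(names(members)[hit], collapse = ";")
  }, "")
}

#' Select biomarker candidates from the classified table
#'
#' A protein qualifies as a candidate iff it (i) belongs to at least one of
#' the configured gene-set categories, (ii) is dysregulated at least
#' `biomarker_fold`-fold in either direction — the bound is inclusive
#' ("at least 5-fold"), deliberately unlike the strict 2-fold regulation
#' bound — and (iii), when `require_normalised`, its abundance was
#' normalised by treatment. Membership is matched on accession with
#' gene-symbol fallback (or the reverse via `match_on`).
#'
#' @param classified data.frame from [classifyProteins()].
#' @param sets a [GeneSetCollection-class] holding the category sets.
#' @param thresholds a [regulationThresholds()] object (`biomarker_fold`).
#' @param categories gene-set ids to use (default: all sets in `sets`).
#' @param require_normalised require `normalisation_call == "normalised"`
#'   (default `TRUE`).
#' @param match_on primary identifier space for membership matching.
#' @return data.frame sorted by `|log2 r_disease|` descending (ties by
#'   accession) with columns `accession`, `gene_symbol`, `category_ids`,
#'   `r_disease`, `direction`, `normalisation_call`.
#' @export
selectCandidates <- function(classified, sets,
                             thresholds = regulationThresholds(),
                             categories = geneSetIds(sets),
                             require_normalised = TRUE,
                             match_on = c("accession", "gene_symbol")) {
  cat_ids <- .match_categories(classified, sets, categories, match_on)
  fold <- thresholds@biomarker_fold
  r <- classified$r_disease
  qual <- nzchar(cat_ids) & !is.na(r) & (r >= fold | r <= 1 / fold)
  if (require_normalised)
    qual <- qual & classified$normalisation_call == "normalised"
  out <- data.frame(accession = classified$accession[qual],
                    gene_symbol = classified$gene_symbol[qual],
                    category_ids = cat_ids[qual],
                    r_disease = r[qual],
                    direction = ifelse(r[qual] > 1, "up", "down"),
                    normalisation_call = classified$normalisation_call[qual],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(log2(out$r_disease)), out$accession), ]
  rownames(out) <- NULL
  out
}

#' Candidate report for external validation
#'
#' One row per candidate with empty concordance columns to be filled by
#' manual literature / expression-atlas comparison; scraping such services
#' is version-dependent and non-reproducible, so it is deliberately left to
#' the user.
#'
#' @param candidates data.frame from [selectCandidates()].
#' @return data.frame in deterministic order (fold magnitude descending)
#'   with blank `literature_concordance` and `expression_atlas_concordance`
#'   columns.
#' @export
candidateReport <- function(candidates) {
  if (anyDuplicated(candidates$accession))
    prn_stop("prn_integrity_error", "duplicate candidate accession '%s'",
             candidates$accession[duplicated(candidates$accession)][1L])
  out <- candidates[order(-abs(log2(candidates$r_disease)),
                          candidates$accession), , drop = FALSE]
  out$literature_concordance <- rep("", nrow(out))
  out$expression_atlas_concordance <- rep("", nrow(out))
  rownames(out) <- NULL
  out
}
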