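#' @include AllClasses.R
NULL

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` members of a `K`-sized set when sampling `n` items without
#' replacement from a universe of `N`. This is the one-sided
#' over-representation p-value.
#'
#' @param k observed overlap.
#' @param K gene-set size within the universe.
#' @param n selection size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeomUpper <- function(k, K, n, N) {
  bad <- K > N | n > N | k > K | k > n | k < 0 | K < 0 | n < 0 | N < 0
  if (any(bad))
    prn_stop("prn_count_error",
             "inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; the returned q-values are
#' aligned to the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in (0, 1].
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    prn_stop("prn_value_error", "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a protein selection
#'
#' Hypergeometric upper-tail test of each gene set against a selection drawn
#' from a universe (by default the quantified proteome at the active
#' unique-peptide filter — the defensible background for a quantified-
#' proteome selection). Set members are intersected with the universe before
#' the set size `K` is computed. Sets whose overlap with the selection is
#' below `min_overlap` are excluded from testing and do not count towards
#' the number of tests in the BH correction.
#'
#' @param selected character vector of selected identifiers (subset of
#'   `universe`).
#' @param universe character vector of background identifiers.
#' @param sets a [GeneSetCollection-class].
#' @param min_overlap minimum selection overlap for a set to be tested
#'   (default 2).
#' @return data.frame ordered by ascending p (ties by set id) with columns
#'   `set_id`, `name`, `N`, `K`, `n`, `k`, `p_value`, `q_value`,
#'   `overlap_members` (semicolon-joined).
#' @export
ora <- function(selected, universe, sets, min_overlap = 2L) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (length(universe) == 0L)
    prn_stop("prn_value_error", "universe must be non-empty")
  stray <- setdiff(selected, universe)
  if (length(stray))
    prn_stop("prn_containment_error",
             "selected identifiers not in universe: %s",
             paste(stray, collapse = ", "))
  empty <- data.frame(set_id = character(), name = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p_value = numeric(),
                      q_value = numeric(), overlap_members = character(),
                      stringsAsFactors = FALSE)
  if (length(selected) == 0L) return(empty)
  N <- length(universe)
  n <- length(selected)
  members <- geneSetMembers(sets)
  rows <- lapply(seq_along(members), function(i) {
    mem <- intersect(members[[i]], universe)
    ov <- intersect(mem, selected)
    if (length(ov) < min_overlap) return(NULL)
    data.frame(set_id = geneSetIds(sets)[i],
               name = unname(geneSetDescriptions(sets)[i]),
               N = N, K = length(mem), n = n, k = length(ov),
               p_value = hypergeomUpper(length(ov), length(mem), n, N),
               overlap_members = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  res <- do.call(rbind, rows)
  res$q_value <- bhAdjust(res$p_value)
  res <- res[order(res$p_value, res$set_id), ]
  rownames(res) <- NULL
  res[, c("set_id", "name", "N", "K", "n", "k", "p_value", "q_value",
          "overlap_members")]
}
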