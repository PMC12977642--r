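#' @include AllClasses.R
NULL

#' Scale each sample to a common total intensity
#'
#' Multiplies every abundance of a sample by one scalar so that the sample's
#' total intensity equals `target` (default: the mean of the per-sample
#' totals). Relative abundances within a sample are unchanged and the
#' operation is idempotent. This single total-intensity scaling stands in
#' for the staged amount normalisation performed at the bench (equal protein
#' load, equal peptide load, spectral-intensity normalisation), which cannot
#' be replayed from an exported table.
#'
#' @param x a [ProteinQuantExperiment-class].
#' @param target positive total to scale every sample to; `NULL` uses the
#'   mean of the current per-sample totals.
#' @return the rescaled [ProteinQuantExperiment-class].
#' @export
scaleTotalIntensity <- function(x, target = NULL) {
  a <- abundances(x)
  totals <- colSums(a, na.rm = TRUE)
  dead <- totals <= 0 | !is.finite(totals)
  if (any(dead))
    prn_stop("prn_degenerate_sample_error",
             "sample '%s' has no detected protein with abundance > 0",
             colnames(a)[dead][1L])
  if (is.null(target)) target <- mean(totals)
  if (!is.finite(target) || target <= 0)
    prn_stop("prn_value_error", "target must be a positive real")
  scaled <- sweep(a, 2L, target / totals, `*`)
  SummarizedExperiment::assay(x, "abundance") <- scaled
  x
}

#' Aggregate technical replicates to one abundance per pool
#'
#' Collapses the columns of each `replicate_group` into a single column. A
#' protein counts as detected in a group iff it is detected in at least
#' `min_detected` member injections; its group abundance is the mean (or
#' median) over the detected values only.
#'
#' @param x a [ProteinQuantExperiment-class].
#' @param method `"mean"` (default) or `"median"`.
#' @param min_detected minimum number of detected member injections
#'   (default 1).
#' @return a [ProteinQuantExperiment-class] with one column per replicate
#'   group.
#' @export
aggregateReplicates <- function(x, method = c("mean", "median"),
                                min_detected = 1L) {
  method <- match.arg(method)
  fun <- if (method == "mean") mean else stats::median
  a <- abundances(x)
  groups <- replicateGroups(x)
  roles <- sampleRoles(x)
  glev <- unique(unname(groups))
  grole <- vapply(glev, function(g) {
    r <- unique(roles[groups == g])
    if (length(r) != 1L)
      prn_stop("prn_design_error",
               "replicate group '%s' mixes roles %s", g,
               paste(r, collapse = "/"))
    r
  }, "")
  agg <- vapply(glev, function(g) {
    sub <- a[, groups == g, drop = FALSE]
    apply(sub, 1L, function(v) {
      det <- !is.na(v)
      if (sum(det) >= min_detected && any(det)) fun(v[det]) else NA_real_
    })
  }, numeric(nrow(a)))
  if (nrow(a) == 1L) agg <- matrix(agg, nrow = 1L)
  dimnames(agg) <- list(rownames(a), glev)
  ProteinQuantExperiment(agg, role = grole, replicate_group = glev,
                         gene_symbol = geneSymbols(x),
                         unique_peptides = uniquePeptides(x))
}

#' Compute disease/reference and treated/reference abundance ratios
#'
#' Expects one (aggregated) abundance per role. A ratio is present iff both
#' its numerator and denominator role are detected with positive abundance;
#' no pseudo-count is ever added, so proteins missing in one condition stay
#' categorical ("exclusive") rather than receiving a fabricated ratio.
#'
#' @param x a [ProteinQuantExperiment-class] with exactly one sample per
#'   role (see [aggregateReplicates()]).
#' @return a data.frame with columns `accession`, `gene_symbol`,
#'   `unique_peptides`, detection flags `det_reference`, `det_disease`,
#'   `det_treated`, and ratios `r_disease`, `r_treated` (`NA` when absent).
#' @export
computeRatios <- function(x) {
  roles <- sampleRoles(x)
  for (r in .SAMPLE_ROLES)
    if (sum(roles == r) != 1L)
      prn_stop("prn_design_error",
               "need exactly one aggregated sample for role '%s' (found %d)",
               r, sum(roles == r))
  a <- abundances(x)
  ref <- a[, which(roles == "reference")]
  dis <- a[, which(roles == "disease")]
  trt <- a[, which(roles == "treated")]
  det <- function(v) !is.na(v) & v > 0
  ratio <- function(num, den) ifelse(det(num) & det(den), num / den, NA_real_)
  data.frame(accession = rownames(a),
             gene_symbol = geneSymbols(x),
             unique_peptides = uniquePeptides(x),
             det_reference = det(ref),
             det_disease = det(dis),
             det_treated = det(trt),
             r_disease = ratio(dis, ref),
             r_treated = ratio(trt, ref),
             stringsAsFactors = FALSE, row.names = NULL)
}
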