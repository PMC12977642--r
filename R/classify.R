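#' @include AllClasses.R
NULL

.REGULATION_LEVELS <- c("regulated_up", "regulated_down", "unregulated",
                        "insufficient_evidence", "exclusive_disease",
                        "exclusive_reference", "undetected")
.NORMALISATION_LEVELS <- c("normalised", "trend", "not_normalised",
                           "not_applicable")

#' Call regulation of each protein versus the reference line
#'
#' The regulation verdict per protein, in rule order: proteins below the
#' active unique-peptide minimum are `insufficient_evidence`; proteins with
#' no disease/reference ratio are `exclusive_disease`, `exclusive_reference`
#' or `undetected` according to the detection flags; otherwise the ratio is
#' compared to the fold-change cut-offs with strict inequalities —
#' `regulated_up` when r > fc_high, `regulated_down` when r < fc_low, else
#' `unregulated`. A ratio of exactly `fc_high` (or `fc_low`) is therefore
#' unregulated, while the unique-peptide minima are inclusive.
#'
#' @param r_disease numeric vector of disease/reference ratios (`NA` =
#'   absent).
#' @param det_reference,det_disease logical detection flags per protein.
#' @param unique_peptides integer vector of unique-peptide counts.
#' @param thresholds a [regulationThresholds()] object.
#' @param level `"standard"` (UP minimum `up_min_standard`) or `"strict"`
#'   (`up_min_strict`).
#' @return character vector of regulation calls.
#' @export
callRegulation <- function(r_disease, det_reference, det_disease,
                           unique_peptides,
                           thresholds = regulationThresholds(),
                           level = c("standard", "strict")) {
  level <- match.arg(level)
  if (any(!is.na(r_disease) & r_disease <= 0))
    prn_stop("prn_value_error", "abundance ratios must be > 0")
  up_min <- if (level == "strict") thresholds@up_min_strict else
    thresholds@up_min_standard
  n <- length(r_disease)
  out <- character(n)
  low_up <- unique_peptides < up_min
  out[low_up] <- "insufficient_evidence"
  absent <- is.na(r_disease) & !low_up
  out[absent & det_disease & !det_reference] <- "exclusive_disease"
  out[absent & !det_disease & det_reference] <- "exclusive_reference"
  out[absent & !det_disease & !det_reference] <- "undetected"
  # detected in both but ratio absent cannot happen upstream; treat as undetected
  out[absent & out == ""] <- "undetected"
  scored <- !low_up & !is.na(r_disease)
  out[scored & r_disease > thresholds@fc_high] <- "regulated_up"
  out[scored & r_disease < thresholds@fc_low] <- "regulated_down"
  out[scored & out == ""] <- "unregulated"
  out
}

#' Call whether treatment normalised a regulated protein
#'
#' Applicable only to proteins called `regulated_up`/`regulated_down` whose
#' treated/reference ratio exists; all others are `not_applicable`. A
#' regulated protein is `normalised` when its treated ratio lies inside the
#' inclusive band `[fc_low, fc_high]`; it shows a `trend` towards
#' normalisation when it is still outside the band but has moved strictly
#' closer to 1 in log space without changing direction; anything else —
#' unchanged, worsened, or overshot past the opposite cut-off — is
#' `not_normalised`.
#'
#' @param r_disease,r_treated numeric ratio vectors (`NA` = absent).
#' @param regulation character vector of calls from [callRegulation()].
#' @param thresholds a [regulationThresholds()] object.
#' @return character vector of normalisation calls.
#' @export
callNormalisation <- function(r_disease, r_treated, regulation,
                              thresholds = regulationThresholds()) {
  if (any(!is.na(r_disease) & r_disease <= 0) ||
      any(!is.na(r_treated) & r_treated <= 0))
    prn_stop("prn_value_error", "abundance ratios must be > 0")
  applicable <- regulation %in% c("regulated_up", "regulated_down") &
    !is.na(r_treated)
  out <- rep("not_applicable", length(regulation))
  inside <- applicable & r_treated >= thresholds@fc_low &
    r_treated <= thresholds@fc_high
  out[inside] <- "normalised"
  rest <- applicable & !inside
  ld <- log2(r_disease)
  lt <- log2(r_treated)
  trend <- rest & sign(lt) == sign(ld) & abs(lt) < abs(ld)
  out[trend] <- "trend"
  out[rest & !trend] <- "not_normalised"
  out
}

#' Classify every protein of a ratio table
#'
#' Convenience wrapper adding `regulation_call` and `normalisation_call`
#' columns to the output of [computeRatios()].
#'
#' @param ratios data.frame from [computeRatios()].
#' @param thresholds a [regulationThresholds()] object.
#' @param level evidence tier, `"standard"` or `"strict"`.
#' @return the input data.frame with call columns appended.
#' @export
classifyProteins <- function(ratios, thresholds = regulationThresholds(),
                             level = c("standard", "strict")) {
  level <- match.arg(level)
  reg <- callRegulation(ratios$r_disease, ratios$det_reference,
                        ratios$det_disease, ratios$unique_peptides,
                        thresholds, level)
  norm <- callNormalisation(ratios$r_disease, ratios$r_treated, reg,
                            thresholds)
  ratios$regulation_call <- reg
  ratios$normalisation_call <- norm
  ratios
}

#' Summarise the regulated set and its normalisation partition
#'
#' Counts up/down-regulated proteins and, over the regulated proteins with
#' an applicable normalisation call, the normalised / trend /
#' not-normalised partition with its percentages. Percentages are returned
#' unrounded; round only at presentation.
#'
#' @param classified data.frame from [classifyProteins()].
#' @return a list with counts `n_regulated_up`, `n_regulated_down`,
#'   `n_normalised`, `n_trend`, `n_not_normalised` and percentages
#'   `pct_normalised`, `pct_trend`, `pct_not_normalised` over the proteins
#'   with an applicable call.
#' @export
summariseCalls <- function(classified) {
  reg <- classified$regulation_call
  norm <- classified$normalisation_call
  n_up <- sum(reg == "regulated_up")
  n_down <- sum(reg == "regulated_down")
  if (n_up + n_down == 0L)
    prn_stop("prn_summary_error",
             "no regulated proteins: percentages are undefined")
  n_norm <- sum(norm == "normalised")
  n_trend <- sum(norm == "trend")
  n_not <- sum(norm == "not_normalised")
  denom <- n_norm + n_trend + n_not
  if (denom == 0L)
    prn_stop("prn_summary_error",
             "no regulated protein has a treated ratio: percentages undefined")
  list(n_regulated_up = n_up, n_regulated_down = n_down,
       n_normalised = n_norm, n_trend = n_trend, n_not_normalised = n_not,
       pct_normalised = 100 * n_norm / denom,
       pct_trend = 100 * n_trend / denom,
       pct_not_normalised = 100 * n_not / denom)
}

#' Count proteins passing the evidence/fold-change filter tiers
#'
#' Tier counts over one ratio table: total identified proteins, regulated
#' and unregulated at the standard unique-peptide minimum, and regulated at
#' the strict minimum.
#'
#' @param ratios data.frame from [computeRatios()].
#' @param thresholds a [regulationThresholds()] object.
#' @return a list with `n_identified`, `n_regulated_standard`,
#'   `n_unregulated_standard`, `n_regulated_strict`.
#' @export
countFilterTiers <- function(ratios, thresholds = regulationThresholds()) {
  std <- callRegulation(ratios$r_disease, ratios$det_reference,
                        ratios$det_disease, ratios$unique_peptides,
                        thresholds, "standard")
  strict <- callRegulation(ratios$r_disease, ratios$det_reference,
                           ratios$det_disease, ratios$unique_peptides,
                           thresholds, "strict")
  regulated <- c("regulated_up", "regulated_down")
  list(n_identified = nrow(ratios),
       n_regulated_standard = sum(std %in% regulated),
       n_unregulated_standard = sum(std == "unregulated"),
       n_regulated_strict = sum(strict %in% regulated))
}
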