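#' @include AllClasses.R
NULL

## Default unique-peptide marginal: 5% of proteins below the standard tier
## (UP = 1), a further 15% between the tiers (UP 2-4), 80% at or above the
## strict tier (UP 5-30), so both evidence filters are exercised.
.default_up_probs <- function() {
  p <- numeric(30L)
  p[1L] <- 0.05
  p[2:4] <- 0.15 / 3
  p[5:30] <- 0.80 / 26
  p
}

#' Simulation configuration
#'
#' Describes a synthetic three-condition proteome: a planted fraction of
#' dysregulated proteins (split up/down), of which configured fractions are
#' normalised or trending after treatment; log-normal multiplicative
#' technical noise across replicate injections; a unique-peptide marginal;
#' and exclusive-detection (missing in one condition) events.
#'
#' @aliases SimConfig-class
#' @export
setClass("SimConfig",
         representation(n_proteins = "integer", frac_dysregulated = "numeric",
                        frac_up_given_dysreg = "numeric",
                        frac_normalised_given_dysreg = "numeric",
                        frac_trend_given_dysreg = "numeric",
                        effect_log2_mean = "numeric", effect_log2_sd = "numeric",
                        cv_technical = "numeric", n_replicates = "integer",
                        frac_exclusive = "numeric", up_count_probs = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(object@frac_dysregulated, object@frac_up_given_dysreg,
          object@frac_normalised_given_dysreg, object@frac_trend_given_dysreg,
          object@frac_exclusive)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@frac_normalised_given_dysreg +
      object@frac_trend_given_dysreg > 1)
    msg <- c(msg, "frac_normalised + frac_trend must be <= 1")
  if (object@cv_technical < 0) msg <- c(msg, "cv_technical must be >= 0")
  if (object@n_proteins < 1L) msg <- c(msg, "n_proteins must be >= 1")
  if (object@n_replicates < 1L) msg <- c(msg, "n_replicates must be >= 1")
  if (object@effect_log2_sd < 0) msg <- c(msg, "effect_log2_sd must be >= 0")
  if (length(object@up_count_probs) != 30L ||
      any(object@up_count_probs < 0) ||
      abs(sum(object@up_count_probs) - 1) > 1e-8)
    msg <- c(msg, "up_count_probs must be 30 probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param n_proteins number of proteins (default 2000).
#' @param frac_dysregulated probability a protein is planted dysregulated
#'   (default 0.6).
#' @param frac_up_given_dysreg probability a dysregulated protein goes up
#'   (default 0.55, matching a 348:281 up:down split).
#' @param frac_normalised_given_dysreg,frac_trend_given_dysreg planted
#'   normalisation outcome fractions among dysregulated proteins (defaults
#'   0.47 and 0.05, the study's summary partition).
#' @param effect_log2_mean,effect_log2_sd effect magnitude beyond the
#'   fold-change cut-off, in log2 units (defaults 1.0 and 0.5).
#' @param cv_technical coefficient of variation of the log-normal technical
#'   noise across replicate injections (default 0.1).
#' @param n_replicates technical replicates per condition pool (default 3).
#' @param frac_exclusive probability of an exclusive-detection event
#'   (default 0.05).
#' @param up_count_probs probabilities of unique-peptide counts 1..30.
#' @param seed RNG seed for [simulateProteomes()].
#' @return a validated `SimConfig`.
#' @export
simConfig <- function(n_proteins = 2000L, frac_dysregulated = 0.6,
                      frac_up_given_dysreg = 0.55,
                      frac_normalised_given_dysreg = 0.47,
                      frac_trend_given_dysreg = 0.05,
                      effect_log2_mean = 1.0, effect_log2_sd = 0.5,
                      cv_technical = 0.1, n_replicates = 3L,
                      frac_exclusive = 0.05,
                      up_count_probs = .default_up_probs(),
                      seed = 1L) {
  new("SimConfig", n_proteins = as.integer(n_proteins),
      frac_dysregulated = frac_dysregulated,
      frac_up_given_dysreg = frac_up_given_dysreg,
      frac_normalised_given_dysreg = frac_normalised_given_dysreg,
      frac_trend_given_dysreg = frac_trend_given_dysreg,
      effect_log2_mean = effect_log2_mean, effect_log2_sd = effect_log2_sd,
      cv_technical = cv_technical, n_replicates = as.integer(n_replicates),
      frac_exclusive = frac_exclusive, up_count_probs = up_count_probs,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d proteins, %.0f%% dysregulated (%.0f%% up), %.0f%% normalised / %.0f%% trend, CV %.2f, %d replicates, seed %d\n",
    object@n_proteins, 100 * object@frac_dysregulated,
    100 * object@frac_up_given_dysreg,
    100 * object@frac_normalised_given_dysreg,
    100 * object@frac_trend_given_dysreg, object@cv_technical,
    object@n_replicates, object@seed))
})

## run expr under a private RNG stream; the caller's .Random.seed survives
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic three-condition quantification experiment
#'
#' Reference abundances are drawn log-normal; disease abundances are the
#' reference times a planted disease/reference ratio placed strictly beyond
#' the fold-change cut-off for dysregulated proteins (magnitude
#' `cutoff * 2^max(|N(effect_log2_mean, effect_log2_sd)|, margin)`) and
#' strictly inside the band otherwise. Treated abundances place normalised
#' proteins inside the band, trend proteins strictly between the band edge
#' and the disease ratio (same direction), and the remaining dysregulated
#' proteins at or beyond the disease ratio. Technical replicates receive
#' independent multiplicative log-normal noise with the configured CV, and
#' exclusive proteins have one condition blanked out. The same config and
#' seed reproduce identical output.
#'
#' Ground-truth labels are derived by applying the classification rules to
#' the noise-free planted ratios and drawn unique-peptide counts, so they
#' are consistent with `thresholds` by construction.
#'
#' @param cfg a [simConfig()] object.
#' @param thresholds a [regulationThresholds()] object used both to place
#'   effects and to derive truth labels.
#' @return list with `experiment` (a [ProteinQuantExperiment-class] with
#'   `n_replicates` injections per condition) and `truth` (data.frame of
#'   per-protein planted ratios and labels at both evidence tiers).
#' @export
simulateProteomes <- function(cfg, thresholds = regulationThresholds()) {
  validObject(cfg)
  lo <- log2(thresholds@fc_high)     # band half-width in log2 space
  if (cfg@frac_trend_given_dysreg > 0 && cfg@effect_log2_sd == 0 &&
      cfg@effect_log2_mean <= 0.3)
    prn_stop("prn_config_error",
             "trend proteins need effect magnitudes above 0.3 log2 units beyond the cut-off")
  .with_seed(cfg@seed, {
    n <- cfg@n_proteins
    accession <- sprintf("SP%05d", seq_len(n))
    gene_symbol <- sprintf("GENE%d", seq_len(n))
    up <- sample.int(30L, n, replace = TRUE, prob = cfg@up_count_probs)

    dys <- stats::runif(n) < cfg@frac_dysregulated
    dir_up <- stats::runif(n) < cfg@frac_up_given_dysreg
    ## outcome classes are planted at exactly the configured fractions of
    ## the dysregulated set (randomly allocated): the planted fraction is a
    ## benchmark constant, not a second source of sampling noise
    outcome <- rep("none", n)
    dys_idx <- sample(which(dys))
    n_dys <- length(dys_idx)
    n_norm <- round(cfg@frac_normalised_given_dysreg * n_dys)
    n_trend <- round(cfg@frac_trend_given_dysreg * n_dys)
    outcome[dys_idx] <- rep(c("normalised", "trend", "not_normalised"),
                            c(n_norm, n_trend, n_dys - n_norm - n_trend))
    excl <- stats::runif(n) < cfg@frac_exclusive
    excl_side <- ifelse(stats::runif(n) < 0.5, "disease", "reference")

    ## planted log2 disease/reference ratio
    margin_floor <- ifelse(outcome == "trend", 0.3, 0.1)
    margin <- pmax(abs(stats::rnorm(n, cfg@effect_log2_mean,
                                    cfg@effect_log2_sd)), margin_floor)
    sgn <- ifelse(dir_up, 1, -1)
    ld <- ifelse(dys, sgn * (lo + margin), stats::runif(n, -0.8 * lo, 0.8 * lo))

    ## planted log2 treated/reference ratio
    lt <- stats::runif(n, -0.9 * lo, 0.9 * lo)          # normalised + background
    is_tr <- dys & outcome == "trend"
    lt[is_tr] <- sgn[is_tr] *
      stats::runif(sum(is_tr), lo + 0.05 * margin[is_tr],
                   lo + 0.95 * margin[is_tr])
    is_nn <- dys & outcome == "not_normalised"
    lt[is_nn] <- ld[is_nn] * stats::runif(sum(is_nn), 1, 1.4)

    ref <- stats::rlnorm(n, meanlog = 13, sdlog = 1.2)
    dis <- ref * 2^ld
    trt <- ref * 2^lt
    ref[excl & excl_side == "disease"] <- NA     # exclusive to disease
    dis[excl & excl_side == "reference"] <- NA   # exclusive to reference

    ## replicate injections with multiplicative log-normal noise
    sdlog <- sqrt(log(1 + cfg@cv_technical^2))
    reps <- cfg@n_replicates
    mk <- function(base, prefix) {
      m <- vapply(seq_len(reps), function(r) {
        noise <- if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else
          rep(1, n)
        base * noise
      }, numeric(n))
      if (n == 1L) m <- matrix(m, nrow = 1L)
      colnames(m) <- sprintf("%s_%d", prefix, seq_len(reps))
      m
    }
    abundance <- cbind(mk(ref, "ref"), mk(dis, "dis"), mk(trt, "trt"))
    rownames(abundance) <- accession
    role <- rep(c("reference", "disease", "treated"), each = reps)
    pqe <- ProteinQuantExperiment(abundance, role = role,
                                  replicate_group = rep(c("ref", "dis", "trt"),
                                                        each = reps),
                                  gene_symbol = gene_symbol,
                                  unique_peptides = up)

    det_ref <- !is.na(ref)
    det_dis <- !is.na(dis)
    r_d <- ifelse(det_ref & det_dis, 2^ld, NA_real_)
    r_t <- ifelse(det_ref, 2^lt, NA_real_)
    truth <- data.frame(accession = accession, gene_symbol = gene_symbol,
                        unique_peptides = up,
                        true_r_disease = r_d, true_r_treated = r_t,
                        stringsAsFactors = FALSE)
    for (level in c("standard", "strict")) {
      reg <- callRegulation(r_d, det_ref, det_dis, up, thresholds, level)
      norm <- callNormalisation(r_d, r_t, reg, thresholds)
      truth[[paste0("true_regulation_", level)]] <- reg
      truth[[paste0("true_normalisation_", level)]] <- norm
    }
    list(experiment = pqe, truth = truth)
  })
}

#' Compare pipeline calls with planted truth
#'
#' Tabulates per-class confusion matrices for the regulation and
#' normalisation calls and reports the recovered fraction of normalised
#' proteins (percent of regulated proteins with an applicable call) next to
#' the same fraction over the truth labels, with their absolute difference
#' in percentage points.
#'
#' @param truth truth data.frame from [simulateProteomes()].
#' @param classified data.frame from [classifyProteins()] over the same
#'   proteins.
#' @param level evidence tier of the calls being evaluated.
#' @return list with `confusion_regulation`, `confusion_normalisation`,
#'   `pct_normalised_called`, `pct_normalised_truth`, `error_pp`.
#' @export
evaluateRecovery <- function(truth, classified,
                             level = c("strict", "standard")) {
  level <- match.arg(level)
  if (nrow(truth) != nrow(classified) ||
      !setequal(truth$accession, classified$accession))
    prn_stop("prn_alignment_error",
             "truth and calls cover different protein sets")
  classified <- classified[match(truth$accession, classified$accession), ]
  treg <- truth[[paste0("true_regulation_", level)]]
  tnorm <- truth[[paste0("true_normalisation_", level)]]
  creg <- factor(classified$regulation_call, levels = .REGULATION_LEVELS)
  cnorm <- factor(classified$normalisation_call,
                  levels = .NORMALISATION_LEVELS)
  pct <- function(x) {
    applicable <- x %in% c("normalised", "trend", "not_normalised")
    if (!any(applicable)) return(NA_real_)
    100 * sum(x == "normalised") / sum(applicable)
  }
  p_called <- pct(classified$normalisation_call)
  p_truth <- pct(tnorm)
  list(confusion_regulation =
         table(truth = factor(treg, levels = .REGULATION_LEVELS),
               called = creg),
       confusion_normalisation =
         table(truth = factor(tnorm, levels = .NORMALISATION_LEVELS),
               called = cnorm),
       pct_normalised_called = p_called,
       pct_normalised_truth = p_truth,
       error_pp = abs(p_called - p_truth))
}
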