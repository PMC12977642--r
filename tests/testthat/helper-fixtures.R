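# Shared in-code fixtures and independent oracles.

# Small three-condition experiment with hand-checkable values.
make_toy_experiment <- function() {
  m <- matrix(c(
    # ref  dis  trt
    10,  40,  12,    # 4-fold up, normalised
    10,   1,   3,    # 10-fold down, trend (0.3 still below 0.5)
    10,  60,  90,    # up, worsens
    10,  15,  12,    # unregulated
    NA,  50,  60,    # exclusive to disease
    10,  NA,  11,    # exclusive to reference
    10,  30,   5),   # up, overshoots below 0.5
    ncol = 3, byrow = TRUE,
    dimnames = list(paste0("P", 1:7), c("ref", "dis", "trt")))
  ProteinQuantExperiment(m, role = c("reference", "disease", "treated"),
                         gene_symbol = paste0("G", 1:7),
                         unique_peptides = c(6L, 6L, 6L, 6L, 6L, 6L, 3L))
}

# Independent clause-by-clause reimplementation of the regulation and
# normalisation rules, scalar and deliberately naive.
oracle_regulation <- function(r, det_ref, det_dis, up, t, level) {
  up_min <- if (level == "strict") t@up_min_strict else t@up_min_standard
  if (up < up_min) return("insufficient_evidence")
  if (is.na(r)) {
    if (det_dis && !det_ref) return("exclusive_disease")
    if (!det_dis && det_ref) return("exclusive_reference")
    return("undetected")
  }
  if (r > t@fc_high) return("regulated_up")
  if (r < t@fc_low) return("regulated_down")
  "unregulated"
}

oracle_normalisation <- function(rd, rt, reg, t) {
  if (!reg %in% c("regulated_up", "regulated_down") || is.na(rt))
    return("not_applicable")
  if (rt >= t@fc_low && rt <= t@fc_high) return("normalised")
  if (sign(log(rt)) == sign(log(rd)) && abs(log(rt)) < abs(log(rd)))
    return("trend")
  "not_normalised"
}

# Random ratio tables for property tests.
random_ratio_table <- function(n) {
  det_ref <- runif(n) < 0.9
  det_dis <- runif(n) < 0.9
  both <- det_ref & det_dis
  data.frame(
    accession = sprintf("R%04d", seq_len(n)),
    gene_symbol = sprintf("G%d", seq_len(n)),
    unique_peptides = sample(0:12, n, replace = TRUE),
    det_reference = det_ref,
    det_disease = det_dis,
    det_treated = TRUE,
    r_disease = ifelse(both, 2^runif(n, -4, 4), NA_real_),
    r_treated = ifelse(det_ref & runif(n) < 0.9, 2^runif(n, -4, 4),
                       NA_real_),
    stringsAsFactors = FALSE)
}

# Exact rational-style hypergeometric upper tail: plain sum of exact
# binomial-coefficient products (all integers representable for N <= 30).
oracle_hyper_upper <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Naive O(n^3) UPGMA oracle recomputing every inter-cluster mean from the
# original distances at each step (no Lance-Williams update).
oracle_upgma_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        h <- mean(D[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

write_quant_fixture <- function(path, sep = "\t") {
  header <- paste(c("Accession", "Gene", "UP", "A_ref", "A_dis", "A_trt"),
                  collapse = sep)
  rows <- c(paste(c("P10001", "FN1", "6", "100", "420", "130"),
                  collapse = sep),
            paste(c("P10002", "COL1A1", "3", "50", "", "40"),
                  collapse = sep),
            paste(c("P10003", "", "1", "10", "12", "9"), collapse = sep))
  writeLines(c(header, rows), path)
  path
}

toy_design <- function() {
  sampleDesign(c(A_ref = "reference", A_dis = "disease", A_trt = "treated"))
}

toy_column_map <- function() {
  list(accession = "Accession", gene_symbol = "Gene", unique_peptides = "UP",
       abundance = c(A_ref = "A_ref", A_dis = "A_dis", A_trt = "A_trt"))
}
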