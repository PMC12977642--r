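t_default <- regulationThresholds()

test_that("regulation calls follow the fold-change and evidence rules", {
  expect_identical(
    callRegulation(2.5, TRUE, TRUE, 6L, t_default, "strict"), "regulated_up")
  # exactly 2.0 is unregulated: the fold bound is a strict inequality
  expect_identical(
    callRegulation(2.0, TRUE, TRUE, 6L, t_default, "strict"), "unregulated")
  expect_identical(
    callRegulation(0.5, TRUE, TRUE, 6L, t_default, "standard"), "unregulated")
  expect_identical(
    callRegulation(0.3, TRUE, TRUE, 1L, t_default, "standard"),
    "insufficient_evidence")
  # UP minimum is inclusive: UP == 2 passes standard, UP == 5 passes strict
  expect_identical(
    callRegulation(0.3, TRUE, TRUE, 2L, t_default, "standard"),
    "regulated_down")
  expect_identical(
    callRegulation(3, TRUE, TRUE, 5L, t_default, "strict"), "regulated_up")
  expect_identical(
    callRegulation(NA, FALSE, TRUE, 6L, t_default, "standard"),
    "exclusive_disease")
  expect_identical(
    callRegulation(NA, TRUE, FALSE, 6L, t_default, "standard"),
    "exclusive_reference")
  expect_identical(
    callRegulation(NA, FALSE, FALSE, 6L, t_default, "standard"), "undetected")
  expect_error(callRegulation(-1, TRUE, TRUE, 6L, t_default, "standard"),
               class = "prn_value_error")
})

test_that("normalisation calls implement band, trend and overshoot rules", {
  reg_up <- "regulated_up"
  reg_down <- "regulated_down"
  expect_identical(callNormalisation(4, 1.2, reg_up, t_default), "normalised")
  # inclusive band edges
  expect_identical(callNormalisation(4, 2.0, reg_up, t_default), "normalised")
  expect_identical(callNormalisation(4, 0.5, reg_up, t_default), "normalised")
  expect_identical(callNormalisation(0.1, 0.3, reg_down, t_default), "trend")
  expect_identical(callNormalisation(4, 6, reg_up, t_default),
                   "not_normalised")
  # overshoot past the opposite cut-off is not a trend
  expect_identical(callNormalisation(4, 0.2, reg_up, t_default),
                   "not_normalised")
  expect_identical(callNormalisation(4, NA, reg_up, t_default),
                   "not_applicable")
  expect_identical(callNormalisation(1.5, 1.2, "unregulated", t_default),
                   "not_applicable")
  expect_error(callNormalisation(4, -2, reg_up, t_default),
               class = "prn_value_error")
})

test_that("calls match a clause-by-clause oracle on random small tables", {
  set.seed(401)
  for (rep in 1:20) {
    tab <- random_ratio_table(50)
    for (level in c("standard", "strict")) {
      cl <- classifyProteins(tab, t_default, level)
      exp_reg <- vapply(seq_len(nrow(tab)), function(i)
        oracle_regulation(tab$r_disease[i], tab$det_reference[i],
                          tab$det_disease[i], tab$unique_peptides[i],
                          t_default, level), "")
      exp_norm <- vapply(seq_len(nrow(tab)), function(i)
        oracle_normalisation(tab$r_disease[i], tab$r_treated[i],
                             exp_reg[i], t_default), "")
      expect_identical(cl$regulation_call, exp_reg)
      expect_identical(cl$normalisation_call, exp_norm)
    }
  }
})

test_that("every protein gets exactly one call from each family and counts partition", {
  set.seed(402)
  for (rep in 1:50) {
    tab <- random_ratio_table(sample(5:80, 1))
    cl <- classifyProteins(tab, t_default,
                           sample(c("standard", "strict"), 1))
    expect_true(all(cl$regulation_call %in%
      c("regulated_up", "regulated_down", "unregulated",
        "insufficient_evidence", "exclusive_disease", "exclusive_reference",
        "undetected")))
    expect_true(all(cl$normalisation_call %in%
      c("normalised", "trend", "not_normalised", "not_applicable")))
    expect_identical(length(cl$regulation_call), nrow(tab))
    # applicable-call bookkeeping
    n_reg <- sum(cl$regulation_call %in% c("regulated_up", "regulated_down"))
    n_reg_no_rt <- sum(cl$regulation_call %in%
                         c("regulated_up", "regulated_down") &
                         is.na(cl$r_treated))
    expect_identical(
      sum(cl$normalisation_call != "not_applicable"), n_reg - n_reg_no_rt)
  }
})

test_that("regulated counts are monotone in the thresholds", {
  set.seed(403)
  tab <- random_ratio_table(300)
  count_reg <- function(t, level) {
    cl <- classifyProteins(tab, t, level)
    sum(cl$regulation_call %in% c("regulated_up", "regulated_down"))
  }
  # raising the UP minimum never increases regulated counts
  for (up in 0:9) {
    t1 <- regulationThresholds(up_min_standard = up, up_min_strict = up)
    t2 <- regulationThresholds(up_min_standard = up + 1L,
                               up_min_strict = up + 1L)
    expect_gte(count_reg(t1, "standard"), count_reg(t2, "standard"))
  }
  # widening the band never increases regulated counts, and proteins still
  # regulated under the wider band can only gain the normalised call
  fcs <- c(1.5, 2, 3, 5)
  for (i in seq_len(length(fcs) - 1)) {
    tn <- regulationThresholds(fc_high = fcs[i])
    tw <- regulationThresholds(fc_high = fcs[i + 1])
    expect_gte(count_reg(tn, "standard"), count_reg(tw, "standard"))
    cln <- classifyProteins(tab, tn, "standard")
    clw <- classifyProteins(tab, tw, "standard")
    still_reg <- clw$regulation_call %in% c("regulated_up", "regulated_down")
    was_norm <- still_reg & cln$normalisation_call == "normalised"
    expect_true(all(clw$normalisation_call[was_norm] == "normalised"))
  }
})

test_that("inverting all ratios swaps up and down and fixes the partition", {
  set.seed(404)
  tab <- random_ratio_table(200)
  inv <- tab
  inv$r_disease <- 1 / tab$r_disease
  inv$r_treated <- 1 / tab$r_treated
  tmp <- inv$det_reference
  inv$det_reference <- inv$det_disease
  inv$det_disease <- tmp
  a <- classifyProteins(tab, t_default, "standard")
  b <- classifyProteins(inv, t_default, "standard")
  expect_identical(sum(a$regulation_call == "regulated_up"),
                   sum(b$regulation_call == "regulated_down"))
  expect_identical(sum(a$regulation_call == "regulated_down"),
                   sum(b$regulation_call == "regulated_up"))
  expect_identical(sum(a$normalisation_call == "normalised"),
                   sum(b$normalisation_call == "normalised"))
  expect_identical(sum(a$normalisation_call == "trend"),
                   sum(b$normalisation_call == "trend"))
})

test_that("the fraction summary reproduces its defining arithmetic", {
  pqe <- make_toy_experiment()
  cl <- classifyProteins(computeRatios(pqe), t_default, "strict")
  s <- summariseCalls(cl)
  # hand count on the toy experiment (P7 has UP=3 -> insufficient at strict)
  expect_identical(s$n_regulated_up, 2L)    # P1, P3
  expect_identical(s$n_regulated_down, 1L)  # P2
  expect_identical(s$n_normalised, 1L)      # P1
  expect_identical(s$n_trend, 1L)           # P2
  expect_identical(s$n_not_normalised, 1L)  # P3
  expect_equal(s$pct_normalised + s$pct_trend + s$pct_not_normalised, 100)

  # degenerate inputs
  all_norm <- cl[cl$normalisation_call == "normalised", ]
  expect_equal(summariseCalls(all_norm)$pct_normalised, 100)
  none <- cl[cl$regulation_call == "unregulated", ]
  expect_error(summariseCalls(none), class = "prn_summary_error")
})

test_that("filter tier counts match hand enumeration and are monotone", {
  # 10-row fixture enumerated by hand:
  #   UP>=2 & |log2 r|>1: rows 1,2,4,6,8  -> 5 regulated standard
  #   UP>=2 & inside band: rows 3,9       -> 2 unregulated standard
  #   UP>=5 & regulated: rows 1,4,8       -> 3 regulated strict
  tab <- data.frame(
    accession = sprintf("P%02d", 1:10),
    gene_symbol = "",
    unique_peptides = c(6L, 3L, 7L, 5L, 1L, 2L, 0L, 9L, 4L, 6L),
    det_reference = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    det_disease = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    det_treated = TRUE,
    r_disease = c(4, 0.25, 1.5, 8, 3, 0.1, 5, 2.5, 0.75, NA),
    r_treated = 1,
    stringsAsFactors = FALSE)
  tiers <- countFilterTiers(tab, t_default)
  expect_identical(tiers$n_identified, 10L)
  expect_identical(tiers$n_regulated_standard, 5L)
  expect_identical(tiers$n_unregulated_standard, 2L)
  expect_identical(tiers$n_regulated_strict, 3L)
  expect_lte(tiers$n_regulated_strict, tiers$n_regulated_standard)

  # all proteins below the standard tier -> zero regulated anywhere
  tab$unique_peptides <- 1L
  t0 <- countFilterTiers(tab, t_default)
  expect_identical(t0$n_regulated_standard, 0L)
  expect_identical(t0$n_regulated_strict, 0L)
})
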