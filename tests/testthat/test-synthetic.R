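test_that("identical config and seed reproduce identical tables", {
  cfg <- simConfig(n_proteins = 300L, seed = 7L)
  a <- simulateProteomes(cfg)
  b <- simulateProteomes(cfg)
  expect_identical(abundances(a$experiment), abundances(b$experiment))
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  c_ <- simulateProteomes(simConfig(n_proteins = 300L, seed = 8L))
  expect_false(identical(abundances(a$experiment), abundances(c_$experiment)))
})

test_that("generation does not leak into the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulateProteomes(simConfig(n_proteins = 50L, seed = 1L)))
  expect_identical(.Random.seed, before)
  x1 <- runif(1)
  set.seed(99)
  expect_identical(runif(1), x1)
})

test_that("invalid and infeasible configurations are rejected", {
  expect_error(simConfig(frac_normalised_given_dysreg = 0.8,
                         frac_trend_given_dysreg = 0.3))
  expect_error(simConfig(cv_technical = -0.1))
  expect_error(simConfig(up_count_probs = rep(1, 5)))
  # trend planted but zero effect spread leaves no room beyond the cut-off
  expect_error(
    simulateProteomes(simConfig(n_proteins = 50L, effect_log2_mean = 0.1,
                                effect_log2_sd = 0, seed = 1L)),
    class = "prn_config_error")
})

test_that("planted truth labels are consistent with the thresholds", {
  t <- regulationThresholds()
  sim <- simulateProteomes(simConfig(n_proteins = 800L, seed = 21L), t)
  tr <- sim$truth
  scored <- which(!is.na(tr$true_r_disease))
  for (level in c("standard", "strict")) {
    exp_reg <- vapply(scored, function(i)
      oracle_regulation(tr$true_r_disease[i], TRUE, TRUE,
                        tr$unique_peptides[i], t, level), "")
    expect_identical(tr[[paste0("true_regulation_", level)]][scored],
                     exp_reg)
    exp_norm <- vapply(seq_along(scored), function(j)
      oracle_normalisation(tr$true_r_disease[scored[j]],
                           tr$true_r_treated[scored[j]], exp_reg[j], t), "")
    expect_identical(tr[[paste0("true_normalisation_", level)]][scored],
                     exp_norm)
  }
  # dysregulated ratios sit strictly beyond the cut-off, background inside
  up <- tr$true_regulation_standard == "regulated_up" &
    !is.na(tr$true_r_disease)
  expect_true(all(tr$true_r_disease[up] > t@fc_high))
  unreg <- tr$true_regulation_standard == "unregulated"
  expect_true(all(tr$true_r_disease[unreg] < t@fc_high &
                    tr$true_r_disease[unreg] > t@fc_low))
  # trend ratios lie strictly between the band edge and the disease ratio
  trend <- tr$true_normalisation_strict == "trend"
  lt <- abs(log2(tr$true_r_treated[trend]))
  ld <- abs(log2(tr$true_r_disease[trend]))
  expect_true(all(lt > log2(t@fc_high) & lt < ld))
})

test_that("the noise-free limit recovers every truth label exactly", {
  cfg <- simConfig(n_proteins = 600L, cv_technical = 0,
                   frac_exclusive = 0, seed = 13L)
  sim <- simulateProteomes(cfg)
  cl <- classifyProteins(computeRatios(aggregateReplicates(sim$experiment)),
                         level = "strict")
  expect_identical(cl$regulation_call, sim$truth$true_regulation_strict)
  expect_identical(cl$normalisation_call,
                   sim$truth$true_normalisation_strict)
  ev <- evaluateRecovery(sim$truth, cl, level = "strict")
  expect_equal(ev$error_pp, 0)
  conf <- ev$confusion_regulation
  expect_identical(sum(conf) - sum(diag(conf)), 0L)
})

test_that("planted dysregulation counts fluctuate like a binomial", {
  n <- 1000L
  p <- 0.6
  # count via planted ratio magnitudes (exclusives have no ratio and are
  # drawn independently, widening the band slightly)
  dys <- vapply(1:25, function(s) {
    tr <- simulateProteomes(simConfig(n_proteins = n, frac_dysregulated = p,
                                      seed = s))$truth
    sum(!is.na(tr$true_r_disease) &
          (tr$true_r_disease > 2 | tr$true_r_disease < 0.5))
  }, 0L)
  sd_bin <- sqrt(n * p * (1 - p))
  expect_true(all(abs(dys - n * p) < 3.5 * sd_bin + n * 0.05))
})

test_that("all-unregulated calls score zero regulation recall", {
  sim <- simulateProteomes(simConfig(n_proteins = 200L, seed = 31L))
  cl <- classifyProteins(computeRatios(aggregateReplicates(sim$experiment)),
                         level = "strict")
  cl$regulation_call <- "unregulated"
  cl$normalisation_call <- "not_applicable"
  ev <- evaluateRecovery(sim$truth, cl)
  conf <- ev$confusion_regulation
  expect_identical(sum(conf[c("regulated_up", "regulated_down"),
                            c("regulated_up", "regulated_down")]), 0L)
  expect_true(is.na(ev$pct_normalised_called))

  cl2 <- cl[-1, ]
  expect_error(evaluateRecovery(sim$truth, cl2),
               class = "prn_alignment_error")
})

test_that("moderate technical noise still recovers the planted normalised fraction", {
  errs <- vapply(1:10, function(s) {
    sim <- simulateProteomes(simConfig(n_proteins = 2000L,
                                       cv_technical = 0.1,
                                       n_replicates = 3L, seed = 100L + s))
    cl <- classifyProteins(computeRatios(aggregateReplicates(sim$experiment)),
                           level = "strict")
    abs(evaluateRecovery(sim$truth, cl)$pct_normalised_called - 47)
  }, 0)
  expect_true(mean(errs <= 3) >= 0.9)
})
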