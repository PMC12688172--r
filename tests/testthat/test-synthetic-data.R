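test_that("cohort generation is bit-identical under a fixed seed", {
  cfg <- strong_cohort_config(50, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- strong_cohort_config(50, seed = 8)
  expect_false(identical(generate_cohort(cfg)$cohort,
                         generate_cohort(cfg2)$cohort))
})

test_that("null cohort recovers the configured baseline rate", {
  cfg <- cohort_config(
    n_patients = 10000,
    predictor_prevalences = c(cNpos = 0.4),
    baseline_log_rate = c(eCTC = log(2), emCTC = log(2), mCTC = log(2)),
    seed = 21
  )
  coh <- generate_cohort(cfg)$cohort
  for (ph in c("eCTC", "emCTC", "mCTC")) {
    se <- sqrt(2 / 10000)  # Poisson(2) mean has sd sqrt(lambda/n)
    expect_lt(abs(mean(coh[[ph]]) - 2), 3 * se)
  }
})

test_that("configured IRRs reappear as ratios of group means", {
  cfg <- cohort_config(
    n_patients = 20000,
    predictor_prevalences = c(cNpos = 0.4),
    true_log_irr = rbind(mCTC = c(cNpos = log(2.85))),
    baseline_log_rate = c(eCTC = 0, emCTC = 0, mCTC = log(1.1)),
    seed = 33
  )
  coh <- generate_cohort(cfg)$cohort
  pos <- coh$cNpos == 1
  ratio <- mean(coh$mCTC[pos]) / mean(coh$mCTC[!pos])
  # SE of the log rate ratio for Poisson group totals
  se_log <- sqrt(1 / sum(coh$mCTC[pos]) + 1 / sum(coh$mCTC[!pos]))
  expect_lt(abs(log(ratio) - log(2.85)), 3 * se_log)
})

test_that("cohort marginals are Poisson (goodness of fit at alpha 0.01)", {
  cfg <- cohort_config(
    n_patients = 10000,
    predictor_prevalences = c(x = 0.5),
    baseline_log_rate = c(eCTC = log(3), emCTC = 0, mCTC = 0),
    seed = 55
  )
  y <- generate_cohort(cfg)$cohort$eCTC
  lambda <- mean(y)
  breaks <- 0:8
  obs <- c(vapply(breaks, function(k) sum(y == k), 0), sum(y > max(breaks)))
  prob <- c(dpois(breaks, lambda), ppois(max(breaks), lambda,
                                         lower.tail = FALSE))
  p <- suppressWarnings(chisq.test(obs, p = prob)$p.value)
  expect_gt(p, 0.01)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(10, c(a = 0)), "strictly in")
  expect_error(cohort_config(10, c(a = 1)), "strictly in")
  expect_error(cohort_config(10, c(0.5)), "named")
  expect_error(
    cohort_config(10, c(a = 0.5),
                  baseline_log_rate = c(eCTC = Inf, emCTC = 0, mCTC = 0)),
    "finite")
  expect_error(
    cohort_config(10, c(a = 0.5),
                  true_log_irr = rbind(bad = c(a = 1))),
    "phenotype set")
})

test_that("expression generation honours class- and panel-specific shifts", {
  cfg <- cellsim_config(
    n_cells_per_class = c(eCTC = 100, mCTC = 100),
    n_genes = 80,
    panel_genes = list(ribosomal = sprintf("RPL%d", 1:20)),
    mean_shift_log2 = list(mCTC = c(ribosomal = -2)),
    dispersion = 2, dropout_rate = 0.1, seed = 9
  )
  sim <- generate_expression(cfg)
  ribo <- sim$panels$ribosomal
  m_mean <- mean(sim$counts[ribo, sim$cell_class == "mCTC"])
  e_mean <- mean(sim$counts[ribo, sim$cell_class == "eCTC"])
  expect_lt(m_mean, e_mean)
  # the configured generative means are the oracle: a -2 shift quarters them
  truth <- sim$truth$class_mean
  expect_equal(truth[ribo, "mCTC"], truth[ribo, "eCTC"] / 4)
})

test_that("expression generation is deterministic and dropout saturates", {
  cfg <- cellsim_config(
    n_cells_per_class = c(A = 10), n_genes = 30,
    panel_genes = list(p = c("G1", "G2")),
    dispersion = 1, dropout_rate = 0.5, seed = 4
  )
  expect_identical(generate_expression(cfg)$counts,
                   generate_expression(cfg)$counts)
  cfg_all_drop <- cellsim_config(
    n_cells_per_class = c(A = 10), n_genes = 30,
    panel_genes = list(p = c("G1", "G2")),
    dispersion = 1, dropout_rate = 1, seed = 4
  )
  expect_true(all(generate_expression(cfg_all_drop)$counts == 0))
})

test_that("large dispersion approaches the Poisson variance/mean limit", {
  cfg <- cellsim_config(
    n_cells_per_class = c(A = 3000), n_genes = 4,
    panel_genes = list(p = "G1"),
    mean_shift_log2 = list(),
    dispersion = 1e6, dropout_rate = 0,
    base_mean_log_mu = log(10), base_mean_log_sd = 0,
    seed = 12
  )
  counts <- generate_expression(cfg)$counts
  ratio <- apply(counts, 1, var) / rowMeans(counts)
  # sampling error of the index of dispersion is ~sqrt(2/n) ~ 0.026
  expect_true(all(abs(ratio - 1) < 4 * sqrt(2 / 3000)))
})

test_that("invalid cell simulation configurations are rejected", {
  expect_error(
    cellsim_config(c(A = 5), 10, list(a = "G1", b = "G1")),
    "disjoint")
  expect_error(
    cellsim_config(c(A = 5), 1, list(a = c("G1", "G2"))),
    "at least the total")
  expect_error(
    cellsim_config(c(A = 5), 10, list(a = character()),
                   mean_shift_log2 = list(A = c(a = -1))),
    "empty panel")
  expect_error(
    cellsim_config(c(A = 5), 10, list(a = "G1"),
                   mean_shift_log2 = list(A = c(zzz = -1))),
    "unknown panel")
})
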