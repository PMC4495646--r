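test_that("row t-tests agree with the t.test oracle", {
  set.seed(61)
  x <- matrix(rnorm(20 * 7), 20, 7)
  g <- c(rep("a", 3), rep("b", 4))
  for (mode in c("pooled", "welch")) {
    dm <- row_ttest(x, g, variance_mode = mode)
    for (i in c(1, 7, 20)) {
      o <- t.test(x[i, g == "b"], x[i, g == "a"],
                  var.equal = (mode == "pooled"))
      expect_equal(dm$effect_hat[i], unname(o$estimate[1] - o$estimate[2]),
                   tolerance = 1e-12)
      expect_equal(dm$t_stat[i], unname(o$statistic), tolerance = 1e-10)
      expect_equal(dm$p_value[i], o$p.value, tolerance = 1e-10)
      expect_equal(dm$df[i], unname(o$parameter), tolerance = 1e-8)
    }
  }
  # textbook pooled case: g1 = {1,2,3}, g2 = {2,3,4} -> |t| = 1.2247
  dm1 <- row_ttest(rbind(c(1, 2, 3, 2, 3, 4), c(1, 2, 3, 2, 3, 4)),
                   c("a", "a", "a", "b", "b", "b"))
  expect_equal(dm1$effect_hat[1], 1)
  expect_equal(abs(dm1$t_stat[1]), 1.2247, tolerance = 1e-4)

  expect_error(row_ttest(x, rep("a", 7)), "two-group")
  expect_error(row_ttest(x, c("a", rep("b", 6))), ">= 2 samples")
})

test_that("degenerate rows get p = 1 with a flag instead of being dropped", {
  x <- rbind(c(1, 1, 1, 1), c(0, 0, 1, 1), c(1, 2, 3, 4))
  dm <- row_ttest(x, c("a", "a", "b", "b"))
  expect_true(dm$degenerate[1])
  expect_true(dm$degenerate[2])  # zero within-group variance, nonzero effect
  expect_false(dm$degenerate[3])
  expect_equal(dm$p_value[1:2], c(1, 1))
  expect_equal(dm$t_stat[1:2], c(0, 0))
  expect_equal(dm$effect_hat[1:2], c(0, 1))
})

test_that("BH adjustment matches the step-up formula and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(71)
  p <- runif(100)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("selection scoring counts discoveries against the truth", {
  n <- 1000
  truth <- simulate_truth(n, pi_dm = 0.05, seed = 81)
  # build a synthetic dm_result with full control over p-values
  p <- rep(0.5, n)
  dm <- structure(list(feature_ids = truth$cpg_ids,
                       effect_hat = truth$dm_delta,
                       t_stat = rep(0, n), p_value = p,
                       p_adjusted = bh_adjust(p), df = rep(8, n),
                       degenerate = rep(FALSE, n),
                       variance_mode = "pooled"),
                  class = "dm_result")
  # empty selection
  s0 <- score_selection(dm, truth, list(type = "fdr", q = 0.01))
  expect_equal(s0$n_selected, 0L)
  expect_equal(s0$n_false_discoveries, 0L)
  expect_equal(s0$tpr, 0)
  expect_equal(s0$fpr, 0)
  # perfect effect estimates -> zero bias and MSE
  expect_equal(s0$bias, 0)
  expect_equal(s0$mse, 0)

  # exactly the true DM set selected
  dm$p_value <- ifelse(truth$dm_mask, 1e-8, 0.9)
  dm$p_adjusted <- bh_adjust(dm$p_value)
  s1 <- score_selection(dm, truth)
  expect_equal(s1$tpr, 1)
  expect_equal(s1$fpr, 0)
  expect_equal(s1$n_false_discoveries, 0L)

  # counting oracle: 10 selected of which 4 non-DM, 50 DM of 1000
  tr <- simulate_truth(1000, pi_dm = 0.05, seed = 82)  # 50 DM
  dm_idx <- which(tr$dm_mask)[1:6]
  null_idx <- which(!tr$dm_mask)[1:4]
  p2 <- rep(0.99, 1000)
  p2[c(dm_idx, null_idx)] <- 1e-9
  dm2 <- structure(list(feature_ids = tr$cpg_ids, effect_hat = tr$dm_delta,
                        t_stat = rep(0, 1000), p_value = p2,
                        p_adjusted = bh_adjust(p2), df = rep(8, 1000),
                        degenerate = rep(FALSE, 1000),
                        variance_mode = "pooled"),
                   class = "dm_result")
  s2 <- score_selection(dm2, tr)
  expect_equal(s2$n_selected, 10L)
  expect_equal(s2$n_false_discoveries, 4L)
  expect_equal(s2$tpr, 6 / 50)
  expect_equal(s2$fpr, 4 / 950)

  # top-M rule picks the M smallest p-values
  s3 <- score_selection(dm2, tr, list(type = "top", m = 10))
  expect_equal(s3$n_selected, 10L)
  expect_equal(s3$n_false_discoveries, 4L)

  expect_error(score_selection(dm2, simulate_truth(500, 0.05, seed = 1)),
               "different numbers")
})

test_that("ROC sweeps are monotone in the selection threshold", {
  truth <- simulate_truth(3000, pi_dm = 0.1, seed = 91)
  arr <- simulate_arrays(truth, seed = 92)
  dm <- row_ttest(arr$beta_observed, arr$groups)
  ms <- c(0, 10, 50, 200, 1000, 3000)
  sweep <- t(vapply(ms, function(m) {
    s <- score_selection(dm, truth, list(type = "top", m = m))
    c(tpr = s$tpr, fpr = s$fpr)
  }, numeric(2)))
  expect_true(all(diff(sweep[, "tpr"]) >= 0))
  expect_true(all(diff(sweep[, "fpr"]) >= 0))
  expect_equal(sweep[nrow(sweep), ], c(tpr = 1, fpr = 1))
})

test_that("run_study produces a long table and honors the shared-branch contract", {
  study <- run_study(pi_dm = 0, tech_var = 0.05, n_reps = 2,
                     n_cpgs = 800, b = 30, seed = 5)
  expect_equal(nrow(study), 4L)
  expect_setequal(unique(study$method), c("qn", "guided"))
  # whenever the guided test accepts, both branches are bit-identical
  acc <- study[study$perm_p >= 0.05, ]
  if (nrow(acc)) {
    for (r in unique(acc$rep)) {
      pair <- acc[acc$rep == r, ]
      expect_equal(pair$n_false_discoveries[1], pair$n_false_discoveries[2])
      expect_equal(pair$mse[1], pair$mse[2])
      expect_equal(pair$applied, rep("quantile", 2))
    }
  }
  # reproducibility from the master seed
  study2 <- run_study(pi_dm = 0, tech_var = 0.05, n_reps = 2,
                      n_cpgs = 800, b = 30, seed = 5)
  expect_identical(study, study2)

  # empty grid contract
  empty <- run_study(n_reps = 0, n_cpgs = 100, seed = 1)
  expect_equal(nrow(empty), 0L)

  summ <- summarize_study(study)
  expect_equal(nrow(summ), 1L)
  expect_equal(summ$n_reps, 2)
})

test_that("under no true DM the realized FPR at BH q = 0.05 is conservative", {
  study <- run_study(pi_dm = 0, tech_var = 0.05, n_reps = 5,
                     n_cpgs = 2000, b = 30, seed = 17)
  expect_lt(mean(study$fpr[study$method == "guided"]), 0.05 + 0.02)
  expect_lt(mean(study$fpr[study$method == "qn"]), 0.05 + 0.02)
})
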