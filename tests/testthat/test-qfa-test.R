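test_that("the F statistic reproduces hand-derived values", {
  we <- worked_example()
  r <- qfa_stat(we$x, we$groups)
  expect_equal(r$f_stat, 18)
  expect_equal(r$df_between, 1L)
  expect_equal(r$df_within, 2L)

  # pure location shifts between groups vanish after median centering
  x <- cbind(c(1, 2, 3), c(1, 2, 3), c(3, 4, 5), c(3, 4, 5))
  expect_equal(qfa_stat(x, c("a", "a", "b", "b"))$f_stat, 0)

  # all columns identical
  x2 <- matrix(rep(c(2, 7, 9), 4), 3, 4)
  expect_equal(qfa_stat(x2, c("a", "a", "b", "b"))$f_stat, 0)
})

test_that("F matches the literal-sum brute-force oracle on small matrices", {
  set.seed(7)
  for (r in 1:50) {
    n_feat <- sample(2:5, 1)
    sizes <- sample(list(c(2, 2), c(2, 3), c(3, 3), c(2, 2, 2)), 1)[[1]]
    rm <- random_grouped_matrix(n_feat, sizes,
                                rdist = function(n) rcauchy(n))
    got <- qfa_stat(rm$x, rm$groups)$f_stat
    want <- oracle_f_stat(rm$x, rm$groups)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("the statistic is location invariant and scale equivariant", {
  set.seed(11)
  rm <- random_grouped_matrix(80, c(3, 4))
  base <- qfa_stat(rm$x, rm$groups)
  shifted <- rm$x + matrix(rnorm(ncol(rm$x), sd = 10),
                           nrow(rm$x), ncol(rm$x), byrow = TRUE)
  expect_equal(qfa_stat(shifted, rm$groups)$f_stat, base$f_stat,
               tolerance = 1e-10)
  scaled <- qfa_stat(rm$x * 3, rm$groups)
  expect_equal(scaled$f_stat, base$f_stat, tolerance = 1e-10)
  expect_equal(scaled$ss_total, base$ss_total * 9, tolerance = 1e-10)
  expect_equal(scaled$ss_between, base$ss_between * 9, tolerance = 1e-10)
  expect_equal(scaled$ss_within, base$ss_within * 9, tolerance = 1e-10)
})

test_that("median ANOVA agrees with the one-way ANOVA oracle", {
  # medians {1,2} vs {4,5}: SSB = 9, SSW = 1, df = (1,2) -> F = 18
  x <- rbind(c(1, 2, 4, 5), c(1, 2, 4, 5), c(1, 2, 4, 5))
  ma <- median_anova(x, c("a", "a", "b", "b"))
  oracle <- oneway.test(c(1, 2, 4, 5) ~ factor(c("a", "a", "b", "b")),
                        var.equal = TRUE)
  expect_equal(ma$f_stat, 18)
  expect_equal(ma$f_stat, unname(oracle$statistic))
  expect_equal(ma$p_value, oracle$p.value)

  set.seed(3)
  rm <- random_grouped_matrix(30, c(3, 4, 2))
  ma2 <- median_anova(rm$x, rm$groups)
  meds <- apply(rm$x, 2, median)
  o2 <- oneway.test(meds ~ rm$groups, var.equal = TRUE)
  expect_equal(ma2$f_stat, unname(o2$statistic))
  expect_equal(ma2$p_value, o2$p.value)
})

test_that("median ANOVA degenerate conventions", {
  x_eq <- matrix(rep(c(0, 1, 2), 4), 3, 4)  # all medians equal
  ma <- median_anova(x_eq, c("a", "a", "b", "b"))
  expect_equal(ma$f_stat, 0)
  expect_equal(ma$p_value, 1)
  expect_false(ma$degenerate)

  # within-group medians constant, groups differ -> infinite F, flagged
  x_inf <- cbind(c(0, 1, 2), c(0, 1, 2), c(5, 6, 7), c(5, 6, 7))
  mi <- median_anova(x_inf, c("a", "a", "b", "b"))
  expect_equal(mi$f_stat, Inf)
  expect_equal(mi$p_value, 0)
  expect_true(mi$degenerate)
})

test_that("exhaustive permutation enumerates all relabelings of the worked example", {
  we <- worked_example()
  t <- qfa_test(we$x, we$groups, exhaustive = TRUE)
  expect_equal(t$b, 6L)  # 4!/(2!2!) label vectors
  expect_equal(sort(unique(round(t$perm_stats, 10))),
               round(c(0, 2 / 9, 18), 10))
  expect_equal(t$perm_p, 1 / 3)

  expect_error(
    qfa_test(we$x, we$groups, exhaustive = TRUE, exhaustive_cap = 3L),
    "use random permutations")
})

test_that("random-permutation p-values respect the add-one convention and seed", {
  set.seed(5)
  rm <- random_grouped_matrix(40, c(4, 4))
  t1 <- qfa_test(rm$x, rm$groups, b = 19, seed = 123)
  expect_gte(t1$perm_p, 1 / 20)
  expect_lte(t1$perm_p, 1)
  expect_length(t1$perm_stats, 19)
  t2 <- qfa_test(rm$x, rm$groups, b = 19, seed = 123)
  expect_identical(t1$perm_p, t2$perm_p)
  expect_identical(t1$perm_stats, t2$perm_stats)

  # ties with the observed statistic count as exceedances: under a constant
  # matrix every permutation ties F_obs = 0, so p = 1
  x0 <- matrix(rep(c(1, 2, 3), 4), 3, 4)
  t0 <- qfa_test(x0, c("a", "a", "b", "b"), b = 25, seed = 1)
  expect_equal(t0$perm_p, 1)
})

test_that("degenerate F conventions: zero within-variance yields +Inf", {
  x <- cbind(c(-1, 0, 1), c(-1, 0, 1), c(-3, 0, 3), c(-3, 0, 3))
  r <- qfa_stat(x, c("a", "a", "b", "b"))
  expect_equal(r$ss_within, 0)
  expect_identical(r$f_stat, Inf)
  # an infinite observed F still ties infinite permuted F values
  t <- qfa_test(x, c("a", "a", "b", "b"), exhaustive = TRUE)
  expect_equal(t$perm_p, 1 / 3)
})

test_that("JSON serialization carries the full result record", {
  skip_if_not_installed("jsonlite")
  we <- worked_example()
  t <- qfa_test(we$x, we$groups, exhaustive = TRUE)
  js <- jsonlite::fromJSON(qfa_result_json(t, include_perm_stats = TRUE))
  expect_equal(js$f_stat, 18)
  expect_equal(js$perm_p, 1 / 3)
  expect_equal(js$df_between, 1)
  expect_length(js$perm_stats, 6)
  expect_false(js$median_anova$degenerate)
})
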