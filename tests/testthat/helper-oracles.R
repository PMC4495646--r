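# Independent brute-force oracles used to cross-check the implementation.
# These literally evaluate the defining sums with explicit loops and never
# share code with the package internals.

# F statistic by literal evaluation of the between/within sums of squared
# Mallow distances over median-centered, sorted columns.
oracle_f_stat <- function(x, groups) {
  v <- sweep(x, 2L, apply(x, 2L, median), "-")
  q <- apply(v, 2L, sort)
  g <- factor(groups)
  k <- nlevels(g)
  n_t <- ncol(q)
  grand <- rowMeans(q)
  ssb <- 0
  ssw <- 0
  for (lev in levels(g)) {
    cols <- which(g == lev)
    gm <- rowMeans(q[, cols, drop = FALSE])
    ssb <- ssb + length(cols) * mean((gm - grand)^2)
    for (j in cols) ssw <- ssw + mean((q[, j] - gm)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n_t - k)
  if (msw > 0) msb / msw else if (msb > 0) Inf else 0
}

# random grouped matrix; unbalanced designs allowed
random_grouped_matrix <- function(n_features, group_sizes,
                                  rdist = function(n) rnorm(n)) {
  n_t <- sum(group_sizes)
  x <- matrix(rdist(n_features * n_t), n_features, n_t)
  groups <- factor(rep(seq_along(group_sizes), times = group_sizes))
  list(x = x, groups = groups)
}

# the worked 3-feature, 2+2-sample example (already median-centered)
worked_example <- function() {
  x <- cbind(a1 = c(-1, 0, 1), a2 = c(-2, 0, 2),
             b1 = c(-4, 0, 4), b2 = c(-5, 0, 5))
  list(x = x, groups = factor(c("a", "a", "b", "b")))
}
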