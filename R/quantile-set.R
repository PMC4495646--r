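#' Empirical quantile functions of a grouped matrix
#'
#' Computes, for each sample column, the empirical quantile function (the
#' vector of order statistics), optionally after subtracting that sample's
#' own median, plus the within-group mean quantile functions and the grand
#' mean quantile function.
#'
#' The grand mean is the sample-size-weighted mean of the per-sample
#' quantile functions (equivalently the unweighted mean over all columns),
#' under which the between/within sum-of-squares decomposition is exact
#' also for unbalanced designs; for balanced designs it coincides with the
#' unweighted mean over group means.
#'
#' All quantile functions share the implied probability grid
#' (j - 0.5) / n_features; because the grid is common to every sample it
#' never enters the arithmetic.
#'
#' @param x A [feature_matrix()], or a numeric matrix together with `groups`.
#' @param groups Group labels when `x` is a plain matrix.
#' @param median_center Subtract each sample's median before sorting
#'   (default `TRUE`). This makes the downstream F statistic invariant to
#'   per-sample location shifts.
#' @return An object of class `"quantile_set"`: list with `sample_qfs`
#'   (n_features x n_samples, each column sorted ascending),
#'   `group_mean_qfs` (n_features x K), `grand_mean_qf`, `groups`, `probs`
#'   and `median_center`.
#' @examples
#' qs <- quantile_set(matrix(rnorm(30), 10, 3), groups = c("a", "a", "b"))
#' all(diff(qs$sample_qfs[, 1]) >= 0)
#' @export
quantile_set <- function(x, groups = NULL, median_center = TRUE) {
  x <- .as_feature_matrix(x, groups)
  v <- x$values
  if (median_center) {
    v <- sweep(v, 2L, apply(v, 2L, stats::median), "-")
  }
  q <- apply(v, 2L, sort, method = "radix")
  if (!is.matrix(q)) q <- matrix(q, nrow = x$n_features)
  colnames(q) <- colnames(x$values)
  gm <- vapply(levels(x$groups),
               function(g) rowMeans(q[, x$groups == g, drop = FALSE]),
               numeric(nrow(q)))
  structure(
    list(sample_qfs = q, group_mean_qfs = gm, grand_mean_qf = rowMeans(q),
         groups = x$groups,
         probs = (seq_len(nrow(q)) - 0.5) / nrow(q),
         median_center = median_center),
    class = "quantile_set")
}

#' Squared Mallow's (Wasserstein-2) distance between two quantile functions
#'
#' For two distributions represented by equal-length sorted vectors of
#' order statistics on a shared probability grid, the squared Mallow's
#' distance with p = 2 is approximated by the mean squared difference
#' `mean((qf_a - qf_b)^2)`. The 1/n scaling makes values comparable across
#' feature counts; any constant scaling cancels in the F statistic.
#'
#' @param qf_a,qf_b Equal-length non-decreasing numeric vectors.
#' @return Non-negative scalar; zero iff the vectors are identical.
#' @examples
#' mallows2(c(1, 3, 5), c(2, 2, 6))  # 1
#' @export
mallows2 <- function(qf_a, qf_b) {
  if (length(qf_a) != length(qf_b)) {
    stop("quantile functions have different lengths (",
         length(qf_a), " vs ", length(qf_b), ")", call. = FALSE)
  }
  if (length(qf_a) == 0L) stop("empty quantile function", call. = FALSE)
  mean((qf_a - qf_b)^2)
}

#' Between/within decomposition of quantile-function variation
#'
#' Decomposes the total squared Mallow-distance variation of the sample
#' quantile functions about the grand mean into a between-group and a
#' within-group component:
#' \deqn{SS_{total} = \sum_k \sum_i d^2(F_{ik}^{-1}, \bar F_{..}^{-1}),\quad
#'       SS_{between} = \sum_k n_k d^2(\bar F_{.k}^{-1}, \bar F_{..}^{-1}),\quad
#'       SS_{within} = \sum_k \sum_i d^2(F_{ik}^{-1}, \bar F_{.k}^{-1})}
#' with \eqn{d^2} the squared Mallow's distance of [mallows2()]. With the
#' weighted grand-mean convention the additive identity
#' `ss_total = ss_between + ss_within` is exact.
#'
#' @param qs A [quantile_set()].
#' @return List with `ss_total`, `ss_between`, `ss_within`.
#' @export
ss_decompose <- function(qs) {
  stopifnot(inherits(qs, "quantile_set"))
  q <- qs$sample_qfs
  gm <- qs$group_mean_qfs
  grand <- qs$grand_mean_qf
  g <- qs$groups
  nk <- .group_sizes(g)
  ss_total <- sum(colMeans((q - grand)^2))
  ss_between <- sum(nk * colMeans((gm - grand)^2))
  ss_within <- sum(colMeans((q - gm[, as.integer(g), drop = FALSE])^2))
  list(ss_total = ss_total, ss_between = ss_between, ss_within = ss_within)
}
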