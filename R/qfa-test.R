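#' One-way ANOVA on per-sample medians
#'
#' Diagnostic pre-step to the distribution test: a fixed-effects one-way
#' ANOVA asking whether the average of the per-sample medians differs
#' across groups, i.e. whether the groups differ in location before any
#' shape comparison. Computed as a fixed-effects linear-model ANOVA
#' ([stats::lm()] + [stats::anova()]); degenerate cases (zero
#' within-group variance of the medians) are resolved by convention: F = 0, p = 1 when the group
#' means of medians also coincide, otherwise F = Inf, p = 0 with
#' `degenerate = TRUE`.
#'
#' @param x A [feature_matrix()], or matrix plus `groups`.
#' @param groups Group labels when `x` is a plain matrix.
#' @return List with `f_stat`, `p_value`, `df` (c(K - 1, n_T - K)),
#'   `medians` and `degenerate` flag.
#' @export
median_anova <- function(x, groups = NULL) {
  x <- .as_feature_matrix(x, groups)
  .check_test_design(x)
  meds <- apply(x$values, 2L, stats::median)
  g <- x$groups
  df <- c(x$k - 1L, x$n_samples - x$k)
  grp_means <- tapply(meds, g, mean)
  ssw <- sum((meds - grp_means[as.integer(g)])^2)
  ssb <- sum(.group_sizes(g) * (grp_means - mean(meds))^2)
  scale <- max(1, ssb + ssw)
  if (ssw <= 1e-12 * scale) {
    if (ssb <= 1e-12 * scale) {
      return(list(f_stat = 0, p_value = 1, df = df, medians = meds,
                  degenerate = FALSE))
    }
    return(list(f_stat = Inf, p_value = 0, df = df, medians = meds,
                degenerate = TRUE))
  }
  tab <- stats::anova(stats::lm(meds ~ g))  # handles singleton groups
  list(f_stat = tab[["F value"]][1L], p_value = tab[["Pr(>F)"]][1L], df = df,
       medians = meds, degenerate = FALSE)
}

# F statistic from pre-sorted (optionally centered) sample quantile
# functions and an arbitrary relabeling; the permutation engine.
.qfa_f_from_qfs <- function(q, groups) {
  g <- as.integer(groups)
  k <- nlevels(groups)
  nk <- tabulate(g, nbins = k)
  n_t <- ncol(q)
  a <- matrix(0, n_t, k)
  a[cbind(seq_len(n_t), g)] <- 1 / nk[g]
  gm <- q %*% a
  grand <- rowMeans(q)
  ss_between <- sum(nk * colMeans((gm - grand)^2))
  ss_within <- sum(colMeans((q - gm[, g, drop = FALSE])^2))
  ms_between <- ss_between / (k - 1L)
  ms_within <- ss_within / (n_t - k)
  f <- if (ms_within > 0) ms_between / ms_within
       else if (ms_between > 0) Inf else 0
  list(f = f, ss_between = ss_between, ss_within = ss_within,
       ms_between = ms_between, ms_within = ms_within)
}

#' Quantile-function F statistic for global distribution differences
#'
#' Computes the F-type statistic comparing between-group to within-group
#' squared Mallow-distance variation of the per-sample empirical quantile
#' functions,
#' \deqn{F = \frac{MS_{between}}{MS_{within}} =
#'       \frac{SS_{between}/(K-1)}{SS_{within}/(n_T-K)}.}
#' Samples are median-centered first (see [quantile_set()]); the median
#' ANOVA is attached as a location diagnostic. Large F indicates the
#' groups differ globally in distribution shape/spread, in which case
#' global-adjustment normalization (quantile normalization) would remove
#' biological signal.
#'
#' @param x A [feature_matrix()], or matrix plus `groups`.
#' @param groups Group labels when `x` is a plain matrix.
#' @param median_center Median-center samples first (default `TRUE`).
#' @return Object of class `"qfa_result"` with the SS/MS components,
#'   `f_stat`, degrees of freedom and `median_anova` (no permutation
#'   fields; see [qfa_test()]).
#' @examples
#' x <- cbind(a1 = c(-1, 0, 1), a2 = c(-2, 0, 2),
#'            b1 = c(-4, 0, 4), b2 = c(-5, 0, 5))
#' r <- qfa_stat(rbind(x, x[0, ]), groups = c("a", "a", "b", "b"))
#' r$f_stat  # 18
#' @export
qfa_stat <- function(x, groups = NULL, median_center = TRUE) {
  x <- .as_feature_matrix(x, groups)
  .check_test_design(x)
  qs <- quantile_set(x, median_center = median_center)
  ss <- ss_decompose(qs)
  df_between <- x$k - 1L
  df_within <- x$n_samples - x$k
  ms_between <- ss$ss_between / df_between
  ms_within <- ss$ss_within / df_within
  f <- if (ms_within > 0) ms_between / ms_within
       else if (ms_between > 0) Inf else 0
  structure(
    list(ss_total = ss$ss_total, ss_between = ss$ss_between,
         ss_within = ss$ss_within,
         ms_between = ms_between, ms_within = ms_within,
         f_stat = f, df_between = df_between, df_within = df_within,
         median_anova = median_anova(x),
         n_samples = x$n_samples, k = x$k, group_sizes = .group_sizes(x$groups)),
    class = "qfa_result")
}

# all distinct label vectors preserving the multiset of labels
.all_label_assignments <- function(groups, cap = 10000L) {
  g <- as.integer(groups)
  n_t <- length(g)
  nk <- tabulate(g, nbins = nlevels(groups))
  n_assign <- round(exp(lgamma(n_t + 1) - sum(lgamma(nk + 1))))
  if (n_assign > cap) {
    stop(sprintf(
      "exhaustive enumeration needs %d assignments (cap %d); use random permutations",
      n_assign, cap), call. = FALSE)
  }
  out <- matrix(NA_integer_, n_t, n_assign)
  col <- 0L
  rec <- function(prefix, remaining) {
    if (!length(remaining)) {
      col <<- col + 1L
      out[, col] <<- prefix
      return(invisible())
    }
    for (lab in unique(remaining)) {
      rec(c(prefix, lab), remaining[-match(lab, remaining)])
    }
  }
  rec(integer(0), sort(g))
  out
}

#' Permutation test for global differences in distributions
#'
#' Assesses the significance of the quantile-function F statistic
#' ([qfa_stat()]) by permuting group labels. Because median centering and
#' sorting are per-sample operations they are label-invariant, so each
#' permutation recomputes the between/within decomposition on the fixed
#' sorted columns — identical to re-running the full pipeline under the
#' permuted grouping.
#'
#' Random permutations are uniform relabelings preserving group sizes
#' (duplicates allowed), pre-generated from `seed` before any dispatch so
#' the result is independent of worker count. The p-value uses the add-one
#' convention `(1 + #\{F_b >= F_obs\}) / (B + 1)`; ties count as
#' exceedances, so `perm_p >= 1/(B + 1)`. With `exhaustive = TRUE` all
#' distinct label assignments (including the identity) are enumerated and
#' `perm_p = #\{F_b >= F_obs\} / B_exhaustive`.
#'
#' @param x A [feature_matrix()], or matrix plus `groups`.
#' @param groups Group labels when `x` is a plain matrix.
#' @param b Number of random permutations (default 1000).
#' @param seed Integer seed for the permutation draws (optional).
#' @param exhaustive Enumerate all distinct assignments instead of
#'   sampling; errors when their number exceeds `exhaustive_cap`.
#' @param alpha Significance level for the `global_differences` flag
#'   (default 0.05).
#' @param exhaustive_cap Maximum number of assignments enumerated.
#' @param keep_perm_stats Keep the vector of permutation F values.
#' @return Object of class `"qfa_result"`: all [qfa_stat()] fields plus
#'   `perm_p`, `b` (permutations used), `perm_stats` (if kept), `alpha`,
#'   `exhaustive` and `global_differences = perm_p < alpha`.
#' @examples
#' x <- matrix(rnorm(400), 100, 4)
#' qfa_test(x, groups = c("a", "a", "b", "b"), b = 99, seed = 1)
#' @export
qfa_test <- function(x, groups = NULL, b = 1000L, seed = NULL,
                     exhaustive = FALSE, alpha = 0.05,
                     exhaustive_cap = 10000L, keep_perm_stats = TRUE) {
  x <- .as_feature_matrix(x, groups)
  .check_test_design(x, permutation = TRUE)
  if (!exhaustive && (!is.numeric(b) || b < 1L)) {
    stop("'b' must be a positive integer", call. = FALSE)
  }
  res <- qfa_stat(x)
  q <- quantile_set(x)$sample_qfs
  f_obs <- .qfa_f_from_qfs(q, x$groups)$f

  if (exhaustive) {
    labs <- .all_label_assignments(x$groups, cap = exhaustive_cap)
    perm_f <- apply(labs, 2L, function(gg) {
      .qfa_f_from_qfs(q, factor(gg, levels = seq_len(x$k)))$f
    })
    b_used <- ncol(labs)
    perm_p <- sum(perm_f >= f_obs) / b_used
  } else {
    b_used <- as.integer(b)
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
      set.seed(seed)
    }
    g_int <- as.integer(x$groups)
    # pre-generate every relabeling up front (worker-count independence)
    perms <- replicate(b_used, sample(g_int))
    perm_f <- apply(perms, 2L, function(gg) {
      .qfa_f_from_qfs(q, factor(gg, levels = seq_len(x$k)))$f
    })
    perm_p <- (1 + sum(perm_f >= f_obs)) / (b_used + 1)
  }
  res$perm_p <- perm_p
  res$b <- b_used
  res$exhaustive <- exhaustive
  res$alpha <- alpha
  res$global_differences <- perm_p < alpha
  if (keep_perm_stats) res$perm_stats <- perm_f
  res
}

#' @export
print.qfa_result <- function(x, ...) {
  cat("Quantile-function ANOVA for global distribution differences\n")
  cat(sprintf("  groups: %d, samples: %d\n", x$k, x$n_samples))
  cat(sprintf("  SS between: %.6g  SS within: %.6g  (total %.6g)\n",
              x$ss_between, x$ss_within, x$ss_total))
  cat(sprintf("  F = %.6g on (%d, %d) df\n",
              x$f_stat, x$df_between, x$df_within))
  cat(sprintf("  median ANOVA: F = %.4g, p = %.4g\n",
              x$median_anova$f_stat, x$median_anova$p_value))
  if (!is.null(x$perm_p)) {
    cat(sprintf("  permutation p = %.4g (%s%d permutations, alpha = %g)\n",
                x$perm_p, if (isTRUE(x$exhaustive)) "exhaustive, " else "",
                x$b, x$alpha))
    cat(sprintf("  global differences detected: %s\n",
                if (x$global_differences) "yes" else "no"))
  }
  invisible(x)
}

#' Serialize a test result to JSON
#'
#' @param x A `"qfa_result"` from [qfa_test()] or [qfa_stat()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @param include_perm_stats Include the permutation null draws.
#' @return JSON string (invisibly when written to `path`).
#' @export
qfa_result_json <- function(x, path = NULL, include_perm_stats = FALSE) {
  stopifnot(inherits(x, "qfa_result"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required for JSON output", call. = FALSE)
  }
  keep <- c("ss_total", "ss_between", "ss_within", "ms_between", "ms_within",
            "f_stat", "df_between", "df_within", "perm_p", "b", "alpha",
            "exhaustive", "global_differences", "n_samples", "k",
            "group_sizes")
  out <- x[intersect(keep, names(x))]
  out$median_anova <- x$median_anova[c("f_stat", "p_value", "degenerate")]
  if (include_perm_stats && !is.null(x$perm_stats)) {
    out$perm_stats <- x$perm_stats
  }
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
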