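#' Row-wise two-sample t-tests
#'
#' Per-feature two-group comparison: `effect_hat = mean(group2) -
#' mean(group1)` and the t statistic `effect_hat / se` with either the
#' pooled-variance (default) or Welch standard error; two-sided p-values
#' from the t distribution. Rows with zero within-group variance get
#' `t = 0`, `p = 1` and are flagged rather than dropped.
#'
#' @param x Numeric matrix, a [feature_matrix()] or a
#'   `"normalized_matrix"`.
#' @param groups Group labels (exactly 2 levels, each with >= 2 samples);
#'   taken from `x` when it carries them.
#' @param variance_mode `"pooled"` or `"welch"`.
#' @return Object of class `"dm_result"`: data.frame-like list with
#'   `effect_hat`, `t_stat`, `p_value`, `p_adjusted` (BH), `df`,
#'   `degenerate` flag per feature, plus `variance_mode`.
#' @export
row_ttest <- function(x, groups = NULL, variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  if (inherits(x, "normalized_matrix")) {
    if (is.null(groups)) groups <- x$groups
    x <- x$values
  } else if (inherits(x, "feature_matrix")) {
    if (is.null(groups)) groups <- x$groups
    x <- x$values
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2L) {
    stop("row_ttest is two-group by design (got ", nlevels(groups),
         " groups)", call. = FALSE)
  }
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (min(n1, n2) < 2L) stop("each group needs >= 2 samples", call. = FALSE)
  x1 <- x[, groups == levels(groups)[1L], drop = FALSE]
  x2 <- x[, groups == levels(groups)[2L], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  effect <- m2 - m1
  if (variance_mode == "pooled") {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(effect))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  degenerate <- se == 0 | !is.finite(se)
  t_stat <- ifelse(degenerate, 0, effect / se)
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(t_stat), df))
  structure(
    list(feature_ids = rownames(x) %||% sprintf("feature_%d", seq_along(effect)),
         effect_hat = unname(effect), t_stat = unname(t_stat),
         p_value = unname(p), p_adjusted = bh_adjust(unname(p)),
         df = unname(df), degenerate = unname(degenerate),
         variance_mode = variance_mode),
    class = "dm_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' [stats::p.adjust()] with input validation).
#'
#' @param p P-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Select differentially methylated features
#'
#' @param dm A [row_ttest()] result.
#' @param rule Either `list(type = "fdr", q = 0.05)` (BH-adjusted p <= q,
#'   the default) or `list(type = "top", m = M)` (the M smallest raw
#'   p-values, ties broken by |t| then index).
#' @return Logical selection vector.
#' @export
dm_select <- function(dm, rule = list(type = "fdr", q = 0.05)) {
  stopifnot(inherits(dm, "dm_result"))
  if (identical(rule$type, "fdr")) {
    return(dm$p_adjusted <= rule$q)
  }
  if (identical(rule$type, "top")) {
    m <- min(rule$m, length(dm$p_value))
    sel <- rep(FALSE, length(dm$p_value))
    if (m > 0L) {
      ord <- order(dm$p_value, -abs(dm$t_stat))
      sel[ord[seq_len(m)]] <- TRUE
    }
    return(sel)
  }
  stop("unknown selection rule type: ", rule$type, call. = FALSE)
}

#' Score a differential-methylation call against the truth
#'
#' Applies a selection rule and scores it against the simulated ground
#' truth: count of false discoveries, true/false positive rates, and the
#' bias and mean squared error of the effect estimate over the truly
#' differentially methylated CpGs.
#'
#' @param dm A [row_ttest()] result, aligned to `truth` (same CpGs, same
#'   order; checked via ids when both carry them).
#' @param truth A [simulate_truth()] result.
#' @param rule Selection rule, see [dm_select()].
#' @return List with `n_selected`, `n_false_discoveries`, `tpr`, `fpr`
#'   (`tpr` is `NaN` when no CpG is truly DM), `bias`, `mse` (over truly
#'   DM CpGs; `NaN` when none).
#' @export
score_selection <- function(dm, truth, rule = list(type = "fdr", q = 0.05)) {
  stopifnot(inherits(dm, "dm_result"), inherits(truth, "methyl_truth"))
  if (length(dm$p_value) != length(truth$dm_mask)) {
    stop("result and truth cover different numbers of CpGs", call. = FALSE)
  }
  if (!is.null(dm$feature_ids) && !all(startsWith(dm$feature_ids, "feature_")) &&
      !identical(dm$feature_ids, truth$cpg_ids)) {
    stop("result and truth CpG ids are misaligned", call. = FALSE)
  }
  sel <- dm_select(dm, rule)
  is_dm <- truth$dm_mask
  n_dm <- sum(is_dm)
  n_null <- sum(!is_dm)
  err <- dm$effect_hat[is_dm] - truth$dm_delta[is_dm]
  list(n_selected = sum(sel),
       n_false_discoveries = sum(sel & !is_dm),
       tpr = if (n_dm > 0L) sum(sel & is_dm) / n_dm else NaN,
       fpr = if (n_null > 0L) sum(sel & !is_dm) / n_null else NaN,
       bias = if (n_dm > 0L) mean(err) else NaN,
       mse = if (n_dm > 0L) mean(err^2) else NaN)
}

#' Monte Carlo comparison of normalization strategies
#'
#' For each scenario (a combination of DM proportion and technical
#' variation) and replicate: simulate a two-group methylation array set,
#' then call differential methylation after (i) always applying quantile
#' normalization and (ii) test-guided normalization
#' ([guided_normalize()]: quantile normalization only when the global
#' distribution test does not reject). Both branches share the simulated
#' data and the identical quantile-normalized matrix, so whenever the
#' guided test accepts, branch outputs are bit-identical.
#'
#' @param pi_dm Vector of DM proportions to sweep.
#' @param tech_var Vector of technical-variation levels
#'   (`sample_scale_sd` values) to sweep.
#' @param n_reps Replicates per scenario (0 gives an empty table).
#' @param n_cpgs CpGs per replicate.
#' @param n_per_group Samples per group (default 5).
#' @param alpha Significance level of the guided test (default 0.05).
#' @param b Permutations for the guided test (default 100).
#' @param rule Selection rule for scoring, see [dm_select()].
#' @param delta_range,noise_sd,bio_sd Simulator settings passed through.
#' @param roc_points Optional integer vector of top-M cutoffs; when given,
#'   a `"roc"` attribute holds the TPR/FPR sweep per replicate and method.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return Long-format data.frame, one row per (scenario, replicate,
#'   method in {"qn", "guided"}): metrics from [score_selection()] plus
#'   the guided test's `perm_p` and the normalization actually applied.
#'   Summarize with [summarize_study()].
#' @export
run_study <- function(pi_dm = c(0.01, 0.10), tech_var = 0.05,
                      n_reps = 20L, n_cpgs = 20000L, n_per_group = 5L,
                      alpha = 0.05, b = 100L,
                      rule = list(type = "fdr", q = 0.05),
                      delta_range = c(0.2, 0.4), noise_sd = 0.1,
                      bio_sd = 0.01, roc_points = NULL, seed = 1L) {
  grid <- expand.grid(pi_dm = pi_dm, tech_var = tech_var,
                      rep = seq_len(n_reps))
  rows <- list()
  roc_rows <- list()
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, max(nrow(grid), 1L))
  for (i in seq_len(nrow(grid))) {
    sc <- grid[i, ]
    truth <- simulate_truth(n_cpgs, sc$pi_dm, delta_range = delta_range,
                            seed = seeds[i])
    params <- langmuir_params(noise_sd = noise_sd,
                              sample_scale_sd = sc$tech_var)
    arr <- simulate_arrays(truth, n_per_group = n_per_group,
                           params = params, bio_sd = bio_sd)
    fm <- feature_matrix(arr$beta_observed, arr$groups)
    qn <- quantile_normalize(fm)
    test <- qfa_test(fm, b = b, alpha = alpha, keep_perm_stats = FALSE)
    use_qn <- test$perm_p >= alpha
    dm_qn <- row_ttest(qn$values, arr$groups)
    dm_guided <- if (use_qn) dm_qn else row_ttest(fm)
    for (method in c("qn", "guided")) {
      dm <- if (method == "qn") dm_qn else dm_guided
      sc_metrics <- score_selection(dm, truth, rule)
      rows[[length(rows) + 1L]] <- data.frame(
        pi_dm = sc$pi_dm, tech_var = sc$tech_var, rep = sc$rep,
        method = method, perm_p = test$perm_p,
        applied = if (method == "qn" || use_qn) "quantile" else "none",
        n_selected = sc_metrics$n_selected,
        n_false_discoveries = sc_metrics$n_false_discoveries,
        tpr = sc_metrics$tpr, fpr = sc_metrics$fpr,
        bias = sc_metrics$bias, mse = sc_metrics$mse,
        seed = seeds[i], stringsAsFactors = FALSE)
      if (!is.null(roc_points)) {
        sweep_m <- lapply(roc_points, function(m) {
          s <- score_selection(dm, truth, list(type = "top", m = m))
          data.frame(pi_dm = sc$pi_dm, tech_var = sc$tech_var,
                     rep = sc$rep, method = method, m = m,
                     tpr = s$tpr, fpr = s$fpr)
        })
        roc_rows[[length(roc_rows) + 1L]] <- do.call(rbind, sweep_m)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pi_dm = numeric(0), tech_var = numeric(0), rep = integer(0),
               method = character(0), perm_p = numeric(0),
               applied = character(0), n_selected = integer(0),
               n_false_discoveries = integer(0), tpr = numeric(0),
               fpr = numeric(0), bias = numeric(0), mse = numeric(0),
               seed = integer(0))
  if (!is.null(roc_points)) {
    attr(out, "roc") <- if (length(roc_rows)) do.call(rbind, roc_rows) else NULL
  }
  out
}

#' Scenario-level summary of a normalization study
#'
#' Means per (scenario, method), plus guided-to-quantile-normalization
#' ratios of the false-discovery count, |bias| and MSE (relative
#' performance; values below 1 favor the guided strategy).
#'
#' @param study A [run_study()] table.
#' @return Wide data.frame, one row per scenario.
#' @export
summarize_study <- function(study) {
  if (!nrow(study)) return(study)
  key <- interaction(study$pi_dm, study$tech_var, drop = TRUE)
  out <- lapply(split(study, key), function(d) {
    qn <- d[d$method == "qn", ]
    gd <- d[d$method == "guided", ]
    data.frame(
      pi_dm = d$pi_dm[1L], tech_var = d$tech_var[1L],
      n_reps = nrow(qn),
      reject_rate = mean(qn$perm_p < 0.05),
      fd_qn = mean(qn$n_false_discoveries),
      fd_guided = mean(gd$n_false_discoveries),
      tpr_qn = mean(qn$tpr), tpr_guided = mean(gd$tpr),
      bias_qn = mean(qn$bias), bias_guided = mean(gd$bias),
      mse_qn = mean(qn$mse), mse_guided = mean(gd$mse),
      fd_ratio = mean(gd$n_false_discoveries) /
        max(mean(qn$n_false_discoveries), .Machine$double.eps),
      bias_ratio = mean(abs(gd$bias)) /
        max(mean(abs(qn$bias)), .Machine$double.eps),
      mse_ratio = mean(gd$mse) / max(mean(qn$mse), .Machine$double.eps))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
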