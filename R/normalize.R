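#' Quantile normalization
#'
#' Forces every sample column onto a common reference distribution, the
#' rank-wise mean of the per-column sorted values: (1) sort each column,
#' (2) average across columns at each rank to form the reference, (3)
#' replace each raw value by the reference value at its within-column
#' rank, (4) restore the original row order.
#'
#' Tie handling: with `tie_mode = "stable"` (default) tied raw values are
#' ranked by original row order (stable sort), so each still maps to a
#' single reference entry and every output column is exactly the reference
#' multiset. With `tie_mode = "average"` tied values all receive the mean
#' of the reference values spanning their tied ranks (the convention of
#' most microarray implementations).
#'
#' @param x A [feature_matrix()] or numeric matrix (>= 2 columns).
#' @param tie_mode `"stable"` or `"average"`.
#' @return Object of class `"normalized_matrix"`: list with `values`,
#'   `method = "quantile"`, and `reference` (the rank-wise mean vector).
#' @examples
#' qn <- quantile_normalize(cbind(a = c(2, 5, 3), b = c(4, 1, 9)))
#' qn$reference  # 1.5 3.5 7
#' @export
quantile_normalize <- function(x, tie_mode = c("stable", "average")) {
  tie_mode <- match.arg(tie_mode)
  vals <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (ncol(vals) < 2L) {
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  }
  if (any(!is.finite(vals))) stop("non-finite values", call. = FALSE)
  n <- nrow(vals)
  sorted <- apply(vals, 2L, sort, method = "radix")
  reference <- rowMeans(sorted)
  out <- vals
  for (j in seq_len(ncol(vals))) {
    ord <- order(vals[, j], method = "radix")  # stable: row order breaks ties
    if (tie_mode == "stable") {
      out[ord, j] <- reference
    } else {
      sv <- vals[ord, j]
      run <- cumsum(c(TRUE, diff(sv) != 0))  # runs of tied values
      out[ord, j] <- stats::ave(reference, run)
    }
  }
  .normalized(out, x, method = "quantile", reference = reference)
}

#' Median normalization
#'
#' Shifts each sample column so its median equals the mean of the original
#' per-column medians, keeping the data on its original scale.
#'
#' @param x A [feature_matrix()] or numeric matrix.
#' @return A `"normalized_matrix"` with `method = "median"` and `target`
#'   (the common median).
#' @export
median_normalize <- function(x) {
  vals <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  meds <- apply(vals, 2L, stats::median)
  target <- mean(meds)
  out <- sweep(vals, 2L, meds - target, "-")
  r <- .normalized(out, x, method = "median")
  r$target <- target
  r
}

#' Spike-in control scaling
#'
#' Normalizes on the log2 scale against spike-in control features: each
#' column has the mean log2 value of its spike-in rows subtracted
#' (equivalently, raw values are divided by a per-sample geometric-mean
#' spike-in factor). Output is on the log2 scale.
#'
#' @param x A [feature_matrix()] or numeric matrix of strictly positive
#'   raw values.
#' @param spike_in_rows Row indices or feature ids of the spike-in
#'   controls; non-empty.
#' @return A `"normalized_matrix"` with `method = "spike_in"` and
#'   `scale_factors` (per-sample log2 means over the spike-ins).
#' @export
spike_in_normalize <- function(x, spike_in_rows) {
  vals <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (is.character(spike_in_rows)) {
    idx <- match(spike_in_rows, rownames(vals))
    if (anyNA(idx)) {
      stop("unknown spike-in feature id(s): ",
           paste(spike_in_rows[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    spike_in_rows <- idx
  }
  if (!length(spike_in_rows)) stop("no spike-in rows given", call. = FALSE)
  if (any(vals <= 0)) {
    stop("spike-in scaling requires strictly positive raw values", call. = FALSE)
  }
  lv <- log2(vals)
  sf <- colMeans(lv[spike_in_rows, , drop = FALSE])
  out <- sweep(lv, 2L, sf, "-")
  r <- .normalized(out, x, method = "spike_in")
  r$scale_factors <- sf
  r
}

#' Test-guided normalization
#'
#' Runs the permutation test for global distribution differences
#' ([qfa_test()]) and applies quantile normalization only when the test
#' does not reject: `perm_p >= alpha` selects quantile normalization,
#' `perm_p < alpha` passes the data through unchanged (method `"none"`),
#' on the grounds that the observed global differences may be biological
#' and would be erased by a global adjustment.
#'
#' @param x A [feature_matrix()], or matrix plus `groups`.
#' @param groups Group labels when `x` is a plain matrix.
#' @param b,seed,alpha Passed to [qfa_test()].
#' @param tie_mode Passed to [quantile_normalize()] when chosen.
#' @return List with `normalized` (a `"normalized_matrix"`, method
#'   `"quantile"` or `"none"`) and `test` (the `"qfa_result"`).
#' @export
guided_normalize <- function(x, groups = NULL, b = 1000L, seed = NULL,
                             alpha = 0.05, tie_mode = "stable") {
  x <- .as_feature_matrix(x, groups)
  test <- qfa_test(x, b = b, seed = seed, alpha = alpha,
                   keep_perm_stats = FALSE)
  normalized <- if (test$perm_p >= alpha) {
    quantile_normalize(x, tie_mode = tie_mode)
  } else {
    .normalized(x$values, x, method = "none")
  }
  list(normalized = normalized, test = test)
}

.normalized <- function(values, input, method, reference = NULL) {
  if (inherits(input, "feature_matrix")) {
    dimnames(values) <- dimnames(input$values)
  }
  structure(list(values = values, method = method, reference = reference,
                 groups = if (inherits(input, "feature_matrix")) input$groups),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d x %d, method = %s\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}
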