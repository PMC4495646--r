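#' Grouped feature matrix
#'
#' Container for a features x samples numeric matrix together with a group
#' factor over the sample columns. This is the common input to the
#' distribution test ([qfa_test()]) and to all normalizers.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   A data.frame of numeric columns is accepted and coerced.
#' @param groups Group label per sample column: a factor, character or
#'   integer vector of length `ncol(values)`. At least two distinct levels
#'   are required by the test itself but not by the container (single-group
#'   matrices can still be normalized).
#' @param feature_ids,sample_ids Optional identifiers; default to the
#'   dimnames of `values` or generated ids.
#' @param drop_na If `TRUE`, rows containing non-finite values are dropped
#'   with a message; if `FALSE` (default) non-finite values are an error
#'   naming the offending sample and feature.
#'
#' @return An object of class `"feature_matrix"`: a list with elements
#'   `values` (matrix with dimnames), `groups` (factor) and the derived
#'   counts `n_features`, `n_samples`, `k` (number of groups).
#' @examples
#' x <- feature_matrix(matrix(rnorm(40), 10, 4), groups = c("a", "a", "b", "b"))
#' x$k
#' @export
feature_matrix <- function(values, groups, feature_ids = NULL,
                           sample_ids = NULL, drop_na = FALSE) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(feature_ids)) {
    feature_ids <- rownames(values)
    if (is.null(feature_ids)) {
      feature_ids <- sprintf("feature_%d", seq_len(nrow(values)))
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(values)
    if (is.null(sample_ids)) {
      sample_ids <- sprintf("sample_%d", seq_len(ncol(values)))
    }
  }
  if (length(feature_ids) != nrow(values)) {
    stop("'feature_ids' must have one entry per row", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("'sample_ids' must have one entry per column", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(groups) != ncol(values)) {
    stop("'groups' must have one label per sample column", call. = FALSE)
  }
  groups <- factor(groups)
  if (anyNA(groups)) stop("'groups' must not contain NA", call. = FALSE)

  bad <- !is.finite(values)
  if (any(bad)) {
    if (drop_na) {
      drop <- unique(which(bad, arr.ind = TRUE)[, 1L])
      message(length(drop), " row(s) with non-finite values dropped")
      values <- values[-drop, , drop = FALSE]
      feature_ids <- feature_ids[-drop]
    } else {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "non-finite value at feature '%s', sample '%s' (use drop_na = TRUE to drop such rows)",
        feature_ids[idx[1L]], sample_ids[idx[2L]]), call. = FALSE)
    }
  }
  if (nrow(values) < 2L) {
    stop("at least 2 features are required", call. = FALSE)
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(
    list(values = values, groups = groups,
         n_features = nrow(values), n_samples = ncol(values),
         k = nlevels(groups)),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d samples, %d group(s)\n",
              x$n_features, x$n_samples, x$k))
  cat("group sizes:",
      paste(sprintf("%s=%d", levels(x$groups), tabulate(x$groups)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# group sizes, in level order
.group_sizes <- function(groups) tabulate(groups, nbins = nlevels(groups))

# validate the design needed for the F statistic / permutation test
.check_test_design <- function(x, permutation = FALSE) {
  if (x$k < 2L) stop("at least 2 groups are required (K >= 2)", call. = FALSE)
  if (x$n_samples <= x$k) {
    stop("need more samples than groups (n_T > K) for within-group degrees of freedom",
         call. = FALSE)
  }
  if (permutation && sum(.group_sizes(x$groups) >= 2L) < 2L) {
    stop("permutation test requires at least two groups with >= 2 samples",
         call. = FALSE)
  }
  invisible(x)
}

.as_feature_matrix <- function(x, groups = NULL) {
  if (inherits(x, "feature_matrix")) return(x)
  if (is.null(groups)) stop("'groups' required when 'x' is a plain matrix",
                            call. = FALSE)
  feature_matrix(x, groups)
}
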