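#' Read a feature matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of feature ids;
#' all remaining cells numeric. The delimiter is taken from the file
#' extension (`.csv` comma, otherwise tab) unless `sep` is given.
#'
#' @param path File path.
#' @param groups Optional group labels: either a path to a two-column
#'   (sample_id, group) TSV, or a vector/comma-separated string aligned to
#'   the sample columns. See [read_groups()].
#' @param sep Field separator override.
#' @param drop_na Passed to [feature_matrix()].
#' @return A [feature_matrix()] (with a single placeholder group when
#'   `groups` is `NULL`).
#' @export
read_feature_matrix <- function(path, groups = NULL, sep = NULL,
                                drop_na = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("expected a feature-id column plus >= 1 sample column",
                          call. = FALSE)
  feature_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- is.na(vals) & !toupper(as.matrix(df[-1L])) %in% c("NA", "NAN")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at line %d, column '%s' of %s",
                 df[-1L][idx[1L], idx[2L]], idx[1L] + 1L,
                 sample_ids[idx[2L]], path), call. = FALSE)
  }
  if (is.null(groups)) {
    grp <- rep("all", length(sample_ids))
  } else if (length(groups) == 1L && is.character(groups) &&
             file.exists(groups)) {
    grp <- read_groups(groups, sample_ids)
  } else {
    grp <- read_groups(groups, sample_ids)
  }
  feature_matrix(vals, grp, feature_ids = feature_ids,
                 sample_ids = sample_ids, drop_na = drop_na)
}

#' Write a feature matrix as TSV/CSV
#'
#' Inverse of [read_feature_matrix()]: header row of sample ids, first
#' column of feature ids.
#'
#' @param x A [feature_matrix()] or plain numeric matrix with dimnames.
#' @param path Output path; `.csv` extension selects comma separation.
#' @param digits Significant digits for the values (default 10).
#' @export
write_feature_matrix <- function(x, path, digits = 10L) {
  vals <- if (inherits(x, "feature_matrix")) x$values else x
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(feature_id = rownames(vals),
                   signif(vals, digits), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve group labels for a set of samples
#'
#' Accepts a two-column (sample_id, group) TSV path, a comma-separated
#' string, or a vector. Every sample must be assigned exactly once.
#'
#' @param groups Path, string or vector of labels.
#' @param sample_ids Sample ids the labels must cover (in column order).
#' @return A factor aligned to `sample_ids`.
#' @export
read_groups <- function(groups, sample_ids) {
  if (length(groups) == 1L && is.character(groups) && file.exists(groups)) {
    df <- utils::read.table(groups, header = FALSE, sep = "\t",
                            col.names = c("sample_id", "group"),
                            colClasses = "character")
    if (any(!sample_ids %in% df$sample_id)) {
      stop("group file missing sample(s): ",
           paste(setdiff(sample_ids, df$sample_id), collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(df$sample_id)) {
      stop("group file assigns sample(s) more than once: ",
           paste(unique(df$sample_id[duplicated(df$sample_id)]),
                 collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(df$sample_id, sample_ids)
    if (length(extra)) {
      stop("group file names unknown sample(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    grp <- df$group[match(sample_ids, df$sample_id)]
  } else {
    if (length(groups) == 1L && is.character(groups) && grepl(",", groups)) {
      groups <- strsplit(groups, ",")[[1L]]
    }
    if (length(groups) != length(sample_ids)) {
      stop(sprintf("%d group label(s) given for %d sample(s)",
                   length(groups), length(sample_ids)), call. = FALSE)
    }
    grp <- groups
  }
  factor(trimws(as.character(grp)))
}
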