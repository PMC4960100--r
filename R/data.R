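#' Labeled dataset container
#'
#' The common currency of all fitting stages: a numeric feature matrix with
#' class labels in \{-1, +1\}. Labels coded \{0, 1\} are remapped (0 to -1)
#' with a message.
#'
#' @param features numeric matrix, samples in rows, features in columns.
#' @param labels vector of class labels in \{-1, 1\} (or \{0, 1\}).
#' @param sample_ids optional character vector of row identifiers.
#' @param feature_ids optional character vector of column identifiers.
#' @return an object of class `labeled_dataset` with elements `features`,
#'   `labels`, `sample_ids`, `feature_ids`.
#' @export
labeled_dataset <- function(features, labels, sample_ids = NULL,
                            feature_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.numeric(labels)
  if (nrow(features) != length(labels)) {
    stop("number of rows of 'features' (", nrow(features),
         ") must equal length of 'labels' (", length(labels), ")")
  }
  if (anyNA(features) || anyNA(labels)) {
    stop("labeled_dataset does not accept missing values")
  }
  if (all(labels %in% c(0, 1)) && any(labels == 0)) {
    message("labels coded {0,1}: remapping 0 -> -1")
    labels[labels == 0] <- -1
  }
  if (!all(labels %in% c(-1, 1))) {
    stop("labels must take values in {-1, +1}")
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(features))) rownames(features) else
      paste0("s", seq_len(nrow(features)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- if (!is.null(colnames(features))) colnames(features) else
      paste0("f", seq_len(ncol(features)))
  }
  dimnames(features) <- NULL
  structure(
    list(features = features, labels = labels,
         sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids)),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", nrow(x$features), "samples x",
      ncol(x$features), "features\n")
  cat("  labels: ", sum(x$labels == -1), " x -1, ",
      sum(x$labels == 1), " x +1\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$features)

# subset rows (and optionally columns) keeping ids in sync
subset_dataset <- function(data, rows = NULL, cols = NULL) {
  f <- data$features
  sid <- data$sample_ids
  lab <- data$labels
  if (!is.null(rows)) {
    f <- f[rows, , drop = FALSE]
    sid <- sid[rows]
    lab <- lab[rows]
  }
  fid <- data$feature_ids
  if (!is.null(cols)) {
    f <- f[, cols, drop = FALSE]
    fid <- fid[cols]
  }
  labeled_dataset(f, lab, sid, fid)
}

check_two_classes <- function(labels, what = "fitting") {
  if (length(unique(labels)) < 2) {
    stop("both classes (-1 and +1) must be present for ", what)
  }
  invisible(TRUE)
}
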