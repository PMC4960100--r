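#' Cross-validation configuration
#'
#' @param n_folds number of folds (>= 2), default 5.
#' @param C_grid candidate regularization constants; default the dyadic
#'   grid `2^(-5), ..., 2^5` (11 values).
#' @param seed optional integer seed for the fold assignment.
#' @param stratified stratify folds by class label (default `TRUE`).
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 5, C_grid = 2^(-5:5), seed = NULL,
                      stratified = TRUE) {
  if (n_folds < 2) stop("'n_folds' must be at least 2")
  if (any(C_grid <= 0)) stop("'C_grid' must be positive")
  structure(list(n_folds = as.integer(n_folds),
                 C_grid = sort(as.numeric(C_grid)),
                 seed = seed, stratified = isTRUE(stratified)),
            class = "cv_config")
}

#' Fold assignment for k-fold cross-validation
#'
#' Stratified assignment shuffles within each class and deals samples
#' round-robin with a running offset, so overall fold sizes differ by at
#' most one and each fold preserves the class ratio within one sample.
#'
#' @param labels vector of class labels.
#' @param n_folds number of folds.
#' @param stratified stratify by label.
#' @return integer vector of fold ids in `1..n_folds`.
#' @export
make_folds <- function(labels, n_folds, stratified = TRUE) {
  N <- length(labels)
  if (n_folds > N) stop("more folds than samples")
  fold <- integer(N)
  if (stratified) {
    offset <- 0L
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  } else {
    fold[sample.int(N)] <- ((seq_len(N) - 1L) %% n_folds) + 1L
  }
  for (f in seq_len(n_folds)) {
    tr <- labels[fold != f]
    if (length(unique(tr)) < 2) {
      stop("fold ", f, " leaves a single-class training set",
           if (!stratified) "; consider stratified folds" else "")
    }
  }
  fold
}

# decision signs at query points given the cross-Gram against the training
# units; avoids recomputing kernels inside the C-grid loop
predict_with_gram <- function(obj, Kc) {
  if (inherits(obj, "wsvm_model")) {
    f <- drop(Kc[, obj$sv_index, drop = FALSE] %*% obj$coefs) + obj$bias
    return(ifelse(f >= 0, 1, -1))
  }
  votes <- t(vapply(obj$weak_models, function(m) {
    f <- drop(Kc[, m$sv_index, drop = FALSE] %*% m$coefs) + m$bias
    ifelse(f >= 0, 1, -1)
  }, numeric(nrow(Kc))))
  score <- drop(obj$vote_weights %*% votes)
  ifelse(score >= 0, 1, -1)
}

#' Select the regularization constant C by k-fold cross-validation
#'
#' Fits the requested method on each set of k-1 folds and scores
#' misclassification on the held-out fold, for every C on the grid. For the
#' K-means-reduced methods the clustering is refit inside each training
#' fold (held-out samples never influence the centers) with
#' `K = floor(n_fold_train / 2)` unless `K` is given; since the clustering
#' does not depend on C it is shared across the grid within a fold. Ties in
#' mean error go to the smallest C (strongest regularization on this
#' parameterization of the dyadic grid).
#'
#' @param data a [labeled_dataset()].
#' @param kernel a [kernel_spec()].
#' @param config a [cv_config()].
#' @param method one of `"svm"`, `"km_svm"`, `"wsvm"`, `"wkm_svm"`.
#' @param K number of centers for the reduced methods (`NULL`: half the
#'   fold-training size).
#' @param boost a [boost_config()] for the weighted (boosted) methods.
#' @param variant K-means reduction variant, `"global"` or `"by_class"`.
#' @param nstart k-means++ restarts.
#' @return list with `C_best` and `cv_table` (data frame of `C`,
#'   `mean_error`, `se_error`).
#' @export
cv_select_C <- function(data, kernel = kernel_spec(), config = cv_config(),
                        method = c("svm", "km_svm", "wsvm", "wkm_svm"),
                        K = NULL, boost = boost_config(),
                        variant = c("global", "by_class"), nstart = 10) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  stopifnot(inherits(data, "labeled_dataset"), inherits(config, "cv_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  grid <- config$C_grid
  folds <- make_folds(data$labels, config$n_folds, config$stratified)
  reduced <- method %in% c("km_svm", "wkm_svm")
  boosted <- method %in% c("wsvm", "wkm_svm")
  errs <- matrix(NA_real_, config$n_folds, length(grid))
  for (f in seq_len(config$n_folds)) {
    tr <- subset_dataset(data, folds != f)
    Xte <- data$features[folds == f, , drop = FALSE]
    yte <- data$labels[folds == f]
    units <- if (reduced) {
      Kf <- if (is.null(K)) default_K(nrow(tr$features)) else
        min(K, nrow(tr$features))
      red <- if (variant == "global") reduce_global(tr, Kf, nstart = nstart)
             else reduce_by_class(tr, Kf, nstart = nstart)
      as_labeled_dataset(red)
    } else tr
    G <- gram_matrix(units$features, units$features, kernel)
    Kc <- gram_matrix(Xte, units$features, kernel)
    for (ci in seq_along(grid)) {
      fitted <- if (boosted) {
        boost_fit(units, C = grid[ci], kernel = kernel, config = boost,
                  gram = G)
      } else {
        solve_weighted_svm(units, C = grid[ci], kernel = kernel, gram = G)
      }
      errs[f, ci] <- mean(predict_with_gram(fitted, Kc) != yte)
    }
  }
  mean_error <- colMeans(errs)
  se_error <- apply(errs, 2, sd) / sqrt(config$n_folds)
  list(C_best = grid[which.min(mean_error)],
       cv_table = data.frame(C = grid, mean_error = mean_error,
                             se_error = se_error))
}
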