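# squared Euclidean distances between rows of X and rows of C
dist2 <- function(X, C) {
  D <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  D[D < 0] <- 0
  D
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center; degenerate (all-zero) distances
# fall back to a uniform draw among the remaining points
kmeanspp_init <- function(X, K) {
  N <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(N, 1)
  if (K > 1) {
    d2 <- dist2(X, X[centers[1], , drop = FALSE])[, 1]
    for (k in 2:K) {
      d2[centers[seq_len(k - 1)]] <- 0
      centers[k] <- if (sum(d2) > 0) sample.int(N, 1, prob = d2) else {
        cand <- setdiff(seq_len(N), centers[seq_len(k - 1)])
        cand[sample.int(length(cand), 1)]
      }
      d2 <- pmin(d2, dist2(X, X[centers[k], , drop = FALSE])[, 1])
    }
  }
  X[centers, , drop = FALSE]
}

# Lloyd's algorithm from given initial centers; empty clusters are re-seeded
# to the point currently farthest from its assigned center. Returns the
# per-iteration WCSS trace (non-increasing by construction of the two
# alternating minimization steps).
lloyd_kmeans <- function(X, centers, max_iter = 100) {
  N <- nrow(X)
  K <- nrow(centers)
  assign_prev <- rep(0L, N)
  wcss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- dist2(X, centers)
    assign <- max.col(-D, ties.method = "first")
    empty <- which(tabulate(assign, K) == 0L)
    if (length(empty)) {
      pd <- D[cbind(seq_len(N), assign)]
      for (k in empty) {
        far <- which.max(pd)
        assign[far] <- k
        pd[far] <- 0
      }
    }
    for (k in seq_len(K)) {
      centers[k, ] <- colMeans(X[assign == k, , drop = FALSE])
    }
    wcss <- sum((X - centers[assign, , drop = FALSE])^2)
    wcss_trace <- c(wcss_trace, wcss)
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }
  list(centers = centers, cluster = assign, wcss = wcss,
       wcss_trace = wcss_trace, iterations = length(wcss_trace))
}

# k-means++ / Lloyd with restarts, best WCSS kept
kmeans_fit <- function(X, K, nstart = 10, max_iter = 100) {
  best <- NULL
  for (s in seq_len(nstart)) {
    fit <- lloyd_kmeans(X, kmeanspp_init(X, K), max_iter)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  best
}

#' Default number of clusters: half the training size
#'
#' @param n_train training sample count (>= 2).
#' @return `floor(n_train / 2)`.
#' @export
default_K <- function(n_train) {
  if (n_train < 2) stop("'n_train' must be at least 2")
  as.integer(floor(n_train / 2))
}

new_reduced_dataset <- function(centers, center_labels, member_counts,
                                variant, source_n, seed) {
  structure(
    list(centers = centers, center_labels = center_labels,
         member_counts = as.integer(member_counts), variant = variant,
         source_n = as.integer(source_n),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "reduced_dataset")
}

#' @export
print.reduced_dataset <- function(x, ...) {
  cat("reduced_dataset (", x$variant, "): ", nrow(x$centers),
      " centers from ", x$source_n, " samples\n", sep = "")
  invisible(x)
}

#' @describeIn reduce_global view the reduction as a [labeled_dataset()] of
#'   centers, ready for SVM fitting.
#' @param reduced a `reduced_dataset`.
#' @export
as_labeled_dataset <- function(reduced) {
  stopifnot(inherits(reduced, "reduced_dataset"))
  labeled_dataset(reduced$centers, reduced$center_labels,
                  sample_ids = paste0("center_", seq_len(nrow(reduced$centers))))
}

#' K-means prototype reduction
#'
#' Replaces the training samples by `K` cluster centers before SVM fitting.
#' `reduce_global` clusters all samples jointly and assigns each center the
#' majority label of its members (ties: label of the member nearest the
#' centroid, then -1); `reduce_by_class` clusters each class separately,
#' allocating `K_c = max(1, round(K * N_c / N))` centers per class (the
#' larger class absorbs any rounding difference) so that no cluster ever
#' mixes classes.
#'
#' Clustering is Lloyd's algorithm with k-means++ seeding, `nstart`
#' restarts, and the best within-cluster sum of squares kept; empty
#' clusters are re-seeded to the point farthest from its current center.
#'
#' @param data a [labeled_dataset()].
#' @param K number of centers, `1 <= K <= N` (see [default_K()]).
#' @param seed optional integer seed for the clustering restarts.
#' @param nstart number of k-means++ restarts.
#' @return a `reduced_dataset`: `centers`, voted/inherited `center_labels`,
#'   `member_counts`, `variant`, `source_n`, `seed`.
#' @export
reduce_global <- function(data, K, seed = NULL, nstart = 10) {
  stopifnot(inherits(data, "labeled_dataset"))
  N <- nrow(data$features)
  check_two_classes(data$labels, "reduction")
  if (K < 1) stop("'K' must be at least 1")
  if (K > N) stop("'K' (", K, ") cannot exceed the number of samples (", N, ")")
  if (!is.null(seed)) set.seed(as.integer(seed))
  fit <- kmeans_fit(data$features, K, nstart)
  labs <- numeric(K)
  counts <- integer(K)
  for (k in seq_len(K)) {
    idx <- which(fit$cluster == k)
    counts[k] <- length(idx)
    vote <- sum(data$labels[idx])
    if (vote != 0) {
      labs[k] <- sign(vote)
    } else {
      # even cluster with equal votes: label of the member nearest the
      # centroid; an exact distance tie across classes resolves to -1
      d <- dist2(data$features[idx, , drop = FALSE],
                 fit$centers[k, , drop = FALSE])[, 1]
      tied <- data$labels[idx[d == min(d)]]
      labs[k] <- if (length(unique(tied)) > 1) -1 else tied[1]
    }
  }
  out <- new_reduced_dataset(fit$centers, labs, counts, "global", N, seed)
  attr(out, "wcss_trace") <- fit$wcss_trace
  out
}

#' @rdname reduce_global
#' @export
reduce_by_class <- function(data, K, seed = NULL, nstart = 10) {
  stopifnot(inherits(data, "labeled_dataset"))
  N <- nrow(data$features)
  check_two_classes(data$labels, "reduction")
  if (K < 2) stop("'K' must be at least 2 for by-class reduction")
  if (K > N) stop("'K' (", K, ") cannot exceed the number of samples (", N, ")")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_neg <- sum(data$labels == -1)
  n_pos <- N - n_neg
  k_neg <- max(1L, as.integer(round(K * n_neg / N)))
  k_pos <- K - k_neg
  if (k_pos < 1) { k_pos <- 1L; k_neg <- K - 1L }
  # a class cannot host more centers than samples
  if (k_neg > n_neg) {
    message("by-class K for class -1 lowered from ", k_neg, " to ", n_neg)
    k_neg <- n_neg; k_pos <- min(K - k_neg, n_pos)
  }
  if (k_pos > n_pos) {
    message("by-class K for class +1 lowered from ", k_pos, " to ", n_pos)
    k_pos <- n_pos; k_neg <- min(K - k_pos, n_neg)
  }
  centers <- NULL; labs <- NULL; counts <- NULL; traces <- list()
  for (cls in c(-1, 1)) {
    idx <- which(data$labels == cls)
    kc <- if (cls == -1) k_neg else k_pos
    fit <- kmeans_fit(data$features[idx, , drop = FALSE], kc, nstart)
    centers <- rbind(centers, fit$centers)
    labs <- c(labs, rep(cls, kc))
    counts <- c(counts, tabulate(fit$cluster, kc))
    traces[[as.character(cls)]] <- fit$wcss_trace
  }
  out <- new_reduced_dataset(centers, labs, counts, "by_class", N, seed)
  attr(out, "wcss_trace") <- traces
  out
}
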