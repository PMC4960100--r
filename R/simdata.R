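#' Two-class bivariate-Gaussian benchmark data
#'
#' Draws a training and a test set from the classical two-Gaussian design:
#' the first half of each set carries label -1 and is drawn from
#' N((0,...,0), I), the second half carries label +1 and is drawn from
#' N((r,...,r), I). Samples are emitted in class-block order (all -1 first)
#' unless `shuffle = TRUE`.
#'
#' With equal spherical covariances the Bayes rule is the midpoint
#' hyperplane and the Bayes error is `pnorm(-r * sqrt(dim) / 2)`; for the
#' planar case `dim = 2` this is `pnorm(-r / sqrt(2))`.
#'
#' @param n_train,n_test even sample sizes (classes split exactly in half).
#' @param r nonnegative shared coordinate of the +1 class mean.
#' @param dim number of features (2 for the standard planar design).
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible and bitwise identical across calls.
#' @param shuffle randomly permute rows within each set (default `FALSE`,
#'   preserving the class-block layout).
#' @return list with elements `train` and `test`, both [labeled_dataset()]s.
#' @export
simulate_gaussian <- function(n_train = 100, n_test = 1000, r = 2, dim = 2,
                              seed = NULL, shuffle = FALSE) {
  for (n in c(n_train, n_test)) {
    if (n < 2 || n %% 2 != 0) {
      stop("sample sizes must be even: classes are split exactly in half ",
           "(got ", n, ")")
    }
  }
  if (!is.numeric(r) || length(r) != 1 || r < 0) stop("'r' must be >= 0")
  if (dim < 1) stop("'dim' must be a positive integer")
  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- function(n, prefix) {
    half <- n / 2
    X <- matrix(rnorm(n * dim), n, dim)
    X[(half + 1):n, ] <- X[(half + 1):n, ] + r
    y <- rep(c(-1, 1), each = half)
    if (shuffle) {
      p <- sample.int(n)
      X <- X[p, , drop = FALSE]
      y <- y[p]
    }
    labeled_dataset(X, y, sample_ids = paste0(prefix, seq_len(n)),
                    feature_ids = paste0("x", seq_len(dim)))
  }
  list(train = draw(n_train, "train_"), test = draw(n_test, "test_"))
}

#' Synthetic methylation-like feature matrix
#'
#' Generates a probes-in-columns matrix of beta-like values in \[0, 1\]:
#' per-probe baseline means and standard deviations are drawn uniformly
#' from `base_mean_range` and `base_sd_range`, values are Gaussian around
#' the baseline and clipped to \[0, 1\]. A random subset of exactly
#' `round(frac_informative * n_probes)` probes carries a class-mean shift
#' of magnitude `effect_size` (random sign per probe, applied to the +1
#' class before clipping). This is a moment-controlled stand-in for real
#' bisulfite-array data, not a biological model: clipping a Gaussian is
#' simpler and more controllable than a Beta model, at the cost of mass at
#' the boundaries for extreme baselines.
#'
#' The first `n_samples_per_class` rows carry label -1, the rest +1.
#'
#' @param n_samples_per_class samples per class.
#' @param n_probes number of probes (columns).
#' @param frac_informative fraction of probes carrying a class effect.
#' @param effect_size class mean shift on informative probes (beta scale,
#'   before clipping).
#' @param base_mean_range,base_sd_range ranges of the per-probe baseline
#'   mean and SD.
#' @param seed optional integer seed.
#' @return a [labeled_dataset()] with attribute `probe_info`: a data frame
#'   of `feature_id`, `base_mean`, `base_sd`, `informative`, `effect`.
#' @export
simulate_methylation <- function(n_samples_per_class = 100, n_probes = 1000,
                                 frac_informative = 0.05, effect_size = 0.15,
                                 base_mean_range = c(0.2, 0.8),
                                 base_sd_range = c(0.02, 0.2),
                                 seed = NULL) {
  if (frac_informative < 0 || frac_informative > 1) {
    stop("'frac_informative' must lie in [0, 1]")
  }
  if (effect_size < 0) stop("'effect_size' must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- 2L * n_samples_per_class
  mu <- runif(n_probes, base_mean_range[1], base_mean_range[2])
  sdv <- runif(n_probes, base_sd_range[1], base_sd_range[2])
  n_inf <- round(frac_informative * n_probes)
  informative <- rep(FALSE, n_probes)
  informative[sample.int(n_probes, n_inf)] <- TRUE
  effect <- numeric(n_probes)
  effect[informative] <- effect_size * sample(c(-1, 1), n_inf, replace = TRUE)
  y <- rep(c(-1, 1), each = n_samples_per_class)
  M <- matrix(rnorm(n * n_probes), n, n_probes)
  M <- sweep(M, 2, sdv, `*`)
  M <- sweep(M, 2, mu, `+`)
  # class effect on the +1 block
  pos <- y == 1
  M[pos, ] <- sweep(M[pos, , drop = FALSE], 2, effect, `+`)
  M[M < 0] <- 0
  M[M > 1] <- 1
  ld <- labeled_dataset(M, y,
                        sample_ids = paste0("sample_", seq_len(n)),
                        feature_ids = sprintf("probe_%04d", seq_len(n_probes)))
  attr(ld, "probe_info") <- data.frame(
    feature_id = ld$feature_ids, base_mean = mu, base_sd = sdv,
    informative = informative, effect = effect)
  ld
}
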