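#' Boosting configuration
#'
#' @param M maximum number of boosting rounds.
#' @param err_floor weighted errors are clamped below at this value before
#'   computing the vote weight `alpha_m = log((1 - err) / err)`, so a
#'   perfect weak learner gets a large finite vote.
#' @param err_ceiling rounds whose weighted error reaches this value (1/2
#'   by default) terminate the loop: such a learner is no better than
#'   chance and would get a nonpositive vote.
#' @param recluster_each_round for boosted KM-SVM: re-run the clustering
#'   before every round instead of once up front (default `FALSE`).
#' @return an object of class `boost_config`.
#' @export
boost_config <- function(M = 10, err_floor = 1e-6, err_ceiling = 0.5,
                         recluster_each_round = FALSE) {
  if (M < 1) stop("'M' must be at least 1")
  if (!(err_floor > 0 && err_floor < err_ceiling && err_ceiling <= 0.5)) {
    stop("need 0 < err_floor < err_ceiling <= 0.5")
  }
  structure(list(M = as.integer(M), err_floor = err_floor,
                 err_ceiling = err_ceiling,
                 recluster_each_round = isTRUE(recluster_each_round)),
            class = "boost_config")
}

#' One AdaBoost.M1 weight update
#'
#' Given current unit weights `c` and a logical misclassification indicator,
#' computes the weighted error `err = sum(c * miss) / sum(c)`, the vote
#' weight `alpha = log((1 - err) / err)` (after clamping `err` into
#' `[err_floor, 1/2)`), and the updated, renormalized weights
#' `c * exp(alpha * miss) / sum(...)`.
#'
#' @param c current nonnegative unit weights.
#' @param miss logical (or 0/1) vector: unit misclassified by the current
#'   weak learner.
#' @param err_floor clamp for degenerate (near-zero) errors.
#' @return list with `err` (unclamped), `alpha`, and `weights` (updated,
#'   summing to 1).
#' @export
adaboost_step <- function(c, miss, err_floor = 1e-6) {
  miss <- as.numeric(miss)
  err <- sum(c * miss) / sum(c)
  err_c <- min(max(err, err_floor), 0.5 - 1e-12)
  alpha <- log((1 - err_c) / err_c)
  w <- c * exp(alpha * miss)
  list(err = err, alpha = alpha, weights = w / sum(w))
}

#' Boosted weighted SVM (AdaBoost.M1 over samples or cluster centers)
#'
#' Implements the reweighting loop: initialize unit weights `c_n = 1/N`;
#' for each round fit a weighted SVM with the current weights, compute the
#' weighted training error `err_m`, the vote weight
#' `alpha_m = log((1 - err_m)/err_m)`, and inflate the weights of
#' misclassified units by `exp(alpha_m)` (followed by renormalization to
#' sum 1, which leaves the ratio-form `err_m` unchanged). The final
#' classifier is the weighted sign vote of the rounds' decision signs.
#'
#' The `units` may be raw training samples (boosted weighted SVM) or the
#' labeled centers of a K-means reduction via [as_labeled_dataset()]
#' (boosted weighted KM-SVM). Rounds stop early when `err_m` reaches
#' `err_ceiling` (a chance-level learner; the round is kept only if the
#' ensemble would otherwise be empty, with `err` clamped just below 1/2)
#' or drops to `err_floor` (a perfect learner; kept with a capped vote).
#'
#' @param units a [labeled_dataset()] of boosting units.
#' @param C positive regularization constant for the weak learners.
#' @param kernel a [kernel_spec()].
#' @param config a [boost_config()].
#' @param gram optional precomputed Gram matrix of `units$features` (the
#'   rounds all share it).
#' @return an object of class `boosted_ensemble`: `weak_models` (list of
#'   `wsvm_model`), `vote_weights` (`alpha_m`), `train_errors` (`err_m`),
#'   `units`, `final_weights` (terminal `c_n`).
#' @export
boost_fit <- function(units, C = 1, kernel = kernel_spec(),
                      config = boost_config(), gram = NULL) {
  stopifnot(inherits(units, "labeled_dataset"),
            inherits(config, "boost_config"))
  y <- units$labels
  N <- length(y)
  check_two_classes(y, "boosting")
  K <- if (is.null(gram)) gram_matrix(units$features, units$features, kernel)
       else gram
  cw <- rep(1 / N, N)
  models <- list()
  alphas <- numeric(0)
  errs <- numeric(0)
  for (m in seq_len(config$M)) {
    model <- solve_weighted_svm(units, cw, C, kernel, gram = K)
    f <- drop(K[, model$sv_index, drop = FALSE] %*% model$coefs) + model$bias
    miss <- ifelse(f >= 0, 1, -1) != y
    err <- sum(cw * miss) / sum(cw)
    if (err >= config$err_ceiling) {
      if (length(models) == 0) {
        # degenerate first round: keep the single learner with a vanishing
        # but positive vote so the ensemble is never empty
        step <- adaboost_step(cw, miss, config$err_floor)
        models[[1]] <- model
        alphas <- step$alpha
        errs <- err
      }
      break
    }
    step <- adaboost_step(cw, miss, config$err_floor)
    models[[length(models) + 1]] <- model
    alphas <- c(alphas, step$alpha)
    errs <- c(errs, err)
    cw <- step$weights
    if (err <= config$err_floor) break
  }
  structure(
    list(weak_models = models, vote_weights = alphas, train_errors = errs,
         units = units, final_weights = cw, C = C, kernel = kernel,
         config = config, shared_units = TRUE),
    class = "boosted_ensemble")
}

# experimental variant behind boost_config(recluster_each_round = TRUE):
# boosting weights live on the raw training samples; every round runs a
# fresh K-means reduction, each center inherits the summed weight of its
# members (plus a vanishing floor so both classes always carry weight),
# the weak weighted SVM is fit on the centers, and err_m / the weight
# update are computed on the samples
boost_fit_recluster <- function(train, K, C, kernel, config,
                                variant = "global", nstart = 10) {
  y <- train$labels
  N <- length(y)
  cw <- rep(1 / N, N)
  models <- list()
  alphas <- numeric(0)
  errs <- numeric(0)
  for (m in seq_len(config$M)) {
    red <- if (variant == "global") reduce_global(train, K, nstart = nstart)
           else reduce_by_class(train, K, nstart = nstart)
    units <- as_labeled_dataset(red)
    asg <- max.col(-dist2(train$features, red$centers),
                   ties.method = "first")
    cwk <- vapply(seq_len(nrow(red$centers)),
                  function(k) sum(cw[asg == k]), numeric(1))
    # rescale to sum K so the weak learners sit on the same effective-cost
    # scale as a plain KM-SVM at the same C
    cwk <- cwk * length(cwk) + 1e-9 / length(cwk)
    model <- solve_weighted_svm(units, cwk, C, kernel)
    miss <- predict(model, train$features) != y
    err <- sum(cw * miss) / sum(cw)
    if (err >= config$err_ceiling) {
      if (length(models) == 0) {
        step <- adaboost_step(cw, miss, config$err_floor)
        models[[1]] <- model
        alphas <- step$alpha
        errs <- err
      }
      break
    }
    step <- adaboost_step(cw, miss, config$err_floor)
    models[[length(models) + 1]] <- model
    alphas <- c(alphas, step$alpha)
    errs <- c(errs, err)
    cw <- step$weights
    if (err <= config$err_floor) break
  }
  structure(
    list(weak_models = models, vote_weights = alphas, train_errors = errs,
         units = train, final_weights = cw, C = C, kernel = kernel,
         config = config, shared_units = FALSE),
    class = "boosted_ensemble")
}

#' @export
print.boosted_ensemble <- function(x, ...) {
  cat("boosted_ensemble:", length(x$weak_models), "weak weighted-SVM",
      "learners over", length(x$units$labels), "units\n")
  cat("  vote weights:", paste(signif(x$vote_weights, 4), collapse = " "),
      "\n")
  invisible(x)
}

# decision signs of every weak model at X, as a length(models) x nrow(X)
# matrix; when all rounds share the same units, one cross-Gram computation
# serves every model
weak_votes <- function(ensemble, X) {
  if (isFALSE(ensemble$shared_units)) {
    return(t(vapply(ensemble$weak_models, function(m) {
      ifelse(decision_function(m, X) >= 0, 1, -1)
    }, numeric(nrow(X)))))
  }
  Kc <- gram_matrix(X, ensemble$units$features, ensemble$kernel)
  t(vapply(ensemble$weak_models, function(m) {
    f <- drop(Kc[, m$sv_index, drop = FALSE] %*% m$coefs) + m$bias
    ifelse(f >= 0, 1, -1)
  }, numeric(nrow(X))))
}

#' Predict with a boosted ensemble
#'
#' Weighted sign vote `sign(sum_m alpha_m G_m(x))`; a tied vote (exactly
#' zero) goes to class +1, matching the single-model convention.
#'
#' @param ensemble a fitted `boosted_ensemble`.
#' @param X numeric matrix of query points.
#' @return vector of predicted labels in \{-1, +1\}.
#' @export
boost_predict <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "boosted_ensemble"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(ensemble$units$features)) {
    stop("feature dimension mismatch: ensemble expects ",
         ncol(ensemble$units$features), " features, got ", ncol(X))
  }
  votes <- weak_votes(ensemble, X)
  score <- drop(ensemble$vote_weights %*% votes)
  ifelse(score >= 0, 1, -1)
}

#' @export
predict.boosted_ensemble <- function(object, newdata, ...) {
  boost_predict(object, newdata)
}

#' Test error of every partial ensemble
#'
#' Entry `m` is the misclassification rate on `test` of the ensemble built
#' from rounds `1..m`, tracing how boosting drives the test error down over
#' iterations.
#'
#' @param ensemble a fitted `boosted_ensemble`.
#' @param test a [labeled_dataset()].
#' @return numeric vector of length `length(ensemble$weak_models)`.
#' @export
boosting_trace <- function(ensemble, test) {
  stopifnot(inherits(ensemble, "boosted_ensemble"),
            inherits(test, "labeled_dataset"))
  votes <- weak_votes(ensemble, test$features)
  scores <- apply(ensemble$vote_weights * votes, 2, cumsum)
  if (length(ensemble$weak_models) == 1) scores <- matrix(scores, nrow = 1)
  pred <- ifelse(scores >= 0, 1, -1)
  apply(pred, 1, function(p) mean(p != test$labels))
}
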