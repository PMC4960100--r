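# deterministic child-seed scheme: rep i of master seed s runs under
# (s * 1009 + i) mod 2147483629 (computed in double, stays below 2^31)
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i)) %% 2147483629)
}

#' Fit one of the four classifier variants
#'
#' Dispatcher used by the tuning and experiment code: `"svm"` (plain
#' soft-margin SVM, all weights 1), `"km_svm"` (SVM on K-means centers),
#' `"wsvm"` (boosted weighted SVM over samples), `"wkm_svm"` (boosted
#' weighted SVM over K-means centers).
#'
#' @param train a [labeled_dataset()].
#' @param method one of `"svm"`, `"km_svm"`, `"wsvm"`, `"wkm_svm"`.
#' @param C regularization constant.
#' @param kernel a [kernel_spec()].
#' @param K number of centers for the reduced methods (`NULL`: half the
#'   training size, the default rule).
#' @param boost a [boost_config()].
#' @param variant reduction variant, `"global"` or `"by_class"`.
#' @param nstart k-means++ restarts.
#' @return a `wsvm_model` or `boosted_ensemble`, with the reduction (if
#'   any) attached as attribute `"reduction"`.
#' @export
fit_method <- function(train, method = c("svm", "km_svm", "wsvm", "wkm_svm"),
                       C = 1, kernel = kernel_spec(), K = NULL,
                       boost = boost_config(),
                       variant = c("global", "by_class"), nstart = 10) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  units <- train
  red <- NULL
  if (method %in% c("km_svm", "wkm_svm")) {
    Kn <- if (is.null(K)) default_K(nrow(train$features)) else K
    if (method == "wkm_svm" && boost$recluster_each_round) {
      return(boost_fit_recluster(train, Kn, C, kernel, boost, variant,
                                 nstart))
    }
    red <- if (variant == "global") reduce_global(train, Kn, nstart = nstart)
           else reduce_by_class(train, Kn, nstart = nstart)
    units <- as_labeled_dataset(red)
  }
  fitted <- if (method %in% c("wsvm", "wkm_svm")) {
    boost_fit(units, C = C, kernel = kernel, config = boost)
  } else {
    solve_weighted_svm(units, C = C, kernel = kernel)
  }
  attr(fitted, "reduction") <- red
  fitted
}

new_experiment_report <- function(errors, config) {
  errors <- as.matrix(errors)
  structure(
    list(errors = errors,
         means = colMeans(errors),
         se = apply(errors, 2, sd) / sqrt(nrow(errors)),
         reps = nrow(errors),
         config = config),
    class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report:", x$reps, "repetitions\n")
  tab <- data.frame(method = colnames(x$errors),
                    mean_error = round(x$means, 4),
                    se = round(x$se, 4), row.names = NULL)
  print(tab)
  invisible(x)
}

#' @describeIn print.experiment_report tidy per-method summary.
#' @param report an `experiment_report`.
#' @export
summary_table <- function(report) {
  data.frame(method = colnames(report$errors), mean_error = report$means,
             se_error = report$se, reps = report$reps, row.names = NULL)
}

#' Two-class Gaussian simulation study
#'
#' Repeats the benchmark protocol: draw a fresh training set (`n_train`
#' samples) and test set (`n_test` samples) from the two-Gaussian design
#' with class-mean separation `r`; for each method select C by
#' `n_folds`-fold cross-validation over `C_grid`; fit on the full training
#' set (reduced methods use `K = floor(n_train / 2)` centers); record the
#' test misclassification rate. Each repetition runs under a child seed
#' derived from `seed` so the whole report is reproducible.
#'
#' @param r class-mean separation parameter (the +1 class has mean (r, r)).
#' @param reps number of repetitions.
#' @param seed master integer seed.
#' @param n_train,n_test sample sizes per repetition.
#' @param methods any subset of `"svm"`, `"km_svm"`, `"wsvm"`, `"wkm_svm"`.
#' @param kernel a [kernel_spec()] (Gaussian with `sigma = 1` by default).
#' @param C_grid cross-validation grid for C.
#' @param n_folds folds for the C selection.
#' @param boost a [boost_config()] for the weighted methods.
#' @param variant K-means reduction variant.
#' @param nstart k-means++ restarts.
#' @param baselines optional established reference classifiers to score on
#'   the same draws: any subset of `"cart"`, `"knn"`, `"rf"` (fit via
#'   rpart, class and randomForest; reported alongside, not tuned).
#' @return an `experiment_report`: per-repetition error matrix, means,
#'   standard errors (`sd/sqrt(reps)`), and a config echo.
#' @export
run_simulation_study <- function(r, reps, seed, n_train = 100, n_test = 1000,
                                 methods = c("svm", "km_svm", "wsvm",
                                             "wkm_svm"),
                                 kernel = kernel_spec("rbf", sigma = 1),
                                 C_grid = 2^(-5:5), n_folds = 5,
                                 boost = boost_config(),
                                 variant = "global", nstart = 10,
                                 baselines = character(0)) {
  stopifnot(reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  cols <- c(methods, baselines)
  errors <- matrix(NA_real_, reps, length(cols),
                   dimnames = list(NULL, cols))
  for (rep_i in seq_len(reps)) {
    set.seed(child_seed(seed, rep_i))
    d <- simulate_gaussian(n_train, n_test, r)
    for (method in methods) {
      cv <- cv_select_C(d$train, kernel = kernel,
                        config = cv_config(n_folds, C_grid),
                        method = method, boost = boost, variant = variant,
                        nstart = nstart)
      fitted <- fit_method(d$train, method, C = cv$C_best, kernel = kernel,
                           boost = boost, variant = variant, nstart = nstart)
      pred <- predict(fitted, d$test$features)
      errors[rep_i, method] <- mean(pred != d$test$labels)
    }
    for (bl in baselines) {
      errors[rep_i, bl] <- fit_baseline(d$train, d$test, bl)
    }
  }
  new_experiment_report(errors, list(
    r = r, reps = reps, seed = seed, n_train = n_train, n_test = n_test,
    kernel = unclass(kernel), C_grid = C_grid, n_folds = n_folds,
    K_rule = "floor(n_train/2)", boost_M = boost$M, variant = variant,
    nstart = nstart, seed_scheme = "(seed*1009 + rep) mod 2147483629"))
}

#' Error curves over a range of class separations
#'
#' Runs [run_simulation_study()] once per value of `r`, each under its own
#' derived child seed, tracing how the test error declines as the classes
#' separate.
#'
#' @param r_values vector of separation parameters.
#' @param reps repetitions per value.
#' @param seed master seed.
#' @param ... passed on to [run_simulation_study()].
#' @return named list of `experiment_report`s (names `r=<value>`).
#' @export
run_r_sweep <- function(r_values, reps, seed, ...) {
  out <- lapply(seq_along(r_values), function(j) {
    run_simulation_study(r_values[j], reps,
                         seed = child_seed(seed, 100000 + j), ...)
  })
  names(out) <- paste0("r=", r_values)
  out
}

#' Split-half evaluation with probe filtering
#'
#' Emulates the genomic-data protocol: stratified random split into halves,
#' probe filtering fitted on the training half only (the kept probe set is
#' then applied to the test half), `K` set to half the training size, all
#' requested methods tuned by cross-validation and scored on the held-out
#' half.
#'
#' @param data a [labeled_dataset()] (e.g. from [simulate_methylation()] or
#'   a real beta-value matrix).
#' @param filter a [filter_spec()] applied to the training half.
#' @param seed master seed.
#' @param reps number of independent random splits.
#' @inheritParams run_simulation_study
#' @return an `experiment_report` over splits.
#' @export
run_split_half <- function(data, filter = filter_spec(), seed, reps = 1,
                           methods = c("svm", "km_svm", "wsvm", "wkm_svm"),
                           kernel = kernel_spec("rbf", sigma = 1),
                           C_grid = 2^(-5:5), n_folds = 5,
                           boost = boost_config(), variant = "global",
                           nstart = 10) {
  stopifnot(inherits(data, "labeled_dataset"))
  methods <- match.arg(methods, several.ok = TRUE)
  errors <- matrix(NA_real_, reps, length(methods),
                   dimnames = list(NULL, methods))
  kept <- vector("list", reps)
  for (rep_i in seq_len(reps)) {
    set.seed(child_seed(seed, rep_i))
    half <- make_folds(data$labels, 2, stratified = TRUE)
    train <- subset_dataset(data, half == 1)
    test <- subset_dataset(data, half == 2)
    check_two_classes(train$labels, "split-half training")
    check_two_classes(test$labels, "split-half testing")
    filt <- filter_probes(train, filter)
    kept[[rep_i]] <- filt$kept_ids
    train <- filt$filtered
    test <- subset_dataset(test,
                           cols = match(filt$kept_ids, test$feature_ids))
    for (method in methods) {
      cv <- cv_select_C(train, kernel = kernel,
                        config = cv_config(n_folds, C_grid),
                        method = method, boost = boost, variant = variant,
                        nstart = nstart)
      fitted <- fit_method(train, method, C = cv$C_best, kernel = kernel,
                           boost = boost, variant = variant, nstart = nstart)
      errors[rep_i, method] <- mean(predict(fitted, test$features) !=
                                      test$labels)
    }
  }
  out <- new_experiment_report(errors, list(
    filter = unclass(filter), seed = seed, reps = reps,
    K_rule = "floor(n_train/2)", kernel = unclass(kernel),
    C_grid = C_grid, n_folds = n_folds, variant = variant))
  attr(out, "kept_ids") <- kept
  out
}
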