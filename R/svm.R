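#' Fit a weighted soft-margin SVM
#'
#' Solves the per-sample-weighted hinge-loss SVM
#' \deqn{\min_{w,b,\xi} \tfrac12\|w\|^2 + C\sum_n \xi_n, \quad
#'   \xi_n \ge 0,\ \xi_n \ge c_n(1 - y_n(\langle w,x_n\rangle + b))}
#' through its Wolfe dual
#' \deqn{\max_\alpha \sum_n \alpha_n c_n - \tfrac12 \sum_{n,m}
#'   \alpha_n c_n y_n \, \alpha_m c_m y_m \, k(x_n, x_m)}
#' subject to \eqn{\sum_n \alpha_n c_n y_n = 0} and
#' \eqn{0 \le \alpha_n \le C}. The change of variables
#' \eqn{\beta_n = \alpha_n c_n} turns this into a standard SVM dual with
#' per-sample box bounds \eqn{0 \le \beta_n \le C c_n}, which is solved by a
#' sequential minimal optimization (SMO) working-set algorithm. With all
#' weights equal to 1 the fit coincides with the ordinary soft-margin SVM.
#'
#' Bias recovery: average of \eqn{y_n - \sum_m \beta_m y_m k(x_m, x_n)} over
#' free vectors (\eqn{0 < \beta_n < C c_n}); if no vector is free, the
#' midpoint of the interval allowed by the box-bound KKT inequalities.
#' Weights below `1e-12` are treated as exactly zero; such samples can never
#' become support vectors.
#'
#' @param data a [labeled_dataset()].
#' @param weights nonnegative per-sample weights `c_n` (default all 1).
#' @param C positive regularization constant.
#' @param kernel a [kernel_spec()].
#' @param tol KKT violation tolerance of the SMO solver (internally scaled
#'   by `max(1, C)`, the scale of the dual box).
#' @param max_iter maximum SMO iterations; default `max(10 * N^2, 2000)`.
#' @param gram optional precomputed training Gram matrix (N x N), as
#'   produced by [gram_matrix()] on `data$features`; saves recomputation in
#'   tight loops such as boosting or cross-validation.
#' @return an object of class `wsvm_model`: support vectors, their labels,
#'   weights and dual coefficients `alpha`, effective coefficients
#'   `beta = alpha * c`, bias, `C`, kernel, and solver diagnostics.
#' @seealso [decision_function()], [kkt_report()], [solve_weighted_svm_qp()]
#' @export
solve_weighted_svm <- function(data, weights = NULL, C = 1,
                               kernel = kernel_spec(), tol = 1e-6,
                               max_iter = NULL, gram = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  X <- data$features
  y <- data$labels
  N <- nrow(X)
  check_two_classes(y)
  if (is.null(weights)) weights <- rep(1, N)
  weights <- as.numeric(weights)
  if (length(weights) != N) stop("'weights' must have one entry per sample")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("'weights' must be finite and nonnegative")
  }
  weights[weights < 1e-12] <- 0
  if (all(weights == 0)) stop("all sample weights are zero; nothing to fit")
  for (cls in c(-1, 1)) {
    if (all(weights[y == cls] == 0)) {
      stop("all weights of class ", cls, " are zero; both classes need ",
           "at least one strictly positive weight")
    }
  }
  if (!is.numeric(C) || length(C) != 1 || C <= 0) stop("'C' must be positive")
  if (is.null(max_iter)) max_iter <- max(10L * N^2, 2000L)
  if (is.null(gram)) gram <- gram_matrix(X, X, kernel)

  # the pairwise KKT violation lives on the scale of the box bounds, so the
  # stopping tolerance scales with C for C > 1
  sol <- smo_solve(gram, y, C * weights, tol * max(1, C),
                  as.integer(max_iter))
  if (!sol$converged) {
    stop("SMO solver did not converge within ", max_iter,
         " iterations (KKT violation ", format(sol$kkt_violation), ")")
  }
  beta <- sol$beta
  alpha <- ifelse(weights > 0, beta / pmax(weights, 1e-300), 0)
  sv <- which(beta > 1e-10)
  structure(
    list(support_vectors = X[sv, , drop = FALSE],
         support_labels = y[sv],
         support_weights = weights[sv],
         dual_coefs = alpha[sv],
         coefs = beta[sv] * y[sv],      # expansion coefficients beta_n * y_n
         bias = sol$bias,
         C = C, kernel = kernel,
         n_features = ncol(X),
         sv_index = sv,
         alpha_full = alpha,
         weights_full = weights,
         objective = sol$objective,
         iterations = sol$iterations,
         converged = sol$converged,
         kkt_violation = sol$kkt_violation),
    class = "wsvm_model")
}

#' @export
print.wsvm_model <- function(x, ...) {
  cat("weighted SVM model: ", length(x$support_labels), " support vectors, ",
      x$kernel$name, " kernel, C = ", x$C, "\n", sep = "")
  cat("  bias ", format(x$bias), ", dual objective ", format(x$objective),
      "\n", sep = "")
  invisible(x)
}

#' Decision values of a fitted weighted SVM
#'
#' \eqn{f(x) = \sum_n \alpha_n c_n y_n k(x_n, x) + b} over the support
#' vectors.
#'
#' @param model a `wsvm_model`.
#' @param X numeric matrix of query points (rows).
#' @return numeric vector of decision values.
#' @export
decision_function <- function(model, X) {
  stopifnot(inherits(model, "wsvm_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop("feature dimension mismatch: model expects ", model$n_features,
         " features, got ", ncol(X))
  }
  if (length(model$coefs) == 0) return(rep(model$bias, nrow(X)))
  Kc <- gram_matrix(X, model$support_vectors, model$kernel)
  drop(Kc %*% model$coefs) + model$bias
}

#' @describeIn decision_function predicted labels, `sign(f(x))` with ties
#'   (`f(x) == 0`) assigned to class `+1`.
#' @param object a `wsvm_model` (for the `predict` method).
#' @param newdata matrix of query points.
#' @param ... unused.
#' @export
predict.wsvm_model <- function(object, newdata, ...) {
  f <- decision_function(object, newdata)
  ifelse(f >= 0, 1, -1)
}

#' KKT diagnostics of a fitted weighted SVM
#'
#' Recomputes, on the training data, the maximal violation over the dual box
#' constraints, the equality constraint `sum(alpha * c * y) = 0`,
#' complementary slackness at free dual coefficients, and the (normalized)
#' duality gap between the weighted primal objective and the dual objective.
#'
#' @param model a `wsvm_model` fitted on `data`.
#' @param data the training [labeled_dataset()].
#' @param weights the training weights used in the fit (default: the ones
#'   stored in the model).
#' @return a list of class `kkt_report` with per-condition violations,
#'   `primal_value`, `dual_value`, `duality_gap` and the aggregate
#'   `kkt_violation`.
#' @export
kkt_report <- function(model, data, weights = NULL) {
  stopifnot(inherits(model, "wsvm_model"), inherits(data, "labeled_dataset"))
  if (is.null(weights)) weights <- model$weights_full
  y <- data$labels
  alpha <- model$alpha_full
  beta <- alpha * weights
  C <- model$C
  f <- decision_function(model, data$features)

  box <- max(0, max(-alpha), max(alpha - C))
  eqcon <- abs(sum(beta * y))
  free <- which(alpha > 1e-6 * C & alpha < C * (1 - 1e-6) & weights > 1e-12)
  slack <- if (length(free)) max(abs(weights[free] * (1 - y[free] * f[free])))
           else 0
  # primal: 1/2 ||w||^2 + C sum c_n [1 - y f]_+ ; ||w||^2 = beta' Q beta
  K <- gram_matrix(data$features, data$features, model$kernel)
  w2 <- drop(t(beta * y) %*% K %*% (beta * y))
  primal <- 0.5 * w2 + C * sum(weights * pmax(1 - y * f, 0))
  dual <- sum(beta) - 0.5 * w2
  gap <- primal - dual
  viol <- max(box, eqcon, slack, abs(gap) / (1 + abs(primal)))
  structure(
    list(alphas = alpha, objective_value = dual, primal_value = primal,
         duality_gap = gap, box_violation = box, equality_violation = eqcon,
         slackness_violation = slack, kkt_violation = viol,
         iterations = model$iterations, converged = model$converged),
    class = "kkt_report")
}

#' @export
print.kkt_report <- function(x, ...) {
  cat("KKT report: max violation ", format(x$kkt_violation), "\n",
      "  box ", format(x$box_violation),
      ", equality ", format(x$equality_violation),
      ", slackness ", format(x$slackness_violation),
      ", duality gap ", format(x$duality_gap), "\n", sep = "")
  invisible(x)
}

#' Reference dense-QP solution of the weighted SVM dual
#'
#' Solves the same weighted Wolfe dual with `kernlab::ipop`, a generic
#' interior-point quadratic-programming solver, entirely independent of the
#' SMO path. Intended as a cross-check on small problems.
#'
#' @inheritParams solve_weighted_svm
#' @param ridge small diagonal ridge added to the dual Hessian for numerical
#'   stability of the interior-point solver.
#' @return a `wsvm_model` (with solver diagnostics from ipop).
#' @export
solve_weighted_svm_qp <- function(data, weights = NULL, C = 1,
                                  kernel = kernel_spec(), ridge = 1e-8) {
  if (!requireNamespace("kernlab", quietly = TRUE)) {
    stop("solve_weighted_svm_qp requires the 'kernlab' package")
  }
  stopifnot(inherits(data, "labeled_dataset"))
  X <- data$features
  y <- data$labels
  N <- nrow(X)
  check_two_classes(y)
  if (is.null(weights)) weights <- rep(1, N)
  weights <- as.numeric(weights)
  weights[weights < 1e-12] <- 0
  act <- which(weights > 0)
  Xa <- X[act, , drop = FALSE]
  ya <- y[act]
  Ua <- C * weights[act]
  K <- gram_matrix(Xa, Xa, kernel)
  H <- (ya %o% ya) * K + diag(ridge, length(act))
  cap <- utils::capture.output(
    sol <- kernlab::ipop(c = matrix(-1, length(act), 1), H = H,
                         A = matrix(ya, 1), b = 0, r = 0,
                         l = matrix(0, length(act), 1),
                         u = matrix(Ua, length(act), 1),
                         sigf = 9, maxiter = 200))
  beta_a <- pmin(pmax(drop(kernlab::primal(sol)), 0), Ua)
  beta <- numeric(N)
  beta[act] <- beta_a
  # bias from free vectors of this solution
  f0 <- drop(K %*% (beta_a * ya))
  rel <- pmax(1, Ua)
  free <- which(beta_a > 1e-6 * rel & beta_a < Ua - 1e-6 * rel)
  bias <- if (length(free)) mean(ya[free] - f0[free]) else {
    # midpoint of [max lower, min upper] bounds on b from the box-bound KKT
    # inequalities: y f >= 1 at beta = 0, y f <= 1 at beta = C c
    lower <- suppressWarnings(max(c(-Inf, (1 - f0[ya > 0 & beta_a <= 1e-9]),
                                    (-1 - f0[ya < 0 & beta_a >= Ua - 1e-9]))))
    upper <- suppressWarnings(min(c(Inf, (1 - f0[ya > 0 & beta_a >= Ua - 1e-9]),
                                   (-1 - f0[ya < 0 & beta_a <= 1e-9]))))
    if (is.finite(lower) && is.finite(upper)) (lower + upper) / 2
    else if (is.finite(lower)) lower else if (is.finite(upper)) upper else 0
  }
  alpha <- numeric(N)
  alpha[act] <- beta_a / weights[act]
  sv <- which(beta > 1e-10)
  obj <- sum(beta_a) - 0.5 * drop(t(beta_a * ya) %*% K %*% (beta_a * ya))
  structure(
    list(support_vectors = X[sv, , drop = FALSE],
         support_labels = y[sv],
         support_weights = weights[sv],
         dual_coefs = alpha[sv],
         coefs = beta[sv] * y[sv],
         bias = bias,
         C = C, kernel = kernel,
         n_features = ncol(X),
         sv_index = sv,
         alpha_full = alpha,
         weights_full = weights,
         objective = obj,
         iterations = NA_integer_,
         converged = TRUE,
         kkt_violation = NA_real_),
    class = "wsvm_model")
}
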