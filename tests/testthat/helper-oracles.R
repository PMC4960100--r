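# shared fixtures and independent oracles for the solver tests

# random weighted-SVM instance; weights in [0.2, 2] unless unweighted
rand_instance <- function(seed, N = 16, dim = 3, weighted = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(N * dim), N, dim)
  y <- rep(c(-1, 1), length.out = N)[sample.int(N)]
  X[y == 1, 1] <- X[y == 1, 1] + 1  # mild separation so fits are non-trivial
  list(data = labeled_dataset(X, y),
       weights = if (weighted) runif(N, 0.2, 2) else rep(1, N),
       C = 2^runif(1, -1, 2),
       kernel = if (seed %% 2 == 0) kernel_spec("rbf", sigma = 1)
                else kernel_spec("linear"))
}

# decision values from e1071/libsvm at tight termination tolerance, with
# its class-ordering sign convention normalized to ours
e1071_decision <- function(X, y, C, kernel, newX = X) {
  fit <- e1071::svm(X, factor(y, levels = c(-1, 1)), scale = FALSE,
                    kernel = if (kernel$name == "rbf") "radial" else "linear",
                    gamma = if (kernel$name == "rbf")
                      1 / (2 * kernel$sigma^2) else 1,
                    cost = C, tolerance = 1e-11)
  dv <- attr(predict(fit, newX, decision.values = TRUE), "decision.values")
  f <- drop(dv)
  if (colnames(dv)[1] == "-1/1") f <- -f
  f
}

# weighted dual objective for arbitrary beta (maximization form)
dual_objective <- function(beta, y, K) {
  sum(beta) - 0.5 * drop(t(beta * y) %*% K %*% (beta * y))
}

# two blob clusters that every sensible classifier separates
separable_blobs <- function(n_per_class = 10, gap = 8, seed = 1, dim = 2) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * dim, 0, 0.3), n_per_class),
             matrix(rnorm(n_per_class * dim, gap, 0.3), n_per_class))
  labeled_dataset(X, rep(c(-1, 1), each = n_per_class))
}
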