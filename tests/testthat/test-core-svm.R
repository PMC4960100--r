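test_that("gram_matrix follows the stated kernel conventions", {
  x <- matrix(rnorm(10), 5, 2)
  Krbf <- gram_matrix(x, x, kernel_spec("rbf", sigma = 1))
  expect_equal(diag(Krbf), rep(1, 5))
  expect_equal(Krbf, t(Krbf))
  expect_gt(min(eigen(Krbf, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
  # exp(-||(0,0)-(2,2)||^2 / 2) = exp(-4)
  expect_equal(gram_matrix(rbind(c(0, 0)), rbind(c(2, 2)),
                           kernel_spec("rbf", 1))[1, 1],
               exp(-4), tolerance = 1e-12)
  expect_equal(gram_matrix(diag(2), diag(2), kernel_spec("linear")), diag(2))
  expect_error(gram_matrix(matrix(0, 2, 2), matrix(0, 2, 3)),
               "dimension mismatch")
  expect_error(kernel_spec("rbf", sigma = 0), "sigma")
})

test_that("two-point instance reproduces the closed-form solution", {
  d <- labeled_dataset(rbind(c(0, 0), c(2, 2)), c(-1, 1))
  m <- solve_weighted_svm(d, C = 10, kernel = kernel_spec("linear"),
                          tol = 1e-12)
  # maximum-margin hyperplane through (1,1): w = (0.5, 0.5), b = -1,
  # alpha = (0.25, 0.25)
  expect_equal(m$dual_coefs, c(0.25, 0.25), tolerance = 1e-9)
  expect_equal(m$bias, -1, tolerance = 1e-9)
  w <- drop(t(m$support_vectors) %*% m$coefs)
  expect_equal(w, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(decision_function(m, rbind(c(1, 1))), 0, tolerance = 1e-9)
  expect_equal(decision_function(m, rbind(c(2, 2))), 1, tolerance = 1e-9)
  # tie convention: f = 0 predicts +1
  expect_equal(predict(m, rbind(c(1, 1))), 1)
})

test_that("unit weights recover the standard soft-margin SVM", {
  skip_if_not_installed("e1071")
  # Gaussian-kernel instances: the Gram matrix is strictly positive
  # definite, so the dual optimum is unique and the cross-solver
  # comparison is numerically well posed (with a linear kernel libsvm's
  # own termination residual can exceed the tolerance asserted here)
  for (s in c(2, 6, 10)) {
    inst <- rand_instance(s, N = 20, weighted = FALSE)
    m <- solve_weighted_svm(inst$data, C = inst$C, kernel = inst$kernel,
                            tol = 1e-11)
    f_ref <- e1071_decision(inst$data$features, inst$data$labels, inst$C,
                            inst$kernel)
    expect_lt(max(abs(decision_function(m, inst$data$features) - f_ref)),
              1e-6)
  }
})

test_that("SMO solution matches the interior-point dual oracle", {
  skip_if_not_installed("kernlab")
  for (s in 1:12) {
    inst <- rand_instance(s, N = 14 + s %% 5, dim = 2 + s %% 3)
    m <- solve_weighted_svm(inst$data, inst$weights, inst$C, inst$kernel,
                            tol = 1e-9)
    q <- solve_weighted_svm_qp(inst$data, inst$weights, inst$C, inst$kernel)
    expect_lt(abs(m$objective - q$objective), 1e-5 * (1 + abs(m$objective)))
    expect_lt(max(abs(decision_function(m, inst$data$features) -
                        decision_function(q, inst$data$features))), 1e-4)
  }
})

test_that("rescaling weights against C leaves the fit invariant", {
  inst <- rand_instance(4, N = 18)
  gam <- 3
  m1 <- solve_weighted_svm(inst$data, inst$weights, inst$C, inst$kernel,
                           tol = 1e-10)
  m2 <- solve_weighted_svm(inst$data, inst$weights * gam, inst$C / gam,
                           inst$kernel, tol = 1e-10)
  # the effective coefficients beta = alpha * c and decisions are unchanged
  expect_equal(m1$alpha_full * inst$weights,
               m2$alpha_full * inst$weights * gam, tolerance = 1e-6)
  expect_lt(max(abs(decision_function(m1, inst$data$features) -
                      decision_function(m2, inst$data$features))), 1e-6)
})

test_that("zero-weight samples never become support vectors", {
  inst <- rand_instance(8, N = 20)
  w <- inst$weights
  w[c(3, 11, 17)] <- 0
  m <- solve_weighted_svm(inst$data, w, inst$C, inst$kernel)
  expect_false(any(c(3, 11, 17) %in% m$sv_index))
  expect_equal(m$alpha_full[c(3, 11, 17)] * w[c(3, 11, 17)], rep(0, 3))
})

test_that("sample order does not affect the fitted function", {
  inst <- rand_instance(6, N = 16)
  set.seed(99)
  perm <- sample.int(16)
  dp <- labeled_dataset(inst$data$features[perm, ],
                        inst$data$labels[perm])
  m1 <- solve_weighted_svm(inst$data, inst$weights, inst$C, inst$kernel,
                           tol = 1e-10)
  m2 <- solve_weighted_svm(dp, inst$weights[perm], inst$C, inst$kernel,
                           tol = 1e-10)
  q <- matrix(rnorm(5 * ncol(inst$data$features)), 5)
  expect_lt(max(abs(decision_function(m1, q) - decision_function(m2, q))),
            1e-6)
})

test_that("KKT report certifies optima and flags perturbations", {
  inst <- rand_instance(3, N = 20)
  m <- solve_weighted_svm(inst$data, inst$weights, inst$C, inst$kernel,
                          tol = 1e-9)
  rep <- kkt_report(m, inst$data, inst$weights)
  expect_lt(rep$kkt_violation, 1e-5)
  expect_gte(rep$duality_gap, -1e-8)
  expect_lt(abs(rep$duality_gap), 1e-5 * (1 + abs(rep$primal_value)))
  # the slack-constrained primal evaluated at the optimal slacks
  # xi*_n = c_n [1 - y_n f(x_n)]_+ equals the weighted hinge objective;
  # recompute both from the support-vector expansion, independently of
  # kkt_report's internals
  y <- inst$data$labels
  f <- decision_function(m, inst$data$features)
  xi_star <- inst$weights * pmax(1 - y * f, 0)
  Ksv <- gram_matrix(m$support_vectors, m$support_vectors, m$kernel)
  w2 <- drop(t(m$coefs) %*% Ksv %*% m$coefs)
  expect_equal(0.5 * w2 + m$C * sum(xi_star), rep$primal_value,
               tolerance = 1e-8)

  mb <- m
  mb$bias <- m$bias + 0.5
  repb <- kkt_report(mb, inst$data, inst$weights)
  expect_gt(repb$slackness_violation, 0.1)
})

test_that("invalid fitting inputs are rejected", {
  d <- labeled_dataset(matrix(rnorm(12), 6, 2), rep(1, 6))
  expect_error(solve_weighted_svm(d), "both classes")
  d2 <- labeled_dataset(matrix(rnorm(12), 6, 2), rep(c(-1, 1), 3))
  expect_error(solve_weighted_svm(d2, weights = rep(0, 6)), "zero")
  expect_error(solve_weighted_svm(d2, weights = c(0, 1, 0, 1, 0, 1)),
               "class -1")
  m <- solve_weighted_svm(d2, C = 1)
  expect_error(decision_function(m, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("labels coded 0/1 are remapped with a message", {
  expect_message(d <- labeled_dataset(matrix(rnorm(8), 4, 2), c(0, 1, 0, 1)),
                 "remapping")
  expect_equal(d$labels, c(-1, 1, -1, 1))
})
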