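test_that("default_K is half the training size, floored", {
  expect_equal(default_K(100), 50L)
  expect_equal(default_K(2), 1L)
  expect_equal(default_K(101), 50L)
  expect_error(default_K(1), "at least 2")
})

test_that("K = N reduction is the identity on the samples", {
  set.seed(1)
  X <- matrix(rnorm(16), 8, 2)
  d <- labeled_dataset(X, rep(c(-1, 1), each = 4))
  red <- reduce_global(d, 8, seed = 3)
  expect_equal(red$member_counts, rep(1L, 8))
  ord <- order(red$centers[, 1])
  oin <- order(X[, 1])
  expect_equal(red$centers[ord, ], X[oin, ], tolerance = 1e-12)
  expect_equal(red$center_labels[ord], d$labels[oin])
  bc <- reduce_by_class(d, 8, seed = 3)
  expect_equal(sort(bc$centers[, 1]), sort(X[, 1]), tolerance = 1e-12)
})

test_that("KM-SVM on a K = N reduction equals the plain SVM", {
  set.seed(2)
  d <- simulate_gaussian(30, 50, r = 1, seed = 21)
  red <- reduce_global(d$train, 30, seed = 5)
  m_red <- solve_weighted_svm(as_labeled_dataset(red), C = 1, tol = 1e-11)
  m_raw <- solve_weighted_svm(d$train, C = 1, tol = 1e-11)
  expect_lt(max(abs(decision_function(m_red, d$test$features) -
                      decision_function(m_raw, d$test$features))), 1e-8)
})

test_that("well-separated pairs collapse to their midpoints", {
  d <- labeled_dataset(rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5.1, 5)),
                       c(-1, -1, 1, 1))
  red <- reduce_global(d, 2, seed = 1)
  ord <- order(red$centers[, 1])
  expect_equal(red$centers[ord, ], rbind(c(0.05, 0), c(5.05, 5)),
               tolerance = 1e-12)
  expect_equal(red$center_labels[ord], c(-1, 1))
  expect_equal(red$member_counts, c(2L, 2L))
})

test_that("center labels follow the majority vote and flip with labels", {
  d <- labeled_dataset(rbind(c(0, 0), c(0.2, 0), c(0.1, 0.2), c(9, 9)),
                       c(1, 1, -1, -1))
  red <- reduce_global(d, 2, seed = 2)
  lab_of_tight <- red$center_labels[which.min(red$centers[, 1])]
  expect_equal(lab_of_tight, 1)  # 2 votes +1 vs 1 vote -1
  dflip <- labeled_dataset(d$features, -d$labels)
  redf <- reduce_global(dflip, 2, seed = 2)
  expect_equal(redf$center_labels, -red$center_labels)
})

test_that("by-class reduction never mixes classes and allocates by size", {
  set.seed(4)
  X <- rbind(matrix(rnorm(180), 90, 2), matrix(rnorm(20, 3), 10, 2))
  d <- labeled_dataset(X, rep(c(-1, 1), c(90, 10)))
  red <- reduce_by_class(d, 10, seed = 6)
  expect_equal(sum(red$center_labels == -1), 9)
  expect_equal(sum(red$center_labels == 1), 1)
  expect_equal(sum(red$member_counts), 100)
  bal <- labeled_dataset(matrix(rnorm(80), 40, 2), rep(c(-1, 1), each = 20))
  redb <- reduce_by_class(bal, 10, seed = 6)
  expect_equal(sum(redb$center_labels == -1), 5)
  expect_equal(sum(redb$center_labels == 1), 5)
})

test_that("within-cluster sum of squares never increases across iterations", {
  set.seed(5)
  d <- labeled_dataset(matrix(rnorm(300), 150, 2),
                       rep(c(-1, 1), each = 75))
  red <- reduce_global(d, 12, seed = 8)
  trace <- attr(red, "wcss_trace")
  expect_true(all(diff(trace) <= 1e-9))
  expect_equal(sum(red$member_counts), 150)
  # final WCSS is no worse than stats::kmeans on the same data
  ref <- kmeans(d$features, 12, nstart = 10)
  expect_lt(trace[length(trace)], ref$tot.withinss * 1.05)
})

test_that("invalid K is rejected", {
  d <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(c(-1, 1), 5))
  expect_error(reduce_global(d, 11), "exceed")
  expect_error(reduce_global(d, 0), "at least 1")
})
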