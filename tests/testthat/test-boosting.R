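test_that("one reweighting step reproduces the hand-computed update", {
  # 4 uniform units, one misclassified: err 1/4, alpha log 3, weights
  # (1/6, 1/6, 1/6, 1/2)
  st <- adaboost_step(rep(0.25, 4), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(st$err, 0.25)
  expect_equal(st$alpha, log(3), tolerance = 1e-12)
  expect_equal(st$weights, c(1/6, 1/6, 1/6, 1/2), tolerance = 1e-12)
  expect_equal(sum(st$weights), 1)
})

test_that("fitted ensembles respect the AdaBoost training-error bound", {
  for (s in 1:3) {
    d <- simulate_gaussian(60, 2, r = 1, seed = 30 + s)
    ens <- boost_fit(d$train, C = 1, config = boost_config(M = 6))
    agg_err <- mean(boost_predict(ens, d$train$features) != d$train$labels)
    bound <- prod(2 * sqrt(ens$train_errors * (1 - ens$train_errors)))
    expect_lte(agg_err, bound + 1e-12)
    expect_true(all(ens$vote_weights > 0))
    expect_equal(sum(ens$final_weights), 1, tolerance = 1e-12)
    expect_true(all(ens$final_weights > 0))
  }
})

test_that("a single round reproduces the uniformly weighted SVM", {
  d <- simulate_gaussian(40, 100, r = 1, seed = 41)
  ens <- boost_fit(d$train, C = 2, config = boost_config(M = 1))
  expect_length(ens$weak_models, 1)
  ref <- solve_weighted_svm(d$train, rep(1 / 40, 40), C = 2)
  expect_equal(boost_predict(ens, d$test$features),
               predict(ref, d$test$features))
})

test_that("weighted sign vote follows the vote arithmetic", {
  d <- labeled_dataset(rbind(c(0, 0), c(2, 2)), c(-1, 1))
  m_fwd <- solve_weighted_svm(d, C = 10, kernel = kernel_spec("linear"))
  m_rev <- solve_weighted_svm(labeled_dataset(d$features, -d$labels),
                              C = 10, kernel = kernel_spec("linear"))
  ens <- structure(
    list(weak_models = list(m_fwd, m_fwd, m_rev),
         vote_weights = c(1, 1, 3), units = d,
         kernel = kernel_spec("linear"), shared_units = TRUE),
    class = "boosted_ensemble")
  # two votes for the forward model's label, outweighed by 3 for reverse
  q <- rbind(c(0, 0), c(2, 2))
  expect_equal(boost_predict(ens, q), -predict(m_fwd, q))
  # splitting a member's vote in half across a duplicate changes nothing
  ens2 <- ens
  ens2$weak_models <- c(ens$weak_models, list(m_rev))
  ens2$vote_weights <- c(1, 1, 1.5, 1.5)
  expect_equal(boost_predict(ens2, q), boost_predict(ens, q))
})

test_that("degenerate rounds terminate the loop with a usable ensemble", {
  sep <- separable_blobs(8, gap = 10, seed = 3)
  ens <- boost_fit(sep, C = 10, config = boost_config(M = 5))
  expect_length(ens$weak_models, 1)  # perfect round: stop, keep capped vote
  expect_lt(ens$train_errors[1], 1e-9)
  expect_true(is.finite(ens$vote_weights[1]) && ens$vote_weights[1] > 0)
  expect_equal(mean(boost_predict(ens, sep$features) != sep$labels), 0)

  # chance-level first round (coincident points with opposite labels):
  # keep the single learner with a vanishing vote, never an empty ensemble
  coin <- labeled_dataset(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)),
                          c(1, -1, 1, -1))
  ensx <- boost_fit(coin, C = 1, kernel = kernel_spec("linear"),
                    config = boost_config(M = 5))
  expect_length(ensx$weak_models, 1)
  expect_gte(ensx$train_errors[1], 0.5)
})

test_that("boosting trace starts at the first weak learner's error", {
  d <- simulate_gaussian(60, 200, r = 1, seed = 55)
  ens <- boost_fit(d$train, C = 1, config = boost_config(M = 4))
  tr <- boosting_trace(ens, d$test)
  expect_length(tr, length(ens$weak_models))
  first <- mean(predict(ens$weak_models[[1]], d$test$features) !=
                  d$test$labels)
  expect_equal(tr[1], first)
  expect_true(all(tr >= 0 & tr <= 1))
})

test_that("boosting is deterministic and the recluster variant works", {
  d <- simulate_gaussian(40, 60, r = 1, seed = 77)
  e1 <- boost_fit(d$train, C = 1, config = boost_config(M = 3))
  e2 <- boost_fit(d$train, C = 1, config = boost_config(M = 3))
  expect_identical(e1$vote_weights, e2$vote_weights)
  expect_identical(e1$final_weights, e2$final_weights)

  set.seed(9)
  rc <- fit_method(d$train, "wkm_svm", C = 1,
                   boost = boost_config(M = 3, recluster_each_round = TRUE))
  expect_s3_class(rc, "boosted_ensemble")
  expect_false(rc$shared_units)
  p <- predict(rc, d$test$features)
  expect_true(all(p %in% c(-1, 1)))
})
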