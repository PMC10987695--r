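test_that("balanced accuracy equals the mean of per-class recalls", {
  expect_equal(balanced_accuracy(diag(6) * 7), 1)
  toy <- matrix(c(5, 5, 0, 10), 2, byrow = TRUE)  # recalls 0.5 and 1.0
  expect_equal(balanced_accuracy(toy), 0.75)
  bad <- diag(6); bad[3, ] <- 0
  expect_error(balanced_accuracy(bad), "no true instances")
})

test_that("beta updating is conjugate, associative and order-invariant", {
  p <- beta_update(beta_posterior(1, 1), 3, 1)
  expect_equal(c(p$alpha, p$beta), c(4, 2))
  expect_equal(beta_update(p, 0, 0), p)
  a <- beta_update(beta_update(beta_posterior(1, 1), 1, 0), 2, 1)
  b <- beta_update(beta_posterior(1, 1), 3, 1)
  expect_equal(a, b)
  set.seed(2)
  for (rep in 1:5) {
    counts <- matrix(sample(0:10, 8, replace = TRUE), 4)
    p1 <- beta_posterior(1, 1)
    for (i in 1:4) p1 <- beta_update(p1, counts[i, 1], counts[i, 2])
    p2 <- beta_update(beta_posterior(1, 1), sum(counts[, 1]), sum(counts[, 2]))
    expect_equal(p1, p2)
  }
  expect_error(beta_update(p, -1, 0), "non-negative")
})

test_that("the MAP follows the closed form with the documented fallback", {
  expect_equal(beta_map(beta_posterior(2, 2)), 0.5)
  expect_equal(beta_map(beta_posterior(10, 4)), 0.75)
  expect_equal(beta_map(beta_posterior(1, 1)), 0.5)  # mean fallback
  expect_equal(beta_map(beta_posterior(1, 3)), 0.25)  # mean fallback
})

test_that("exceedance probabilities match analytic and quadrature oracles", {
  p <- beta_posterior(5, 5)
  expect_equal(prob_greater(p, p, draws = 20000, seed = 1), 0.5,
               tolerance = 0.01)
  # closed form: P(a > b) = 5/6 for beta(2,1) vs beta(1,2)
  a <- beta_posterior(2, 1); b <- beta_posterior(1, 2)
  expect_equal(prob_greater(a, b, method = "quadrature"), 5 / 6,
               tolerance = 1e-6)
  expect_equal(prob_greater(a, b, draws = 100000, seed = 2), 5 / 6,
               tolerance = 0.01)
  dom <- prob_greater(beta_posterior(50, 10), beta_posterior(10, 50),
                      method = "quadrature")
  expect_gt(dom, 0.99)
  expect_error(prob_greater(a, b, draws = 500), "at least 10,000")
})

test_that("Monte-Carlo exceedance agrees with quadrature over random pairs", {
  set.seed(7)
  for (i in 1:20) {
    a <- beta_posterior(stats::runif(1, 1, 80), stats::runif(1, 1, 80))
    b <- beta_posterior(stats::runif(1, 1, 80), stats::runif(1, 1, 80))
    mc <- prob_greater(a, b, draws = 100000, seed = i)
    quad <- prob_greater(a, b, method = "quadrature")
    expect_lt(abs(mc - quad), 0.01)
  }
})

test_that("the overlap coefficient behaves as a bounded symmetric similarity", {
  p <- beta_posterior(8, 3)
  expect_equal(overlap_coefficient(p, p), 1, tolerance = 1e-6)
  sep <- overlap_coefficient(beta_posterior(500, 10), beta_posterior(10, 500))
  expect_lt(sep, 0.001)
  a <- beta_posterior(12, 30); b <- beta_posterior(20, 9)
  expect_equal(overlap_coefficient(a, b), overlap_coefficient(b, a),
               tolerance = 1e-6)
  expect_true(overlap_coefficient(a, b) >= 0 && overlap_coefficient(a, b) <= 1)
})

test_that("a simulated random classifier recovers the 1/6 chance level", {
  post <- random_classifier_posterior(10000, seed = 5)
  expect_lt(abs(beta_mean(post) - 1 / 6), 3 * beta_sd(post))
  expect_equal(attr(post, "expected_rate"), 1 / 6)
  expect_error(random_classifier_posterior(0), "at least 1")
})

test_that("human rating counts convert to per-emotion posteriors", {
  hp <- human_posteriors(tibble::tibble(emotion = "joy", correct = 30,
                                        total = 40))
  expect_equal(c(hp$alpha, hp$beta), c(31, 11))
  expect_warning(
    hp2 <- human_posteriors(tibble::tibble(
      emotion = c("joy", "fear"), correct = c(3, 0), total = c(5, 0))),
    "no ratings")
  expect_equal(hp2$emotion, "joy")
  expect_error(human_posteriors(tibble::tibble(emotion = "joy", correct = 5,
                                               total = 4)), "exceed")
  # identical posteriors overlap fully
  cmp <- compare_posteriors(hp, hp)
  expect_equal(cmp$overlap, 1, tolerance = 1e-6)
})

test_that("stratified folds partition the data exactly once per fold", {
  labels <- as_emotion(rep(emotion_levels(), each = 10))
  fold <- stratified_folds(labels, 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) == 6))
  for (f in 1:10) {
    expect_true(all(table(labels[fold == f]) == 1))
  }
  expect_identical(fold, stratified_folds(labels, 10, seed = 3))
})

test_that("cross-validation reports per-fold confusions and balanced accuracy", {
  ds <- tiny_dataset(separation = 1, n_per_class = 5, seed = 21)
  cv <- run_cv(ds, "dnn", k = 5, seed = 2,
               config = model_config("dnn", hidden = c(32), seed = 2,
                                     max_epochs = 2))
  expect_equal(nrow(cv$folds), 5)
  for (cm in cv$folds$confusion) expect_equal(sum(cm), 6)
  g <- glance(cv)
  expect_true(g$mean_bac >= 0 && g$mean_bac <= 1)
  expect_gt(g$mean_bac, 1 / 6)  # separable classes: clearly above chance
})

test_that("independent validation keeps exact bookkeeping", {
  ds <- tiny_dataset(separation = 1, n_per_class = 10, seed = 7)
  iv <- run_independent_validation(ds, "dnn", seed = 4,
                                   config = model_config("dnn", hidden = c(32),
                                                         seed = 4))
  expect_equal(iv$n_init + iv$n_val + iv$n_stream, ds$n)
  expect_equal(sum(iv$trace$n_items), iv$n_stream)
  expect_true(all(iv$trace$n_items[-nrow(iv$trace)] == 16))
  expect_equal(iv$posterior$alpha, 1 + sum(iv$predictions$correct))
  expect_equal(iv$posterior$beta, 1 + sum(!iv$predictions$correct))
  # trace posterior is the running cumulative update
  expect_equal(iv$trace$alpha, 1 + cumsum(iv$trace$n_correct))
  expect_error(
    run_independent_validation(tiny_dataset(n_per_class = 2, seed = 31), "dnn"),
    "too small")
})

test_that("per-class IV mode maintains six recall posteriors", {
  ds <- tiny_dataset(separation = 1, n_per_class = 10, seed = 7)
  iv <- run_independent_validation(ds, "dnn", seed = 4, mode = "balanced",
                                   config = model_config("dnn", hidden = c(32),
                                                         seed = 4))
  expect_length(iv$class_posteriors, 6)
  per_class_n <- vapply(iv$class_posteriors,
                        function(p) p$alpha + p$beta - 2, numeric(1))
  expect_equal(sum(per_class_n), iv$n_stream)
})
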