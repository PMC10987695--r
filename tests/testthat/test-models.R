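test_that("untrained models emit valid seeded softmax probabilities", {
  cfg <- model_config("dnn", hidden = c(16), seed = 4)
  m1 <- build_model(cfg, feature_dim = 20)
  m2 <- build_model(cfg, feature_dim = 20)
  expect_identical(m1$params, m2$params)
  X <- matrix(stats::rnorm(5 * 20), 5)
  p <- predict_proba(m1, X)
  expect_equal(dim(p), c(5L, 6L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_identical(predict_proba(m1, X), predict_proba(m1, X))
})

test_that("the hybrid design demands both input branches", {
  cfg <- model_config("cdnn", hidden = c(8), seed = 1)
  m <- build_model(cfg, feature_dim = 10, image_shape = c(32, 48, 3))
  X <- matrix(stats::rnorm(30), 3)
  expect_error(predict_proba(m, list(features = X)), "needs image")
  expect_error(predict_proba(m, list(images = array(0, c(3, 32, 48, 3)))),
               "needs feature")
  expect_error(build_model(model_config("cdnn")), "feature_dim")
})

test_that("training is seeded-reproducible and checkpoints the best epoch", {
  ds <- tiny_dataset(separation = 1)
  split <- stratified_split(ds$labels, c(0.7, 0.3), 5)
  run <- function() {
    m <- build_model(model_config("dnn", seed = 5),
                     feature_dim = ncol(ds$features))
    train_model(m, dataset_inputs(ds, split[[1]]), ds$labels[split[[1]]],
                dataset_inputs(ds, split[[2]]), ds$labels[split[[2]]])
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_lte(nrow(m1$history), 4)  # at most four epochs
  # returned weights correspond to the best recorded validation accuracy
  best <- max(m1$history$val_accuracy)
  pv <- predict(m1, dataset_inputs(ds, split[[2]]))
  expect_equal(mean(as.character(pv) == as.character(ds$labels[split[[2]]])),
               best)
})

test_that("all designs beat chance on separable data; none learns shuffled labels", {
  ds <- tiny_dataset(separation = 1)
  split <- stratified_split(ds$labels, c(0.7, 0.3), 5)
  m <- build_model(model_config("dnn", seed = 5),
                   feature_dim = ncol(ds$features))
  m <- train_model(m, dataset_inputs(ds, split[[1]]), ds$labels[split[[1]]],
                   dataset_inputs(ds, split[[2]]), ds$labels[split[[2]]])
  expect_gt(utils::tail(m$history$val_bac, 1), 1 / 3)

  # shuffled labels: validation accuracy posterior consistent with chance
  set.seed(99)
  shuffled <- sample(ds$labels)
  m0 <- build_model(model_config("dnn", seed = 5),
                    feature_dim = ncol(ds$features))
  m0 <- train_model(m0, dataset_inputs(ds, split[[1]]), shuffled[split[[1]]],
                    dataset_inputs(ds, split[[2]]), shuffled[split[[2]]])
  pred <- predict(m0, dataset_inputs(ds, split[[2]]))
  correct <- sum(as.character(pred) == as.character(shuffled[split[[2]]]))
  post <- beta_update(beta_posterior(1, 1), correct,
                      length(split[[2]]) - correct)
  expect_lt(abs(beta_map(post) - 1 / 6), 3 * beta_sd(post))
})

test_that("convolutional and hybrid designs train on pooled spectrogram inputs", {
  ds <- tiny_dataset(separation = 1, design = "cdnn", n_per_class = 6)
  split <- stratified_split(ds$labels, c(0.7, 0.3), 3)
  m <- build_model(model_config("cdnn", hidden = c(32), seed = 2),
                   feature_dim = ncol(ds$features))
  m <- train_model(m, dataset_inputs(ds, split[[1]]), ds$labels[split[[1]]],
                   dataset_inputs(ds, split[[2]]), ds$labels[split[[2]]],
                   epochs = 2)
  p <- predict_proba(m, dataset_inputs(ds, split[[2]]))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)

  mc <- build_model(model_config("cnn", hidden = c(32), seed = 2))
  expect_match(mc$design, "cnn")
  pc <- predict_proba(mc, list(images = ds$images[1:3, , , , drop = FALSE]))
  expect_equal(rowSums(pc), rep(1, 3), tolerance = 1e-6)
})
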