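# A probability matrix from a vector of scores for class 1, spread evenly
# over the remaining classes.
score_to_probs <- function(s) {
  p1 <- stats::plogis(s)
  cbind(p1, matrix((1 - p1) / 5, length(s), 5))
}

test_that("saliency maps require a convolutional branch and average correctly", {
  cfg <- model_config("cnn", hidden = c(16), seed = 2)
  m <- build_model(cfg, image_shape = c(32, 48, 3))
  img <- array(stats::runif(32 * 48 * 3), c(1, 32, 48, 3))
  s1 <- average_saliency(m, img)
  expect_equal(dim(s1), c(32L, 48L))
  expect_true(all(s1 >= 0))
  expect_equal(attr(s1, "n_images"), 1L)
  # duplicated image list: mean is unchanged
  img3 <- array(0, c(3, 32, 48, 3))
  for (i in 1:3) img3[i, , , ] <- img[1, , , ]
  s3 <- average_saliency(m, img3)
  expect_equal(unclass(s3), unclass(s1), tolerance = 1e-12,
               ignore_attr = TRUE)

  dm <- build_model(model_config("dnn", seed = 1), feature_dim = 5)
  expect_error(average_saliency(dm, img), "convolutional")
})

test_that("a model with a zeroed head has zero saliency everywhere", {
  cfg <- model_config("cnn", hidden = c(16), seed = 2)
  m <- build_model(cfg, image_shape = c(32, 48, 3))
  m$params$out_W[] <- 0
  m$params$out_b[] <- 0
  s <- average_saliency(m, array(stats::runif(32 * 48 * 3), c(1, 32, 48, 3)))
  expect_equal(max(abs(s)), 0)
})

test_that("attribution concentrates on the planted time segment", {
  # additive model: class-1 score depends only on segment 7's features
  n_seg <- 48
  d <- n_seg * 2
  groups <- rep(seq_len(n_seg), each = 2)
  planted <- which(groups == 7)
  f <- function(X) score_to_probs(3 * rowMeans(X[, planted, drop = FALSE]))
  set.seed(5)
  X <- matrix(stats::rnorm(4 * d, sd = 2), 4)
  shap <- shap_time_segments(f, X, n_segments = n_seg, draws = 8, seed = 2,
                             time_groups = groups)
  expect_equal(nrow(shap), 48)
  mass <- abs(shap$value)
  expect_gte(mass[7] / sum(mass), 0.9)
})

test_that("two-coalition estimates match the exact two-player Shapley value", {
  groups <- c(1L, 2L)
  v_fun <- function(X) score_to_probs(1.5 * X[, 1] + 0.8 * X[, 2] +
                                        0.6 * X[, 1] * X[, 2])
  x <- matrix(c(1.2, -0.7), 1)
  base <- c(0, 0)  # enforced by centering the background below
  X_bg <- rbind(x, -x)  # mean is exactly zero
  shap <- shap_time_segments(v_fun, X_bg, n_segments = 2, draws = 10, seed = 1,
                             time_groups = groups, duration = 1.5)
  # exact 2-player Shapley from the four coalition values, per input,
  # averaged over the two inputs (mirroring the estimator's averaging)
  exact_for <- function(xi) {
    v <- function(mask) {
      z <- xi; z[!mask] <- 0
      v_fun(matrix(z, 1))[, which.max(v_fun(matrix(xi, 1)))]
    }
    v00 <- v(c(FALSE, FALSE)); v10 <- v(c(TRUE, FALSE))
    v01 <- v(c(FALSE, TRUE)); v11 <- v(c(TRUE, TRUE))
    c(0.5 * (v10 - v00) + 0.5 * (v11 - v01),
      0.5 * (v01 - v00) + 0.5 * (v11 - v10))
  }
  exact <- (exact_for(c(1.2, -0.7)) + exact_for(c(-1.2, 0.7))) / 2
  expect_lt(max(abs(shap$value - exact)), 0.01)
  expect_true(attr(shap, "exact"))
})

test_that("attributions satisfy efficiency and vanish for a null model", {
  groups <- rep(1:4, each = 3)
  f <- function(X) score_to_probs(rowSums(X))
  set.seed(3)
  X <- matrix(stats::rnorm(3 * 12), 3)
  shap <- shap_time_segments(f, X, n_segments = 4, draws = 24, seed = 9,
                             time_groups = groups)
  expect_equal(sum(shap$value), attr(shap, "full") - attr(shap, "baseline"),
               tolerance = 1e-10)
  null_f <- function(X) matrix(1 / 6, nrow(X), 6)
  shap0 <- shap_time_segments(null_f, X, n_segments = 4, draws = 6, seed = 1,
                              time_groups = groups)
  expect_equal(max(abs(shap0$value)), 0)
})

test_that("segment boundaries cover the window with the remainder at the end", {
  b <- segment_boundaries(1.5, 16000, 48)
  expect_equal(nrow(b), 48)
  expect_equal(b$start_s[1], 0)
  expect_equal(b$end_s[48], 1.5)
  expect_true(all(b$start_s[-1] == b$end_s[-48]))
  # feature time map: localized blocks mapped, bin-wise summaries unmapped
  g <- feature_time_groups(frame_spec(), 48)
  expect_length(g, 14244)
  expect_true(all(is.na(g[5105:13304])))   # the four bin-wise blocks
  expect_true(all(!is.na(g[1:1200])))
  expect_true(all(g[!is.na(g)] >= 1 & g[!is.na(g)] <= 48))
})
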