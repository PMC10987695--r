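#' Hyperparameter search space
#'
#' Declared default space for all three designs: depth 1-4, layer widths
#' 32-512 (log2 grid), dropout \[0, 0.5\], learning rate log-uniform
#' \[1e-4, 1e-2\], batch size one of 16/32/64.
#'
#' @param depth Integer range `c(min, max)` of hidden-layer count.
#' @param width Integer range of hidden-layer width (rounded to powers of 2).
#' @param dropout Continuous range.
#' @param learning_rate Continuous range, searched on the log scale.
#' @param batch_size Discrete choices.
#' @return A `hyper_space` list.
#' @export
hyper_space <- function(depth = c(1L, 4L), width = c(32L, 512L),
                        dropout = c(0, 0.5), learning_rate = c(1e-4, 1e-2),
                        batch_size = c(16L, 32L, 64L)) {
  stopifnot(depth[1] >= 1, depth[2] >= depth[1], width[2] >= width[1],
            dropout[2] >= dropout[1], learning_rate[1] > 0,
            learning_rate[2] >= learning_rate[1], length(batch_size) >= 1)
  structure(list(depth = depth, width = width, dropout = dropout,
                 learning_rate = learning_rate, batch_size = batch_size),
            class = "hyper_space")
}

# Decode a unit-cube point into a model configuration.
decode_config <- function(u, space, design, seed) {
  depth <- round(space$depth[1] + u[1] * (space$depth[2] - space$depth[1]))
  lw <- log2(space$width)
  width <- 2^round(lw[1] + u[2] * (lw[2] - lw[1]))
  dropout <- space$dropout[1] + u[3] * (space$dropout[2] - space$dropout[1])
  llr <- log(space$learning_rate)
  lr <- exp(llr[1] + u[4] * (llr[2] - llr[1]))
  bs <- space$batch_size[pmin(length(space$batch_size),
                              1 + floor(u[5] * length(space$batch_size)))]
  model_config(design = design, hidden = rep(as.integer(width), depth),
               dropout = dropout, learning_rate = lr, batch_size = bs,
               seed = seed)
}

# Gaussian-process surrogate: RBF kernel with a small nugget; the
# lengthscale is chosen by maximizing the log marginal likelihood over a
# one-dimensional grid (signal variance profiled from the standardized y).
gp_fit <- function(U, y) {
  y_mu <- mean(y); y_sd <- max(stats::sd(y), 1e-8)
  ys <- (y - y_mu) / y_sd
  D2 <- as.matrix(stats::dist(U))^2
  best <- NULL
  for (ell in c(0.1, 0.2, 0.4, 0.8, 1.6)) {
    K <- exp(-0.5 * D2 / ell^2) + diag(1e-4, nrow(U))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, ell = ell, chol = ch, alpha = alpha)
    }
  }
  c(best, list(U = U, y_mu = y_mu, y_sd = y_sd))
}

gp_predict <- function(fit, Unew) {
  cross <- Unew %*% t(fit$U)
  K_star <- exp(-0.5 * (outer(rowSums(Unew^2), rowSums(fit$U^2), `+`) -
                          2 * cross) / fit$ell^2)
  mu <- as.vector(K_star %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(K_star))
  var <- pmax(1 + 1e-4 - colSums(v^2), 1e-10)
  list(mean = mu * fit$y_sd + fit$y_mu, sd = sqrt(var) * fit$y_sd)
}

expected_improvement <- function(mu, sd, best) {
  z <- (mu - best) / sd
  (mu - best) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Bayesian hyperparameter optimization with a Gaussian process
#'
#' Sequential model-based search: an initial Latin-hypercube design is
#' evaluated, a Gaussian-process surrogate (RBF kernel, marginal-likelihood
#' lengthscale selection) is fit to the observed configuration scores, and
#' each subsequent configuration maximizes expected improvement over seeded
#' random candidates. The best observed configuration is returned.
#' Deterministic given `seed`.
#'
#' @param design Classifier design to tune.
#' @param dataset An `svc_dataset` used for short training evaluations
#'   (80/20 split, 2 epochs), or `NULL` when `objective` is supplied.
#' @param space A [hyper_space()].
#' @param budget Total number of configuration evaluations (>= 5).
#' @param seed Integer seed.
#' @param objective Optional function `f(u)` on the unit cube to maximize in
#'   place of the training evaluation (used for validating the optimizer
#'   against known functions).
#' @param dims Dimensionality of the search cube when `objective` is given.
#' @return The best [model_config()] found (or, with `objective`, a list
#'   with `u` and `value`), with the evaluation trace attached as attribute
#'   `trace`.
#' @export
tune_model <- function(design = "dnn", dataset = NULL, space = hyper_space(),
                       budget = 10, seed = 1, objective = NULL, dims = 5L) {
  if (budget < 5) stop("tuning budget must be at least 5", call. = FALSE)
  custom_obj <- !is.null(objective)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  if (is.null(objective)) {
    stopifnot(inherits(dataset, "svc_dataset"))
    dims <- 5L
    split <- stratified_split(dataset$labels, c(0.8, 0.2), seed)
    objective <- function(u) {
      cfg <- decode_config(u, space, design, seed)
      cfg$max_epochs <- 2L
      model <- build_model(cfg,
                           feature_dim = if (!is.null(dataset$features))
                             ncol(dataset$features) else NULL,
                           image_shape = c(240, 320, 3))
      model <- train_model(model, dataset_inputs(dataset, split[[1]]),
                           dataset$labels[split[[1]]],
                           dataset_inputs(dataset, split[[2]]),
                           dataset$labels[split[[2]]])
      utils::tail(model$history$val_accuracy, 1)
    }
  }

  n_init <- min(5L, budget)
  U <- lhs::randomLHS(n_init, dims)
  y <- apply(U, 1, objective)
  while (nrow(U) < budget) {
    fit <- gp_fit(U, y)
    cand <- matrix(stats::runif(256 * dims), ncol = dims)
    pr <- gp_predict(fit, cand)
    ei <- expected_improvement(pr$mean, pr$sd, max(y))
    u_next <- cand[which.max(ei), , drop = FALSE]
    U <- rbind(U, u_next)
    y <- c(y, objective(as.vector(u_next)))
  }
  best_i <- which.max(y)
  trace <- tibble::tibble(eval = seq_along(y), value = y)
  if (custom_obj) {
    out <- list(u = U[best_i, ], value = y[best_i])
  } else {
    out <- decode_config(U[best_i, ], space, design, seed)
  }
  attr(out, "trace") <- trace
  out
}
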