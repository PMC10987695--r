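#' Classifier configuration
#'
#' Hyperparameters shared by the three designs. Training runs for at most
#' `max_epochs` epochs (default 4) with the validation split scored after
#' every epoch; the epoch state with the best validation accuracy is kept,
#' which is how overfitting is held in check.
#'
#' @param design One of `"dnn"` (feedforward over the feature battery),
#'   `"cnn"` (convolutional over spectrogram images) or `"cdnn"` (both
#'   branches concatenated before a softmax head).
#' @param hidden Integer vector of hidden-layer widths for the feedforward
#'   stack (its length is the depth).
#' @param dropout Dropout fraction in \[0, 1).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(design = c("dnn", "cnn", "cdnn"), hidden = c(128, 64),
                         dropout = 0.1, learning_rate = 1e-3, batch_size = 32,
                         max_epochs = 4, seed = 1) {
  design <- match.arg(design)
  stopifnot(length(hidden) >= 1, all(hidden >= 1),
            dropout >= 0, dropout < 1, learning_rate > 0,
            batch_size >= 1, max_epochs >= 1)
  structure(list(design = design, hidden = as.integer(hidden),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "model_config")
}

CNN_FILTERS <- c(16L, 32L, 64L)

#' Build an untrained classifier
#'
#' Initializes seeded He-normal weights for the requested design. The `dnn`
#' is a feedforward stack over the feature vector; the `cnn` applies a fixed
#' 4x4 average-pool stem to the 240x320x3 image followed by three 3x3
#' convolution + 2x2 max-pool stages (16/32/64 filters) and a dense head;
#' the `cdnn` runs both branches and concatenates their representations
#' before a feedforward head. All designs end in a 6-way softmax.
#'
#' @param config A [model_config()].
#' @param feature_dim Feature-vector length (required for dnn/cdnn).
#' @param image_shape Image dimensions `c(height, width, channels)` (required
#'   for cnn/cdnn).
#' @return An `svc_model` object (untrained).
#' @export
build_model <- function(config, feature_dim = NULL, image_shape = c(240, 320, 3)) {
  stopifnot(inherits(config, "model_config"))
  design <- config$design
  if (design %in% c("dnn", "cdnn") && is.null(feature_dim)) {
    stop("design '", design, "' requires feature_dim", call. = FALSE)
  }
  if (design %in% c("cnn", "cdnn") &&
      (length(image_shape) != 3 || any(image_shape[1:2] %% 16 != 0))) {
    stop("design '", design, "' requires image_shape with height/width ",
         "divisible by 16", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  params <- list()
  if (design %in% c("dnn", "cdnn")) {
    d_prev <- feature_dim
    for (i in seq_along(config$hidden)) {
      params[[paste0("f_W", i)]] <- he_init(d_prev, config$hidden[i])
      params[[paste0("f_b", i)]] <- numeric(config$hidden[i])
      d_prev <- config$hidden[i]
    }
    feat_rep <- d_prev
  }
  if (design %in% c("cnn", "cdnn")) {
    stem_dim <- c(image_shape[1] %/% 4L, image_shape[2] %/% 4L, image_shape[3])
    cin <- stem_dim[3]
    h <- stem_dim[1]; w <- stem_dim[2]
    for (i in seq_along(CNN_FILTERS)) {
      params[[paste0("c_W", i)]] <- he_init(9 * cin, CNN_FILTERS[i])
      params[[paste0("c_b", i)]] <- numeric(CNN_FILTERS[i])
      cin <- CNN_FILTERS[i]
      h <- h %/% 2L; w <- w %/% 2L
    }
    flat_dim <- h * w * cin
    img_rep <- config$hidden[length(config$hidden)]
    params$c_Wd <- he_init(flat_dim, img_rep)
    params$c_bd <- numeric(img_rep)
  }
  if (design == "dnn") {
    params$out_W <- he_init(feat_rep, 6L)
    params$out_b <- numeric(6L)
  } else if (design == "cnn") {
    params$out_W <- he_init(img_rep, 6L)
    params$out_b <- numeric(6L)
  } else {
    head_in <- feat_rep + img_rep
    params$h_W <- he_init(head_in, 64L)
    params$h_b <- numeric(64L)
    params$out_W <- he_init(64L, 6L)
    params$out_b <- numeric(6L)
  }

  structure(list(design = design, config = config, params = params,
                 feature_dim = feature_dim, image_shape = image_shape,
                 norm = NULL, classes = emotion_levels(),
                 opt = adam_init(params), epoch_counter = 0L,
                 history = NULL, trained = FALSE),
            class = "svc_model")
}

#' @export
print.svc_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<svc_model: %s, %s parameters, %s>\n", x$design,
              format(n_par, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

# inputs: list(features = n x d matrix or NULL, images = (n,h,w,3) array or
# pre-pooled (n,h/4,w/4,3), or NULL). Returns probs and (if train) caches.
model_forward <- function(model, inputs, train = FALSE) {
  p <- model$params
  cfg <- model$config
  cache <- list()

  feat_rep <- NULL
  if (model$design %in% c("dnn", "cdnn")) {
    X <- inputs$features
    if (is.null(X)) stop("design '", model$design, "' needs feature inputs",
                         call. = FALSE)
    X <- standardize_features(model, X)
    A <- X
    cache$dense <- list()
    for (i in seq_along(cfg$hidden)) {
      dc <- dense_forward(A, p[[paste0("f_W", i)]], p[[paste0("f_b", i)]])
      rc <- relu_forward(dc$out)
      oc <- if (train) dropout_forward(rc$out, cfg$dropout) else
        list(out = rc$out, mask = NULL)
      cache$dense[[i]] <- list(dense = dc, relu = rc, drop = oc)
      A <- oc$out
    }
    feat_rep <- A
  }

  img_rep <- NULL
  if (model$design %in% c("cnn", "cdnn")) {
    imgs <- inputs$images
    if (is.null(imgs)) stop("design '", model$design, "' needs image inputs",
                            call. = FALSE)
    d <- dim(imgs)
    if (length(d) != 4) stop("images must be a (n, h, w, 3) array", call. = FALSE)
    if (d[2] == model$image_shape[1]) {
      cache$full_dim <- d
      x <- avgpool4_forward(imgs)
    } else if (d[2] == model$image_shape[1] %/% 4L) {
      x <- imgs  # already stem-pooled
    } else {
      stop("image height ", d[2], " does not match model signature ",
           model$image_shape[1], call. = FALSE)
    }
    cache$conv <- list()
    for (i in seq_along(CNN_FILTERS)) {
      cf <- conv3_forward(x, p[[paste0("c_W", i)]], p[[paste0("c_b", i)]])
      rf <- relu_forward(cf$out)
      pf <- maxpool2_forward(rf$out)
      cache$conv[[i]] <- list(conv = cf, relu = rf, pool = pf)
      x <- pf$out
    }
    cache$flat_dim <- dim(x)
    Xf <- matrix(x, dim(x)[1])
    dcd <- dense_forward(Xf, p$c_Wd, p$c_bd)
    rcd <- relu_forward(dcd$out)
    cache$img_dense <- list(dense = dcd, relu = rcd)
    img_rep <- rcd$out
  }

  if (model$design == "dnn") {
    rep <- feat_rep
  } else if (model$design == "cnn") {
    rep <- img_rep
  } else {
    rep <- cbind(feat_rep, img_rep)
    hc <- dense_forward(rep, p$h_W, p$h_b)
    hr <- relu_forward(hc$out)
    cache$head <- list(dense = hc, relu = hr)
    rep <- hr$out
  }
  cache$feat_rep_dim <- if (!is.null(feat_rep)) ncol(feat_rep) else 0L
  oc <- dense_forward(rep, p$out_W, p$out_b)
  probs <- softmax_rows(oc$out)
  cache$out <- oc
  list(probs = probs, cache = cache)
}

model_backward <- function(model, cache, dlogits, want_dx = FALSE) {
  p <- model$params
  grads <- list()
  ob <- dense_backward(cache$out, dlogits, p$out_W)
  grads$out_W <- ob$dW; grads$out_b <- ob$db
  drep <- ob$dX

  if (model$design == "cdnn") {
    dh <- relu_backward(cache$head$relu, drep)
    hb <- dense_backward(cache$head$dense, dh, p$h_W)
    grads$h_W <- hb$dW; grads$h_b <- hb$db
    nf <- cache$feat_rep_dim
    dfeat_rep <- hb$dX[, seq_len(nf), drop = FALSE]
    dimg_rep <- hb$dX[, (nf + 1):ncol(hb$dX), drop = FALSE]
  } else if (model$design == "dnn") {
    dfeat_rep <- drep; dimg_rep <- NULL
  } else {
    dfeat_rep <- NULL; dimg_rep <- drep
  }

  dX_feat <- NULL
  if (!is.null(dfeat_rep)) {
    dA <- dfeat_rep
    for (i in rev(seq_along(cache$dense))) {
      lc <- cache$dense[[i]]
      dA <- dropout_backward(lc$drop, dA)
      dA <- relu_backward(lc$relu, dA)
      db <- dense_backward(lc$dense, dA, p[[paste0("f_W", i)]])
      grads[[paste0("f_W", i)]] <- db$dW
      grads[[paste0("f_b", i)]] <- db$db
      dA <- db$dX
    }
    dX_feat <- dA
  }

  dX_img <- NULL
  if (!is.null(dimg_rep)) {
    dr <- relu_backward(cache$img_dense$relu, dimg_rep)
    db <- dense_backward(cache$img_dense$dense, dr, p$c_Wd)
    grads$c_Wd <- db$dW; grads$c_bd <- db$db
    dx <- array(db$dX, cache$flat_dim)
    for (i in rev(seq_along(cache$conv))) {
      lc <- cache$conv[[i]]
      dx <- maxpool2_backward(lc$pool, dx)
      dx <- relu_backward(lc$relu, dx)
      cb <- conv3_backward(lc$conv, dx, p[[paste0("c_W", i)]])
      grads[[paste0("c_W", i)]] <- cb$dW
      grads[[paste0("c_b", i)]] <- cb$db
      dx <- cb$dX
    }
    if (want_dx && !is.null(cache$full_dim)) {
      dx <- avgpool4_backward(dx, cache$full_dim)
    }
    dX_img <- dx
  }
  list(grads = grads, dX_feat = dX_feat, dX_img = dX_img)
}

# Z-score by the training-set statistics, clipped to +/-10: feature blocks
# have wildly different scales and near-constant columns on a small training
# partition would otherwise blow up on later (stream) data.
standardize_features <- function(model, X) {
  if (is.null(model$norm)) return(X)
  Z <- sweep(sweep(X, 2, model$norm$mean, `-`), 2, model$norm$sd, `/`)
  pmin(pmax(Z, -10), 10)
}

# ---- training ---------------------------------------------------------------

coerce_inputs <- function(model, inputs) {
  if (is.list(inputs) && !is.data.frame(inputs) &&
      any(c("features", "images") %in% names(inputs))) {
    return(inputs)
  }
  if (is.matrix(inputs)) return(list(features = inputs))
  if (is.array(inputs) && length(dim(inputs)) == 4) return(list(images = inputs))
  stop("inputs must be a feature matrix, image array, or list(features=, images=)",
       call. = FALSE)
}

subset_inputs <- function(inputs, idx) {
  list(features = if (!is.null(inputs$features))
    inputs$features[idx, , drop = FALSE] else NULL,
    images = if (!is.null(inputs$images))
      inputs$images[idx, , , , drop = FALSE] else NULL)
}

n_inputs <- function(inputs) {
  if (!is.null(inputs$features)) nrow(inputs$features) else dim(inputs$images)[1]
}

#' Train a classifier with per-epoch validation checkpointing
#'
#' Runs minibatch Adam for up to `epochs` epochs (default: the config's
#' `max_epochs`). After every epoch the validation split is predicted and
#' plain accuracy plus balanced accuracy are recorded; the returned model
#' carries the weights of the epoch with the best validation accuracy.
#' Fully deterministic given the config seed.
#'
#' @param model An `svc_model` from [build_model()].
#' @param inputs Training inputs: feature matrix, image array, or
#'   `list(features =, images =)`.
#' @param labels Training emotion labels (length n).
#' @param val_inputs,val_labels Disjoint validation split (required unless
#'   `epochs = 1` incremental updates are being made).
#' @param epochs Number of epochs to run.
#' @param reset_optimizer If `FALSE`, continue from the model's stored Adam
#'   state (used for incremental updating during Independent Validation).
#' @return The trained `svc_model`, with a `history` tibble of per-epoch
#'   validation metrics.
#' @export
train_model <- function(model, inputs, labels, val_inputs = NULL,
                        val_labels = NULL, epochs = model$config$max_epochs,
                        reset_optimizer = TRUE) {
  stopifnot(inherits(model, "svc_model"))
  inputs <- coerce_inputs(model, inputs)
  n <- n_inputs(inputs)
  if (n == 0) stop("empty training partition", call. = FALSE)
  y <- as.integer(as_emotion(labels))
  if (length(y) != n) stop("labels length does not match inputs", call. = FALSE)
  has_val <- !is.null(val_inputs)
  if (has_val) {
    val_inputs <- coerce_inputs(model, val_inputs)
    if (n_inputs(val_inputs) == 0) stop("empty validation partition", call. = FALSE)
    yv <- as.integer(as_emotion(val_labels))
  }

  if (is.null(model$norm) && !is.null(inputs$features)) {
    mu <- colMeans(inputs$features)
    sd <- apply(inputs$features, 2, stats::sd)
    model$norm <- list(mean = mu, sd = pmax(sd, 1e-8))
  }
  if (reset_optimizer) {
    model$opt <- adam_init(model$params)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)

  Y <- matrix(0, n, 6L)
  Y[cbind(seq_len(n), y)] <- 1
  bs <- model$config$batch_size
  best <- list(acc = -Inf, params = model$params, opt = model$opt)
  hist <- list()

  for (ep in seq_len(epochs)) {
    model$epoch_counter <- model$epoch_counter + 1L
    set.seed((model$config$seed + 104729 * model$epoch_counter) %% 2147483647)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      bi <- subset_inputs(inputs, idx)
      fw <- model_forward(model, bi, train = TRUE)
      losses <- c(losses, cross_entropy(fw$probs, y[idx]))
      dlogits <- (fw$probs - Y[idx, , drop = FALSE]) / length(idx)
      bw <- model_backward(model, fw$cache, dlogits)
      upd <- adam_step(model$params, bw$grads, model$opt,
                       model$config$learning_rate)
      model$params <- upd$params
      model$opt <- upd$state
    }
    if (has_val) {
      pv <- predict_proba(model, val_inputs)
      pred <- max.col(pv, ties.method = "first")
      acc <- mean(pred == yv)
      cm <- table(factor(yv, levels = 1:6), factor(pred, levels = 1:6))
      present <- rowSums(cm) > 0
      bac <- mean(diag(cm)[present] / rowSums(cm)[present])
      hist[[ep]] <- tibble::tibble(epoch = model$epoch_counter,
                                   train_loss = mean(losses),
                                   val_accuracy = acc, val_bac = bac)
      if (acc > best$acc) {
        best <- list(acc = acc, params = model$params, opt = model$opt)
      }
    }
  }
  if (has_val && length(hist) > 0) {
    model$params <- best$params
    model$opt <- best$opt
    model$history <- dplyr::bind_rows(model$history, dplyr::bind_rows(hist))
  }
  model$trained <- TRUE
  model
}

#' Predict class probabilities
#'
#' @param model A trained `svc_model`.
#' @param inputs Feature matrix, image array, or `list(features =, images =)`
#'   matching the model's signature.
#' @return An `n x 6` matrix of probabilities (columns named by emotion);
#'   rows sum to 1. The predicted label is the argmax, ties broken toward
#'   the lowest class index.
#' @export
predict_proba <- function(model, inputs) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.svc_model <- function(model, inputs) {
  inputs <- coerce_inputs(model, inputs)
  probs <- model_forward(model, inputs, train = FALSE)$probs
  colnames(probs) <- model$classes
  probs
}

#' @export
predict.svc_model <- function(object, inputs, ...) {
  probs <- predict_proba(object, inputs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}
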