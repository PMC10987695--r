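# Batch-first neural layer primitives used by the three classifier designs.
# All arrays are (n, height, width, channels); dense activations are (n, d).
# Each forward returns the output plus whatever its backward pass needs.

dense_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, `+`), X = X)
}

dense_backward <- function(cache, dout, W) {
  list(dX = dout %*% t(W), dW = t(cache$X) %*% dout, db = colSums(dout))
}

relu_forward <- function(X) list(out = pmax(X, 0), mask = X > 0)
relu_backward <- function(cache, dout) dout * cache$mask

dropout_forward <- function(X, p) {
  if (p <= 0) return(list(out = X, mask = NULL, p = p))
  mask <- array(stats::runif(length(X)) >= p, dim = dim(X)) / (1 - p)
  list(out = X * mask, mask = mask, p = p)
}
dropout_backward <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# 3x3 same-padding convolution via im2col. W is (9 * c_in) x c_out with
# columns of the patch matrix ordered offset-major then input channel.
conv3_im2col <- function(x) {
  d <- dim(x)
  n <- d[1]; h <- d[2]; w <- d[3]; cin <- d[4]
  xp <- array(0, c(n, h + 2, w + 2, cin))
  xp[, 2:(h + 1), 2:(w + 1), ] <- x
  cols <- matrix(0, n * h * w, 9 * cin)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    slice <- xp[, di + seq_len(h), dj + seq_len(w), , drop = FALSE]
    cols[, ((k - 1) * cin + 1):(k * cin)] <- matrix(slice, n * h * w, cin)
  }
  cols
}

conv3_forward <- function(x, W, b) {
  d <- dim(x)
  cols <- conv3_im2col(x)
  out_mat <- sweep(cols %*% W, 2, b, `+`)
  list(out = array(out_mat, c(d[1], d[2], d[3], ncol(W))),
       cols = cols, in_dim = d)
}

conv3_backward <- function(cache, dout, W) {
  d <- cache$in_dim
  n <- d[1]; h <- d[2]; w <- d[3]; cin <- d[4]
  cout <- dim(dout)[4]
  dmat <- matrix(dout, n * h * w, cout)
  dW <- t(cache$cols) %*% dmat
  db <- colSums(dmat)
  dcols <- dmat %*% t(W)
  dxp <- array(0, c(n, h + 2, w + 2, cin))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    block <- array(dcols[, ((k - 1) * cin + 1):(k * cin)], c(n, h, w, cin))
    dxp[, di + seq_len(h), dj + seq_len(w), ] <-
      dxp[, di + seq_len(h), dj + seq_len(w), , drop = FALSE] + block
  }
  list(dX = dxp[, 2:(h + 1), 2:(w + 1), , drop = FALSE], dW = dW, db = db)
}

# 2x2 max pooling, stride 2; odd trailing rows/columns are cropped.
# Ties route the gradient to the first maximal position (fixed scan order).
maxpool2_forward <- function(x) {
  d <- dim(x)
  h2 <- d[2] %/% 2L; w2 <- d[3] %/% 2L
  ri <- seq_len(2 * h2); ci <- seq_len(2 * w2)
  x <- x[, ri, ci, , drop = FALSE]
  v <- list(x[, seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE],
            x[, seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE],
            x[, seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE],
            x[, seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE])
  out <- pmax(v[[1]], v[[2]], v[[3]], v[[4]])
  masks <- vector("list", 4)
  assigned <- array(FALSE, dim(out))
  for (k in 1:4) {
    mk <- (v[[k]] == out) & !assigned
    assigned <- assigned | mk
    masks[[k]] <- mk
  }
  list(out = out, masks = masks, in_dim = d, h2 = h2, w2 = w2)
}

maxpool2_backward <- function(cache, dout) {
  d <- cache$in_dim
  h2 <- cache$h2; w2 <- cache$w2
  dx <- array(0, d)
  rows <- list(seq(1, 2 * h2, 2), seq(2, 2 * h2, 2),
               seq(1, 2 * h2, 2), seq(2, 2 * h2, 2))
  cols <- list(seq(1, 2 * w2, 2), seq(1, 2 * w2, 2),
               seq(2, 2 * w2, 2), seq(2, 2 * w2, 2))
  for (k in 1:4) {
    dx[, rows[[k]], cols[[k]], ] <- dx[, rows[[k]], cols[[k]], , drop = FALSE] +
      dout * cache$masks[[k]]
  }
  dx
}

# Fixed 4x4 average-pooling stem that reduces 240x320x3 images to 60x80x3
# before the learned convolution stages.
avgpool4_forward <- function(x) {
  d <- dim(x)
  h4 <- d[2] %/% 4L; w4 <- d[3] %/% 4L
  out <- array(0, c(d[1], h4, w4, d[4]))
  for (di in 0:3) for (dj in 0:3) {
    out <- out + x[, seq(1 + di, 4 * h4, 4), seq(1 + dj, 4 * w4, 4), ,
                   drop = FALSE] / 16
  }
  out
}

avgpool4_backward <- function(dout, full_dim) {
  dx <- array(0, full_dim)
  h4 <- full_dim[2] %/% 4L; w4 <- full_dim[3] %/% 4L
  for (di in 0:3) for (dj in 0:3) {
    dx[, seq(1 + di, 4 * h4, 4), seq(1 + dj, 4 * w4, 4), ] <- dout / 16
  }
  dx
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

cross_entropy <- function(probs, y_int) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y_int)], 1e-12)))
}

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
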