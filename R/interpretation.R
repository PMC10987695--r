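#' Average gradient saliency over spectrograms
#'
#' For each image the saliency is the absolute gradient of the predicted
#' class's probability with respect to the input pixels, summed over the
#' three color channels; the output is the pixel-wise mean over all images.
#' Only designs with a convolutional branch (cnn, cdnn) support saliency.
#'
#' @param model A trained `svc_model` of design cnn or cdnn.
#' @param images Full-resolution image array `(n, 240, 320, 3)` in \[0, 1\]
#'   (e.g. stacked [render_spectrogram()] outputs / 255), or a list of
#'   `spectrogram` objects.
#' @param features Feature matrix (required for cdnn).
#' @return An `svc_saliency` object: 240x320 non-negative matrix with the
#'   image count as attribute `n_images`.
#' @export
average_saliency <- function(model, images, features = NULL) {
  stopifnot(inherits(model, "svc_model"))
  if (model$design == "dnn") {
    stop("saliency maps require a convolutional branch (design cnn or cdnn)",
         call. = FALSE)
  }
  if (is.list(images) && !is.array(images)) {
    images <- abind_images(images)
  }
  d <- dim(images)
  stopifnot(length(d) == 4)
  n <- d[1]
  acc <- matrix(0, d[2], d[3])
  for (i in seq_len(n)) {
    inputs <- list(images = images[i, , , , drop = FALSE],
                   features = if (!is.null(features))
                     features[i, , drop = FALSE] else NULL)
    fw <- model_forward(model, inputs, train = FALSE)
    probs <- fw$probs
    cls <- max.col(probs, ties.method = "first")
    # d p_c / d logits = p_c * (1[j = c] - p_j)
    onehot <- matrix(0, 1, 6); onehot[1, cls] <- 1
    dlogits <- probs[1, cls] * (onehot - probs)
    bw <- model_backward(model, fw$cache, dlogits, want_dx = TRUE)
    g <- bw$dX_img
    acc <- acc + apply(abs(g[1, , , , drop = FALSE]), c(2, 3), sum)
  }
  structure(acc / n, class = "svc_saliency", n_images = n)
}

abind_images <- function(lst) {
  stopifnot(length(lst) >= 1)
  d <- dim(lst[[1]])
  out <- array(0, c(length(lst), d))
  for (i in seq_along(lst)) {
    x <- lst[[i]]
    out[i, , , ] <- if (inherits(x, "spectrogram")) unclass(x) / 255 else x
  }
  out
}

#' @export
print.svc_saliency <- function(x, ...) {
  cat(sprintf("<svc_saliency: %d x %d, mean over %d image(s)>\n",
              nrow(x), ncol(x), attr(x, "n_images")))
  invisible(x)
}

# Map every feature column to one of n_segments time intervals spanning
# [0, duration]. Bin-wise summary blocks (variance/mean per frequency bin)
# aggregate over the whole segment and carry no time localization; they are
# returned NA and are never masked.
feature_time_groups <- function(spec = frame_spec(), n_segments = 48) {
  sizes <- feature_block_sizes(spec)
  duration <- spec$target_len / spec$rate
  seg_of_time <- function(t) {
    pmin(n_segments, pmax(1, floor(t / duration * n_segments) + 1))
  }
  groups <- integer(0)
  nf <- spec$n_frames
  frame_times <- (seq_len(nf) - 1) * spec$hop / spec$rate
  win_times <- (seq_len(spec$target_len %/% VAR_WIN) - 0.5) * VAR_WIN / spec$rate
  for (b in names(sizes)) {
    g <- switch(b,
      raw_variance = seg_of_time(win_times),
      hpss_variance = rep(seg_of_time(win_times), 2),
      flatness = , centroid = , f0 = , bandwidth = , zcr = , rms =
        seg_of_time(frame_times),
      voiced = , rolloff = rep(seg_of_time(frame_times), 2),
      contrast = rep(seg_of_time(frame_times), 4),
      tonnetz = rep(seg_of_time(frame_times), 6),
      chroma = rep(seg_of_time(frame_times), 12),
      mfcc = rep(seg_of_time(frame_times), 20),
      pitch_track = , pitch_mag = , magnitude = , phase =
        rep(NA_integer_, sizes[[b]])
    )
    groups <- c(groups, g)
  }
  stopifnot(length(groups) == sum(sizes))
  groups
}

# Time-segment boundaries in seconds: computed in samples, with the
# remainder of target_len / n_segments assigned to the final segment.
segment_boundaries <- function(duration, rate, n_segments) {
  target <- round(duration * rate)
  base <- target %/% n_segments
  starts <- (seq_len(n_segments) - 1) * base
  ends <- starts + base
  ends[n_segments] <- target
  tibble::tibble(segment = seq_len(n_segments),
                 start_s = starts / rate, end_s = ends / rate)
}

#' Shapley attribution of prediction probability to time segments
#'
#' Groups the model's inputs into `n_segments` time-interval coalitions and
#' estimates each coalition's Shapley value for the predicted-class
#' probability by permutation sampling. Masked coalitions are replaced with
#' the dataset mean (the baseline is the fully masked input). When
#' `factorial(n_segments)` does not exceed `draws` the permutations are
#' enumerated and the attribution is exact. Attributions are averaged over
#' inputs; per input, the attributions sum exactly to the prediction minus
#' the baseline prediction.
#'
#' For feature-battery inputs the grouping follows each feature's time
#' localization (bin-wise summary features carry none and are never masked);
#' for image inputs the image columns are grouped into `n_segments` column
#' bands.
#'
#' @param model A trained `svc_model`, or a plain function mapping an input
#'   batch to an `n x 6` probability matrix (useful for validating the
#'   estimator against models with known exact Shapley values).
#' @param inputs Feature matrix or image array (matching the model).
#' @param n_segments Number of time coalitions (default 48).
#' @param draws Number of sampled permutations per input (default 64).
#' @param seed Integer seed.
#' @param time_groups Optional explicit column-to-segment map (integer
#'   vector, NA = never masked) overriding the derived one.
#' @param duration,rate Segment geometry used to derive boundaries and the
#'   feature time map.
#' @return An `svc_shap` tibble: `segment`, `start_s`, `end_s`, `value`,
#'   with the per-input baseline/prediction recorded as attributes.
#' @export
shap_time_segments <- function(model, inputs, n_segments = 48, draws = 64,
                               seed = 1, time_groups = NULL, duration = 1.5,
                               rate = 16000) {
  stopifnot(n_segments >= 1, draws >= 1)
  is_image <- is.array(inputs) && length(dim(inputs)) == 4
  if (!is_image) inputs <- as.matrix(inputs)
  n <- if (is_image) dim(inputs)[1] else nrow(inputs)
  stopifnot(n >= 1)

  if (is.null(time_groups)) {
    if (is_image) {
      w <- dim(inputs)[3]
      time_groups <- floor((seq_len(w) - 1) / w * n_segments) + 1L
    } else {
      spec <- frame_spec(rate, round(duration * rate))
      time_groups <- if (ncol(inputs) == sum(feature_block_sizes(spec))) {
        feature_time_groups(spec, n_segments)
      } else {
        floor((seq_len(ncol(inputs)) - 1) / ncol(inputs) * n_segments) + 1L
      }
    }
  }

  # dataset-mean baseline
  if (is_image) {
    base_mean <- apply(inputs, c(2, 3, 4), mean)
  } else {
    base_mean <- colMeans(inputs)
  }

  mask_apply <- function(x, masked_segments) {
    if (is_image) {
      cols <- which(time_groups %in% masked_segments)
      if (length(cols) > 0) x[1, , cols, ] <- base_mean[, cols, , drop = FALSE]
      x
    } else {
      cols <- which(time_groups %in% masked_segments)
      if (length(cols) > 0) x[, cols] <- matrix(base_mean[cols], nrow(x),
                                                length(cols), byrow = TRUE)
      x
    }
  }

  predict_fn <- if (is.function(model)) model else
    function(x) predict_proba(model, x)
  value_of <- function(x_masked_batch, cls) {
    predict_fn(x_masked_batch)[, cls]
  }

  enumerate <- factorial(n_segments) <= draws
  perms <- if (enumerate) {
    all_perms(n_segments)
  } else {
    NULL
  }
  n_perm <- if (enumerate) length(perms) else draws

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  phi <- numeric(n_segments)
  baselines <- numeric(n)
  fulls <- numeric(n)
  for (i in seq_len(n)) {
    xi <- if (is_image) inputs[i, , , , drop = FALSE] else inputs[i, , drop = FALSE]
    cls <- max.col(predict_fn(xi), ties.method = "first")[1]
    phi_i <- numeric(n_segments)
    for (p in seq_len(n_perm)) {
      perm <- if (enumerate) perms[[p]] else sample.int(n_segments)
      # build the n_segments + 1 nested coalitions along this permutation
      batch <- vector("list", n_segments + 1)
      for (k in 0:n_segments) {
        masked <- if (k < n_segments) perm[(k + 1):n_segments] else integer(0)
        batch[[k + 1]] <- mask_apply(xi, masked)
      }
      xb <- if (is_image) {
        arr <- array(0, c(n_segments + 1, dim(inputs)[-1]))
        for (k in seq_along(batch)) arr[k, , , ] <- batch[[k]]
        arr
      } else {
        do.call(rbind, batch)
      }
      v <- value_of(xb, cls)
      gains <- diff(v)           # marginal contribution of perm[k] at step k
      phi_i[perm] <- phi_i[perm] + gains
      if (p == 1) {
        baselines[i] <- v[1]
        fulls[i] <- v[n_segments + 1]
      }
    }
    phi <- phi + phi_i / n_perm
  }
  phi <- phi / n

  out <- segment_boundaries(duration, rate, n_segments)
  out$value <- phi
  structure(out, class = c("svc_shap", class(out)),
            baseline = mean(baselines), full = mean(fulls),
            exact = enumerate, draws = n_perm)
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (s in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(s, n, after = pos)
    }
  }
  out
}
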