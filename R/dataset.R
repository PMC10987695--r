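#' Assemble model-ready inputs from a dataset manifest
#'
#' Extracts the feature battery and/or renders spectrogram images for every
#' row of a manifest (in-memory segments from [synth_segments()] or WAV
#' paths), producing the input bundle the classifiers train on. Images are
#' stored stem-pooled (60x80x3) to keep desk-scale memory modest; the full
#' 240x320x3 rendering path is [render_spectrogram()].
#'
#' @param manifest Manifest tibble (optionally with a `segment` list-column).
#' @param design Which classifier design the inputs are for; controls whether
#'   features, images or both are materialized.
#' @param duration Window duration in seconds.
#' @param rate Working sample rate in Hz.
#' @return An `svc_dataset`: list with `features` (n x p matrix or NULL),
#'   `images` (pooled array or NULL), `labels` (factor) and `n`.
#' @export
build_dataset <- function(manifest, design = c("dnn", "cnn", "cdnn"),
                          duration = 1.5, rate = 16000) {
  design <- match.arg(design)
  stopifnot(nrow(manifest) >= 1)
  wspec <- window_spec(duration, rate = rate)
  fspec <- frame_spec(rate, wspec$target_len)
  segs <- if ("segment" %in% names(manifest)) {
    lapply(manifest$segment, fix_window, spec = wspec)
  } else {
    lapply(manifest$path, function(p) fix_window(load_audio(p, rate), wspec))
  }
  features <- NULL
  images <- NULL
  if (design %in% c("dnn", "cdnn")) {
    features <- segments_to_feature_matrix(segs, fspec)
  }
  if (design %in% c("cnn", "cdnn")) {
    images <- avgpool4_forward(segments_to_image_array(segs, fspec))
  }
  structure(list(features = features, images = images,
                 labels = as_emotion(manifest$label), n = length(segs)),
            class = "svc_dataset")
}

#' @export
print.svc_dataset <- function(x, ...) {
  cat(sprintf("<svc_dataset: %d items, %s features, %s images>\n", x$n,
              if (is.null(x$features)) "no" else ncol(x$features),
              if (is.null(x$images)) "no" else
                paste(dim(x$images)[-1], collapse = "x")))
  invisible(x)
}

dataset_inputs <- function(dataset, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(dataset$n)
  list(features = if (!is.null(dataset$features))
    dataset$features[idx, , drop = FALSE] else NULL,
    images = if (!is.null(dataset$images))
      dataset$images[idx, , , , drop = FALSE] else NULL)
}

# Seeded stratified index split: returns a list of index vectors with the
# requested fractions, every class represented in every partition when
# counts permit.
stratified_split <- function(labels, fracs, seed) {
  stopifnot(abs(sum(fracs) - 1) < 1e-9)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  parts <- vector("list", length(fracs))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 0) next
    idx <- sample(idx)
    cuts <- round(cumsum(fracs) * length(idx))
    starts <- c(0L, cuts[-length(cuts)]) + 1L
    for (k in seq_along(fracs)) {
      if (starts[k] <= cuts[k]) {
        parts[[k]] <- c(parts[[k]], idx[starts[k]:cuts[k]])
      }
    }
  }
  lapply(parts, sort)
}

# Seeded stratified fold assignment for k-fold cross-validation.
stratified_folds <- function(labels, k, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 0) next
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
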