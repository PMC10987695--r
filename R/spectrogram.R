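#' Render a fixed-window segment as a 320x240 RGB spectrogram
#'
#' The convolutional branch consumes each segment as an image: a 128-band
#' mel spectrogram (same 2,048/512 frame geometry as the feature battery) is
#' converted to decibels relative to its own maximum, clamped to a -80 dB
#' floor, mapped through the viridis perceptual colormap and bilinearly
#' resampled to 320x240 pixels with no axes, margins or border -- 230,400
#' integer values (320 x 240 x 3). Row 1 is the top of the image and carries
#' the highest frequency. Rendering is deterministic.
#'
#' @param segment A fixed-window [audio_segment()].
#' @param spec A [frame_spec()].
#' @param width,height Output size in pixels.
#' @param floor_db Dynamic-range floor in dB (default -80).
#' @return A `spectrogram` object: integer array `height x width x 3` in
#'   \[0, 255\] with the segment's provenance attached.
#' @export
#' @examples
#' seg <- fix_window(synth_segment("fear", synth_config()), window_spec())
#' dim(render_spectrogram(seg))
render_spectrogram <- function(segment,
                               spec = frame_spec(segment$rate, length(segment$samples)),
                               width = 320, height = 240, floor_db = -80) {
  stopifnot(is_audio_segment(segment))
  S <- stft(segment$samples, spec$n_fft, spec$hop)
  fb <- mel_filterbank(segment$rate, spec$n_fft, n_mels = 128)
  mel <- fb %*% Mod(S)^2
  db <- power_to_db(mel, ref = max(mel))
  db <- pmax(db, floor_db)
  norm <- (db - floor_db) / (-floor_db)   # [0, 1]

  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))  # 3 x 256
  idx <- matrix(pmin(255L, as.integer(floor(norm * 255))) + 1L, nrow(norm))
  small <- array(0, c(nrow(norm), ncol(norm), 3))
  for (ch in 1:3) small[, , ch] <- matrix(pal[ch, idx], nrow(norm))

  # flip so row 1 = highest frequency, then bilinear resize to height x width
  small <- small[nrow(small):1, , , drop = FALSE]
  Wr <- bilinear_weights(nrow(small), height)
  Wc <- bilinear_weights(ncol(small), width)
  px <- array(0L, c(height, width, 3))
  for (ch in 1:3) {
    px[, , ch] <- as.integer(round(Wr %*% small[, , ch] %*% t(Wc)))
  }
  px[px < 0L] <- 0L
  px[px > 255L] <- 255L
  structure(px, class = "spectrogram",
            source = segment$source, label = segment$label)
}

# n_out x n_in bilinear interpolation weight matrix (pixel-center aligned,
# edge-clamped).
bilinear_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  pos <- ((seq_len(n_out) - 0.5) * scale) + 0.5 - 1  # 0-based source coord
  pos <- pmin(pmax(pos, 0), n_in - 1)
  lo <- floor(pos)
  frac <- pos - lo
  hi <- pmin(lo + 1, n_in - 1)
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), lo + 1)] <- W[cbind(seq_len(n_out), lo + 1)] + (1 - frac)
  W[cbind(seq_len(n_out), hi + 1)] <- W[cbind(seq_len(n_out), hi + 1)] + frac
  W
}

#' @export
print.spectrogram <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<spectrogram: %d x %d x %d (%s values)>\n", d[1], d[2], d[3],
              format(prod(d), big.mark = ",")))
  invisible(x)
}

#' Write / read a spectrogram as a lossless 8-bit RGB PNG
#'
#' @param s A `spectrogram` from [render_spectrogram()].
#' @param path PNG path.
#' @return `write_spectrogram_png()`: the path, invisibly.
#'   `read_spectrogram_png()`: a `spectrogram` object; the round trip is
#'   bit-exact.
#' @export
write_spectrogram_png <- function(s, path) {
  stopifnot(inherits(s, "spectrogram"))
  arr <- unclass(s)
  attributes(arr) <- list(dim = dim(s))
  tryCatch(png::writePNG(arr / 255, target = path),
           error = function(e) stop("cannot write PNG to ", path, " (",
                                    conditionMessage(e), ")", call. = FALSE))
  invisible(path)
}

#' @rdname write_spectrogram_png
#' @export
read_spectrogram_png <- function(path) {
  if (!file.exists(path)) stop("PNG not found: ", path, call. = FALSE)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  px <- array(as.integer(round(arr[, , 1:3] * 255)), dim = c(dim(arr)[1:2], 3))
  structure(px, class = "spectrogram", source = path, label = NULL)
}

# Internal: stacked image array (n, height, width, 3) in [0, 1] doubles for
# a list of segments, ready for the convolutional branch.
segments_to_image_array <- function(segments, spec = NULL) {
  stopifnot(length(segments) > 0)
  if (is.null(spec)) {
    s1 <- segments[[1]]
    spec <- frame_spec(s1$rate, length(s1$samples))
  }
  imgs <- lapply(segments, function(s) render_spectrogram(s, spec))
  n <- length(imgs)
  out <- array(0, c(n, dim(imgs[[1]])))
  for (i in seq_len(n)) out[i, , , ] <- imgs[[i]] / 255
  out
}
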