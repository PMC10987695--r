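#' Short-time frame specification
#'
#' Fixes the analysis geometry of the feature battery: a 2,048-sample window
#' hopped by 512 samples over centered frames, which yields
#' `1 + floor(target_len / hop)` frames -- 47 for a 1.5 s segment at
#' 16,000 Hz -- and `n_fft / 2 + 1 = 1,025` frequency bins.
#'
#' @param rate Sample rate in Hz.
#' @param target_len Segment length in samples.
#' @param n_fft Analysis window length in samples.
#' @param hop Hop length in samples.
#' @return A `frame_spec` list with derived `n_frames` and `n_bins`.
#' @export
frame_spec <- function(rate = 16000, target_len = round(1.5 * rate),
                       n_fft = 2048, hop = 512) {
  stopifnot(rate > 0, target_len >= hop, n_fft > 0, hop > 0)
  structure(list(rate = rate, target_len = as.integer(target_len),
                 n_fft = as.integer(n_fft), hop = as.integer(hop),
                 n_frames = n_stft_frames(target_len, hop),
                 n_bins = as.integer(n_fft / 2 + 1)),
            class = "frame_spec")
}

# Width in samples of the non-overlapping variance windows applied to the
# raw signal and the HPSS reconstructions (24,000 / 20 = 1,200 values).
VAR_WIN <- 20L

#' Declared feature block sizes for a segment geometry
#'
#' @param spec A [frame_spec()].
#' @return Named integer vector of block sizes in the declared block order;
#'   sums to 14,244 at the default 1.5 s / 16 kHz geometry.
#' @export
feature_block_sizes <- function(spec = frame_spec()) {
  nf <- spec$n_frames
  nb <- spec$n_bins
  nraw <- spec$target_len %/% VAR_WIN
  c(raw_variance = nraw, hpss_variance = 2L * nraw,
    flatness = nf, centroid = nf, f0 = nf, voiced = 2L * nf,
    rolloff = 2L * nf, bandwidth = nf, zcr = nf, rms = nf,
    contrast = 4L * nf, tonnetz = 6L * nf, chroma = 12L * nf,
    pitch_track = 2L * nb, pitch_mag = 2L * nb,
    magnitude = 2L * nb, phase = 2L * nb, mfcc = 20L * nf)
}

#' Population variance over consecutive non-overlapping windows
#'
#' @param samples Numeric vector whose length is divisible by `win`.
#' @param win Window width in samples.
#' @return `length(samples) / win` population variances.
#' @export
#' @examples
#' windowed_variance(c(0, 1, 0, 1), win = 2)
windowed_variance <- function(samples, win = VAR_WIN) {
  n <- length(samples)
  if (n %% win != 0) {
    stop("sample count (", n, ") is not divisible by the variance window (",
         win, ")", call. = FALSE)
  }
  M <- matrix(samples, nrow = win)
  colMeans(M^2) - colMeans(M)^2
}

# Harmonic-percussive separation by median filtering of the magnitude
# spectrogram (horizontal medians enhance harmonics, vertical medians enhance
# percussive transients), soft power-2 masking, and inverse STFT.
hpss_components <- function(segment, spec = frame_spec(segment$rate, length(segment$samples)),
                            kernel = 31) {
  S <- stft(segment$samples, spec$n_fft, spec$hop)
  mag <- Mod(S)
  H <- median_filter_rows(mag, kernel)
  P <- median_filter_cols(mag, kernel)
  denom <- H^2 + P^2
  denom[denom < 1e-24] <- 1e-24
  mask_h <- H^2 / denom
  mask_p <- P^2 / denom
  n <- length(segment$samples)
  list(harmonic = istft(S * mask_h, spec$n_fft, spec$hop, n),
       percussive = istft(S * mask_p, spec$n_fft, spec$hop, n))
}

#' Windowed variances of the harmonic and percussive components
#'
#' The segment is separated into harmonic and percussive time-domain
#' reconstructions; each is summarized by [windowed_variance()] and the two
#' are concatenated harmonic-first (2,400 values at the default geometry).
#'
#' @param segment A fixed-window [audio_segment()].
#' @param spec A [frame_spec()].
#' @return Numeric vector of `2 * target_len / 20` values.
#' @export
hpss_variance <- function(segment, spec = frame_spec(segment$rate, length(segment$samples))) {
  comp <- hpss_components(segment, spec)
  c(windowed_variance(comp$harmonic), windowed_variance(comp$percussive))
}

#' Framewise scalar descriptors
#'
#' Per short-time frame: spectral flatness, spectral centroid, spectral
#' rolloff at the 0.85 (high) and 0.15 (low) energy fractions concatenated
#' high-first, spectral bandwidth, zero crossing rate and root mean square
#' energy. Each scalar yields `n_frames` values (47 at the default geometry;
#' rolloff 94).
#'
#' @param segment A fixed-window [audio_segment()].
#' @param spec A [frame_spec()].
#' @return Named list of numeric blocks
#'   `{flatness, centroid, rolloff, bandwidth, zcr, rms}`.
#' @export
framewise_scalars <- function(segment, spec = frame_spec(segment$rate, length(segment$samples))) {
  S <- stft(segment$samples, spec$n_fft, spec$hop)
  mag <- Mod(S)
  pow <- mag^2
  freqs <- fft_bin_freqs(spec$rate, spec$n_fft)

  pow_f <- pmax(pow, 1e-10)
  flatness <- exp(colMeans(log(pow_f))) / colMeans(pow_f)

  mag_sum <- colSums(mag)
  safe <- pmax(mag_sum, 1e-12)
  centroid <- colSums(mag * freqs) / safe
  centroid[mag_sum < 1e-12] <- 0

  cum <- apply(mag, 2, cumsum)
  rolloff_at <- function(pct) {
    thresh <- pct * mag_sum
    idx <- vapply(seq_len(ncol(mag)), function(j) {
      if (mag_sum[j] < 1e-12) return(1L)
      which(cum[, j] >= thresh[j])[1]
    }, integer(1))
    out <- freqs[idx]
    out[mag_sum < 1e-12] <- 0
    out
  }
  rolloff <- c(rolloff_at(0.85), rolloff_at(0.15))

  dev2 <- (matrix(freqs, spec$n_bins, spec$n_frames) -
             matrix(centroid, spec$n_bins, spec$n_frames, byrow = TRUE))^2
  bandwidth <- sqrt(colSums(mag * dev2) / safe)
  bandwidth[mag_sum < 1e-12] <- 0

  frames <- time_frames(segment$samples, spec$n_fft, spec$hop)
  sgn <- frames >= 0
  zcr <- colMeans(sgn[-1, , drop = FALSE] != sgn[-nrow(sgn), , drop = FALSE])
  rms <- sqrt(colMeans(frames^2))

  list(flatness = flatness, centroid = centroid, rolloff = rolloff,
       bandwidth = bandwidth, zcr = zcr, rms = rms)
}

#' Framewise fundamental frequency and voicing
#'
#' F0 is estimated per frame from the normalized autocorrelation peak in the
#' 50-600 Hz range with parabolic refinement. The peak height serves as the
#' voicing probability; frames with probability above 0.45 are flagged
#' voiced. Unvoiced frames encode F0 as 0 so the vector stays finite and
#' fixed-length. The voiced block concatenates flags first, probabilities
#' second.
#'
#' @param segment A fixed-window [audio_segment()].
#' @param spec A [frame_spec()].
#' @return Named list with blocks `f0` (`n_frames`) and `voiced`
#'   (`2 * n_frames`).
#' @export
f0_and_voiced <- function(segment, spec = frame_spec(segment$rate, length(segment$samples))) {
  frames <- time_frames(segment$samples, spec$n_fft, spec$hop) * hann_window(spec$n_fft)
  n_fft2 <- 2L * spec$n_fft
  padded <- rbind(frames, matrix(0, spec$n_fft, ncol(frames)))
  spec_full <- stats::mvfft(padded)
  acf <- Re(stats::mvfft(Mod(spec_full)^2, inverse = TRUE)) / n_fft2

  lag_min <- max(2L, floor(spec$rate / 600))
  lag_max <- min(spec$n_fft - 2L, ceiling(spec$rate / 50))
  f0 <- numeric(ncol(frames))
  prob <- numeric(ncol(frames))
  for (j in seq_len(ncol(frames))) {
    a0 <- acf[1, j]
    if (a0 < 1e-10) next
    r <- acf[(lag_min + 1):(lag_max + 1), j] / a0
    k <- which.max(r)
    prob[j] <- min(1, max(0, r[k]))
    lag <- lag_min + k - 1L
    # parabolic interpolation around the peak
    ym <- acf[lag, j] / a0; y0 <- r[k]; yp <- acf[lag + 2, j] / a0
    denom <- ym - 2 * y0 + yp
    shift <- if (abs(denom) > 1e-12) 0.5 * (ym - yp) / denom else 0
    shift <- max(-0.5, min(0.5, shift))
    f0[j] <- spec$rate / (lag + shift)
  }
  flag <- as.numeric(prob > 0.45)
  f0[flag == 0] <- 0
  list(f0 = f0, voiced = c(flag, prob))
}

#' Per-bin variance and mean of a spectral matrix
#'
#' Summarizes a bins-by-frames matrix by the population variance of each
#' frequency bin across frames, followed by the per-bin mean
#' (`2 * n_bins` values, variances first).
#'
#' @param M Numeric matrix with `n_bins` rows.
#' @param n_bins Expected row count (default 1,025).
#' @return Numeric vector `c(variances, means)`.
#' @export
#' @examples
#' binwise_var_mean(matrix(c(1, 2, 3, 2), 2), n_bins = 2)
binwise_var_mean <- function(M, n_bins = 1025L) {
  if (nrow(M) != n_bins) {
    stop("matrix has ", nrow(M), " rows, expected ", n_bins, " frequency bins",
         call. = FALSE)
  }
  mu <- rowMeans(M)
  c(rowMeans(M^2) - mu^2, mu)
}

# Peak-interpolated pitch tracking: each frame's spectral local maxima above
# a relative threshold receive a parabolic-refined frequency and magnitude;
# all other bins are 0. Returns two n_bins x n_frames matrices.
pitch_track_matrices <- function(S_mag, spec, threshold = 0.1) {
  nb <- nrow(S_mag); nf <- ncol(S_mag)
  up <- S_mag[2:(nb - 1), , drop = FALSE] > S_mag[1:(nb - 2), , drop = FALSE]
  down <- S_mag[2:(nb - 1), , drop = FALSE] >= S_mag[3:nb, , drop = FALSE]
  col_max <- apply(S_mag, 2, max)
  above <- S_mag[2:(nb - 1), , drop = FALSE] >=
    matrix(threshold * col_max, nb - 2, nf, byrow = TRUE)
  is_peak <- up & down & above
  pitches <- matrix(0, nb, nf)
  mags <- matrix(0, nb, nf)
  if (any(is_peak)) {
    idx <- which(is_peak, arr.ind = TRUE)
    bins <- idx[, 1] + 1L  # offset back into full bin index
    js <- idx[, 2]
    a <- S_mag[cbind(bins - 1L, js)]
    b <- S_mag[cbind(bins, js)]
    cc <- S_mag[cbind(bins + 1L, js)]
    denom <- a - 2 * b + cc
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * (a - cc) / denom, 0)
    shift <- pmax(-0.5, pmin(0.5, shift))
    pitches[cbind(bins, js)] <- (bins - 1 + shift) * spec$rate / spec$n_fft
    mags[cbind(bins, js)] <- b - 0.25 * (a - cc) * shift
  }
  list(pitches = pitches, mags = mags)
}

# Chroma aggregation matrix (12 x n_bins): each FFT bin's power is assigned
# to the pitch class of its center frequency (A440 reference).
chroma_map <- function(spec) {
  freqs <- fft_bin_freqs(spec$rate, spec$n_fft)
  A <- matrix(0, 12, spec$n_bins)
  nonzero <- which(freqs > 0)
  pc <- (round(12 * log2(freqs[nonzero] / 440) + 69) %% 12) + 1
  A[cbind(pc, nonzero)] <- 1
  A
}

# Six-dimensional tonal centroid (tonnetz) projection of L1-normalized chroma.
tonnetz_transform <- function() {
  n <- 0:11
  rbind(sin(n * 7 * pi / 6), cos(n * 7 * pi / 6),
        sin(n * 3 * pi / 2), cos(n * 3 * pi / 2),
        0.5 * sin(n * 2 * pi / 3), 0.5 * cos(n * 2 * pi / 3))
}

#' Tonal and cepstral feature blocks
#'
#' Spectral contrast over 3 octave sub-bands above 200 Hz plus the base band
#' (4 x n_frames), the six-dimensional tonnetz projection of chroma
#' (6 x n_frames), twelve-class chroma (12 x n_frames) and 20 MFCCs from a
#' 128-band mel spectrogram (20 x n_frames). Matrices are flattened
#' coefficient-major (row-major).
#'
#' @param segment A fixed-window [audio_segment()].
#' @param spec A [frame_spec()].
#' @return Named list of blocks `{contrast, tonnetz, chroma, mfcc}`.
#' @export
tonal_blocks <- function(segment, spec = frame_spec(segment$rate, length(segment$samples))) {
  S <- stft(segment$samples, spec$n_fft, spec$hop)
  mag <- Mod(S)
  pow <- mag^2
  freqs <- fft_bin_freqs(spec$rate, spec$n_fft)

  # spectral contrast: per band, dB difference between the mean of the top
  # and bottom 2% of bin magnitudes (at least one bin each)
  edges <- c(0, 200, 400, 800, spec$rate / 2)
  contrast <- matrix(0, 4, spec$n_frames)
  for (b in seq_len(4)) {
    in_band <- freqs >= edges[b] & (if (b < 4) freqs < edges[b + 1] else freqs <= edges[b + 1])
    sub <- mag[in_band, , drop = FALSE]
    k <- max(1L, floor(0.02 * nrow(sub)))
    sorted <- apply(sub, 2, sort)
    valley <- colMeans(sorted[seq_len(k), , drop = FALSE])
    peak <- colMeans(sorted[(nrow(sorted) - k + 1):nrow(sorted), , drop = FALSE])
    contrast[b, ] <- power_to_db(peak^2) - power_to_db(valley^2)
  }

  A <- chroma_map(spec)
  chroma <- A %*% pow
  cmax <- apply(chroma, 2, max)
  chroma <- sweep(chroma, 2, pmax(cmax, 1e-12), "/")
  chroma[, cmax < 1e-12] <- 0

  l1 <- colSums(chroma)
  chroma_l1 <- sweep(chroma, 2, pmax(l1, 1e-12), "/")
  tonnetz <- tonnetz_transform() %*% chroma_l1

  fb <- mel_filterbank(spec$rate, spec$n_fft, n_mels = 128)
  mel_db <- power_to_db(fb %*% pow)
  mfcc <- dct_matrix(20, 128) %*% mel_db

  flatten <- function(M) as.vector(t(M))
  list(contrast = flatten(contrast), tonnetz = flatten(tonnetz),
       chroma = flatten(chroma), mfcc = flatten(mfcc))
}

#' Extract the full feature battery from one fixed-window segment
#'
#' Assembles all declared blocks in the fixed order
#' `r paste(names(feature_block_sizes()), collapse = ", ")`. At the default
#' 1.5 s / 16 kHz geometry the vector has exactly 14,244 entries. Any
#' non-finite value produced upstream is replaced by 0 before assembly.
#'
#' @param segment A fixed-window [audio_segment()] whose length is divisible
#'   by the 20-sample variance window (call [fix_window()] first).
#' @param spec A [frame_spec()]; defaults to the segment's own geometry.
#' @return Named numeric vector (`block.index` names) with attribute
#'   `blocks`, a tibble of block names, sizes and offsets.
#' @export
#' @examples
#' seg <- fix_window(synth_segment("joy", synth_config(duration = 1.5)),
#'                   window_spec(1.5, rate = 16000))
#' length(extract_feature_vector(seg))
extract_feature_vector <- function(segment,
                                   spec = frame_spec(segment$rate, length(segment$samples))) {
  stopifnot(is_audio_segment(segment))
  n <- length(segment$samples)
  if (n != spec$target_len || n %% VAR_WIN != 0 || n < spec$hop) {
    stop("segment has ", n, " samples but the frame spec expects ",
         spec$target_len, "; run fix_window() before feature extraction",
         call. = FALSE)
  }
  x <- segment$samples

  S <- stft(x, spec$n_fft, spec$hop)
  S_mag <- Mod(S)
  S_phase <- Arg(S)
  pt <- pitch_track_matrices(S_mag, spec)
  fw <- framewise_scalars(segment, spec)
  fv <- f0_and_voiced(segment, spec)
  tb <- tonal_blocks(segment, spec)

  blocks <- list(
    raw_variance = windowed_variance(x),
    hpss_variance = hpss_variance(segment, spec),
    flatness = fw$flatness, centroid = fw$centroid,
    f0 = fv$f0, voiced = fv$voiced,
    rolloff = fw$rolloff, bandwidth = fw$bandwidth,
    zcr = fw$zcr, rms = fw$rms,
    contrast = tb$contrast, tonnetz = tb$tonnetz, chroma = tb$chroma,
    pitch_track = binwise_var_mean(pt$pitches, spec$n_bins),
    pitch_mag = binwise_var_mean(pt$mags, spec$n_bins),
    magnitude = binwise_var_mean(S_mag, spec$n_bins),
    phase = binwise_var_mean(S_phase, spec$n_bins),
    mfcc = tb$mfcc
  )

  sizes <- feature_block_sizes(spec)
  got <- vapply(blocks, length, integer(1))
  if (!identical(unname(got[names(sizes)]), unname(as.integer(sizes)))) {
    stop("internal block-size mismatch: ",
         paste(names(sizes)[got[names(sizes)] != sizes], collapse = ", "),
         call. = FALSE)
  }
  out <- unlist(blocks, use.names = FALSE)
  out[!is.finite(out)] <- 0
  names(out) <- unlist(lapply(names(sizes), function(b) {
    paste0(b, ".", seq_len(sizes[[b]]))
  }), use.names = FALSE)
  attr(out, "blocks") <- tibble::tibble(
    block = names(sizes), size = as.integer(sizes),
    start = cumsum(c(1L, as.integer(sizes)))[seq_along(sizes)],
    end = cumsum(as.integer(sizes))
  )
  out
}

# Internal: feature matrix (n x p) for a list of fixed-window segments.
segments_to_feature_matrix <- function(segments, spec = NULL) {
  stopifnot(length(segments) > 0)
  if (is.null(spec)) {
    s1 <- segments[[1]]
    spec <- frame_spec(s1$rate, length(s1$samples))
  }
  rows <- lapply(segments, extract_feature_vector, spec = spec)
  M <- do.call(rbind, lapply(rows, unname))
  colnames(M) <- names(rows[[1]])
  M
}

#' Feature table for a dataset manifest
#'
#' Extracts the feature battery for every manifest row, in manifest order.
#' The manifest may carry in-memory segments (a `segment` list-column, as
#' produced by [synth_segments()]) or `path`s to WAV files, which are loaded
#' at `rate` and forced to the fixed window first. Per-file failures are
#' collected and reported together; no partial table is returned.
#'
#' @param manifest Manifest tibble.
#' @param duration Window duration in seconds.
#' @param rate Working sample rate in Hz.
#' @return A tibble: `label` plus one `block.index` column per feature.
#' @export
feature_matrix <- function(manifest, duration = 1.5, rate = 16000) {
  stopifnot(nrow(manifest) >= 1)
  wspec <- window_spec(duration, rate = rate)
  get_segment <- function(i) {
    seg <- if ("segment" %in% names(manifest)) {
      manifest$segment[[i]]
    } else {
      load_audio(manifest$path[i], target_rate = rate)
    }
    fix_window(seg, wspec)
  }
  results <- lapply(seq_len(nrow(manifest)), function(i) {
    tryCatch(list(ok = TRUE, segment = get_segment(i)),
             error = function(e) list(ok = FALSE, msg = conditionMessage(e),
                                      path = manifest$path[i]))
  })
  failed <- results[!vapply(results, `[[`, logical(1), "ok")]
  if (length(failed) > 0) {
    stop("feature extraction failed for ", length(failed), " file(s):\n",
         paste(vapply(failed, function(f) paste0("  ", f$path, ": ", f$msg),
                      character(1)), collapse = "\n"), call. = FALSE)
  }
  segs <- lapply(results, `[[`, "segment")
  fspec <- frame_spec(rate, wspec$target_len)
  M <- segments_to_feature_matrix(segs, fspec)
  out <- tibble::as_tibble(as.data.frame(M, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(label = manifest$label), out)
}

#' @rdname feature_matrix
#' @param features Feature tibble from [feature_matrix()].
#' @param path CSV path.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
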