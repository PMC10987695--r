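# Short-time Fourier analysis internals shared by the feature battery and the
# spectrogram renderer. Conventions: periodic Hann window, centered frames
# with reflection padding, n_frames = 1 + floor(n_samples / hop).

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

reflect_pad <- function(x, pad) {
  n <- length(x)
  if (pad >= n) {
    # short signals: reflect repeatedly
    while (pad >= n) {
      x <- reflect_pad(x, n - 1)
      pad <- pad - (n - 1)
      n <- length(x)
    }
    if (pad > 0) x <- reflect_pad(x, pad)
    return(x)
  }
  c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
}

n_stft_frames <- function(n_samples, hop = 512) 1L + n_samples %/% as.integer(hop)

# Matrix of centered time-domain frames (n_fft x n_frames), unwindowed.
time_frames <- function(x, n_fft = 2048, hop = 512) {
  n <- length(x)
  xp <- reflect_pad(x, n_fft %/% 2)
  n_frames <- n_stft_frames(n, hop)
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(n_fft), starts, `+`)
  matrix(xp[idx], nrow = n_fft)
}

# Complex STFT, (n_fft/2 + 1) x n_frames.
stft <- function(x, n_fft = 2048, hop = 512) {
  frames <- time_frames(x, n_fft, hop) * hann_window(n_fft)
  full <- stats::mvfft(frames)
  full[seq_len(n_fft / 2 + 1), , drop = FALSE]
}

# Inverse STFT by windowed overlap-add with squared-window normalization;
# returns exactly `n_out` samples (the center-padding is removed).
istft <- function(S, n_fft = 2048, hop = 512, n_out) {
  n_bins <- nrow(S)
  stopifnot(n_bins == n_fft / 2 + 1)
  full <- rbind(S, Conj(S[(n_bins - 1):2, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  w <- hann_window(n_fft)
  frames <- frames * w
  n_frames <- ncol(frames)
  total <- n_fft + (n_frames - 1L) * hop
  y <- numeric(total)
  wsum <- numeric(total)
  w2 <- w^2
  for (k in seq_len(n_frames)) {
    pos <- (k - 1L) * hop
    idx <- (pos + 1):(pos + n_fft)
    y[idx] <- y[idx] + frames[, k]
    wsum[idx] <- wsum[idx] + w2
  }
  y <- y / pmax(wsum, 1e-12)
  pad <- n_fft %/% 2
  y[(pad + 1):(pad + n_out)]
}

# FFT bin center frequencies in Hz for the one-sided spectrum.
fft_bin_freqs <- function(rate, n_fft = 2048) {
  (0:(n_fft / 2)) * rate / n_fft
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank, n_mels x (n_fft/2 + 1).
mel_filterbank <- function(rate, n_fft = 2048, n_mels = 128, fmin = 0,
                           fmax = rate / 2) {
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  freqs <- fft_bin_freqs(rate, n_fft)
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freqs - lo) / max(ctr - lo, 1e-12)
    down <- (hi - freqs) / max(hi - ctr, 1e-12)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix, n_out x n_in (MFCC lifting).
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  n <- seq_len(n_in) - 1
  M <- sqrt(2 / n_in) * cos(outer(k, (2 * n + 1) * pi / (2 * n_in)))
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

power_to_db <- function(p, amin = 1e-10, ref = 1) {
  10 * log10(pmax(p, amin)) - 10 * log10(max(ref, amin))
}

# Running median per row / per column with kernel clipped at the edges
# (median filtering for harmonic-percussive separation). The row filter is
# vectorized: all row-medians of each sliding window are taken at once by
# radix-ordering within rows.
median_filter_rows <- function(M, k) {
  n <- nrow(M); nc <- ncol(M)
  if (nc < 3 || k < 3) return(M)
  h <- (min(k, nc) - 1) %/% 2
  out <- matrix(0, n, nc)
  for (j in seq_len(nc)) {
    idx <- max(1, j - h):min(nc, j + h)
    W <- M[, idx, drop = FALSE]
    w <- length(idx)
    o <- order(rep(seq_len(n), w), W)  # sort within rows
    S <- matrix(W[o], n, w, byrow = TRUE)
    out[, j] <- if (w %% 2 == 1) S[, (w + 1) %/% 2] else
      (S[, w %/% 2] + S[, w %/% 2 + 1]) / 2
  }
  out
}

median_filter_cols <- function(M, k) {
  k <- min(k, if (nrow(M) %% 2 == 1) nrow(M) else nrow(M) - 1)
  if (k < 3) return(M)
  apply(M, 2, function(cc) stats::runmed(cc, k, endrule = "median"))
}
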