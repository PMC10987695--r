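test_that("windowed variance matches hand-computed oracles", {
  expect_equal(windowed_variance(c(0, 1, 0, 1), win = 2), c(0.25, 0.25))
  expect_equal(windowed_variance(rep(3, 40), win = 20), c(0, 0))
  expect_length(windowed_variance(numeric(24000)), 1200)
  expect_error(windowed_variance(numeric(30), win = 20), "not divisible")
})

test_that("bin-wise variance/mean summarization matches hand computation", {
  M <- matrix(c(1, 2, 3, 2), 2)  # rows: (1,3), (2,2)
  expect_equal(binwise_var_mean(M, n_bins = 2), c(1, 0, 2, 2))
  K <- matrix(5, 4, 3)
  expect_equal(binwise_var_mean(K, n_bins = 4), c(rep(0, 4), rep(5, 4)))
  expect_error(binwise_var_mean(M, n_bins = 3), "expected 3")
})

test_that("block-size ledger sums to 14,244 at the default geometry", {
  sizes <- feature_block_sizes(frame_spec())
  expect_equal(sum(sizes), 14244L)
  expect_equal(unname(sizes[c("raw_variance", "hpss_variance", "voiced",
                              "rolloff", "contrast", "tonnetz", "chroma",
                              "mfcc")]),
               c(1200L, 2400L, 94L, 94L, 188L, 282L, 564L, 940L))
  expect_equal(unname(sizes[c("pitch_track", "pitch_mag", "magnitude",
                              "phase")]), rep(2050L, 4))
  expect_true(all(sizes[c("flatness", "centroid", "f0", "bandwidth",
                          "zcr", "rms")] == 47L))
})

test_that("frame-count law reproduces 47 frames and scales with duration", {
  expect_equal(frame_spec(16000, 24000)$n_frames, 47L)
  expect_equal(frame_spec(16000, 48000)$n_frames, 94L)
  expect_equal(frame_spec(16000, 80000)$n_frames, 157L)
  s3 <- frame_spec(16000, 48000)
  sizes3 <- feature_block_sizes(s3)
  expect_equal(unname(sizes3["raw_variance"]), 2400L)
  expect_equal(unname(sizes3["mfcc"]), 20L * 94L)
})

test_that("the full battery extracts 14,244 finite, named, deterministic entries", {
  seg <- full_segment("anger")
  fv <- extract_feature_vector(seg)
  expect_length(fv, 14244)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv)[1], "raw_variance.1")
  expect_identical(names(fv)[14244], "mfcc.940")
  blocks <- attr(fv, "blocks")
  expect_equal(sum(blocks$size), 14244L)
  fv2 <- extract_feature_vector(full_segment("anger"))
  expect_identical(unname(fv), unname(fv2))
  expect_error(extract_feature_vector(audio_segment(numeric(1000), 16000),
                                      frame_spec()), "fix_window")
})

test_that("silence yields a well-defined all-finite vector", {
  fv <- extract_feature_vector(silence_segment())
  expect_true(all(is.finite(fv)))
  blocks <- attr(fv, "blocks")
  pick <- function(b) fv[blocks$start[blocks$block == b]:blocks$end[blocks$block == b]]
  expect_true(all(pick("f0") == 0))
  expect_true(all(pick("voiced")[1:47] == 0))
  expect_true(all(pick("rms") == 0))
  mfcc <- matrix(pick("mfcc"), 20, 47, byrow = TRUE)
  expect_true(all(apply(mfcc, 1, stats::var) == 0))
})

test_that("a pure tone puts the spectral centroid at its frequency", {
  fw <- framewise_scalars(sine_segment(440))
  bin_width <- 16000 / 2048
  expect_true(all(abs(fw$centroid[5:43] - 440) < bin_width))
  expect_length(fw$rolloff, 94)
  # high rolloff >= low rolloff frame by frame
  expect_true(all(fw$rolloff[1:47] >= fw$rolloff[48:94]))
})

test_that("F0 tracking recovers the fundamental of a harmonic stack", {
  fv <- f0_and_voiced(harmonic_segment(200))
  expect_true(all(fv$f0[5:43] > 190 & fv$f0[5:43] < 210))
  expect_true(all(fv$voiced[5:43] == 1))
  sil <- f0_and_voiced(silence_segment())
  expect_true(all(sil$f0 == 0))
  expect_true(all(sil$voiced[1:47] == 0))
})

test_that("a stationary tone is attributed to the harmonic HPSS component", {
  hv <- hpss_variance(sine_segment(440))
  expect_length(hv, 2400)
  harm <- sum(hv[1:1200]); perc <- sum(hv[1201:2400])
  expect_lt(perc / (harm + perc), 0.1)
  expect_equal(hpss_variance(silence_segment()), numeric(2400))
})

test_that("white noise spreads chroma mass nearly uniformly", {
  set.seed(4)
  wn <- audio_segment(stats::rnorm(24000) * 0.1, 16000)
  tb <- tonal_blocks(wn)
  ch <- matrix(tb$chroma, 12, 47, byrow = TRUE)
  rm_ <- rowMeans(ch)
  expect_lt(max(rm_) / min(rm_), 2)
  expect_length(tb$contrast, 188)
  expect_length(tb$tonnetz, 282)
  expect_length(tb$mfcc, 940)
})

test_that("amplitude scaling leaves zcr and chroma shape invariant, scales rms", {
  seg <- full_segment("joy")
  seg2 <- audio_segment(seg$samples * 0.5, seg$rate)  # halve to stay in [-1,1]
  a <- framewise_scalars(seg); b <- framewise_scalars(seg2)
  expect_equal(a$zcr, b$zcr)
  expect_equal(b$rms, a$rms * 0.5, tolerance = 1e-10)
  ca <- matrix(tonal_blocks(seg)$chroma, 12, 47, byrow = TRUE)
  cb <- matrix(tonal_blocks(seg2)$chroma, 12, 47, byrow = TRUE)
  expect_equal(ca, cb, tolerance = 1e-8)
})

test_that("feature_matrix produces one named row per manifest entry", {
  man <- synth_segments(synth_config(n_per_class = 1, duration = 0.5, seed = 9))
  ft <- feature_matrix(man, duration = 0.5)
  spec <- frame_spec(16000, 8000)
  expect_equal(dim(ft), c(6L, sum(feature_block_sizes(spec)) + 1L))
  expect_identical(ft$label, man$label)
  ft2 <- feature_matrix(man, duration = 0.5)
  expect_identical(ft, ft2)
})
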