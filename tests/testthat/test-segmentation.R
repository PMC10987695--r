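test_that("fix_window trims symmetrically with the declared tie-break", {
  spec <- window_spec(1.5, rate = 16000)
  x <- seq_len(48000) / 48000
  out <- fix_window(audio_segment(x, 16000), spec)
  expect_identical(out$samples, x[12001:36000])

  odd <- fix_window(audio_segment(seq_len(24001), 16000), spec)
  expect_identical(odd$samples, as.numeric(seq_len(24000)))  # drop 0 start, 1 end

  same <- audio_segment(x[1:24000], 16000)
  expect_identical(fix_window(same, spec)$samples, same$samples)
})

test_that("fix_window pads symmetrically with silence", {
  spec <- window_spec(1.5, rate = 16000)
  x <- stats::rnorm(16000)
  out <- fix_window(audio_segment(x, 16000), spec)
  expect_length(out$samples, 24000)
  expect_identical(out$samples[1:4000], numeric(4000))
  expect_identical(out$samples[20001:24000], numeric(4000))
  expect_identical(out$samples[4001:20000], x)

  # odd deficit: extra zero at the start
  out2 <- fix_window(audio_segment(x[1:15999], 16000), spec)
  expect_identical(out2$samples[1:4001], numeric(4001))
  expect_identical(out2$samples[20001:24000], numeric(4000))
})

test_that("fix_window is idempotent and conserves energy as declared", {
  spec <- window_spec(1.5, rate = 16000)
  for (n in c(10000, 24000, 30001)) {
    seg <- audio_segment(stats::rnorm(n), 16000)
    once <- fix_window(seg, spec)
    twice <- fix_window(once, spec)
    expect_identical(once$samples, twice$samples)
    if (n >= 24000) {
      expect_lte(sum(once$samples^2), sum(seg$samples^2))
    } else {
      expect_equal(sum(once$samples^2), sum(seg$samples^2))
    }
  }
  expect_error(fix_window(audio_segment(numeric(0), 16000)), "non-empty")
})

test_that("stream_windows covers the stream with the declared offsets", {
  spec <- window_spec(1.5, stride = 1.5, rate = 16000)
  x <- stats::rnorm(72000)  # 4.5 s
  win <- stream_windows(audio_segment(x, 16000), spec)
  expect_equal(win$offset, c(0, 1.5, 3.0))
  # non-overlapping exact multiple: concatenation reconstructs bit-exactly
  expect_identical(unlist(lapply(win$segment, `[[`, "samples")), x)

  one <- stream_windows(audio_segment(x[1:24000], 16000), spec)
  expect_equal(nrow(one), 1)
  expect_identical(one$segment[[1]]$samples, x[1:24000])

  spec2 <- window_spec(1.5, stride = 0.5, rate = 16000)
  win2 <- stream_windows(audio_segment(stats::rnorm(64000), 16000), spec2)
  expect_equal(win2$offset, seq(0, 3.5, by = 0.5))
  expect_true(all(vapply(win2$segment, length, integer(1)) == 24000))
})
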