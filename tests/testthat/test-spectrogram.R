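test_that("rendered spectrograms have exactly 230,400 values in [0, 255]", {
  sp <- render_spectrogram(full_segment("fear"))
  expect_equal(dim(sp), c(240L, 320L, 3L))
  expect_equal(length(sp), 230400L)
  expect_true(all(sp >= 0 & sp <= 255))
  expect_true(all(sp == as.integer(sp)))
})

test_that("silence renders to a spatially constant image", {
  sp <- render_spectrogram(silence_segment())
  for (ch in 1:3) expect_equal(stats::var(as.vector(sp[, , ch])), 0)
})

test_that("a pure tone renders as one dominant horizontal band", {
  sp <- render_spectrogram(fix_window(sine_segment(440), window_spec()))
  lum <- sp[, , 1] * 0.299 + sp[, , 2] * 0.587 + sp[, , 3] * 0.114
  maxrow <- apply(lum, 2, which.max)
  expect_gte(mean(abs(maxrow - stats::median(maxrow)) <= 8), 0.9)
})

test_that("rendering is deterministic and PNG round trips bit-exactly", {
  seg <- full_segment("joy")
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_spectrogram_png(render_spectrogram(seg), p1)
  write_spectrogram_png(render_spectrogram(seg), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_spectrogram_png(p1)
  expect_identical(unclass(back)[, , ],
                   array(as.integer(render_spectrogram(seg)), c(240, 320, 3))[, , ])
  expect_error(write_spectrogram_png(render_spectrogram(seg),
                                     "no/such/dir/out.png"), "cannot write")
  expect_error(read_spectrogram_png("absent.png"), "not found")
})
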