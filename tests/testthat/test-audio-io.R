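write_stereo_wav <- function(left, right, rate, path) {
  # test-only helper: interleaved 16-bit stereo PCM
  ints <- as.integer(round(pmin(1, pmax(-1, as.vector(rbind(left, right)))) * 32767))
  con <- file(path, "wb"); on.exit(close(con))
  data_size <- length(ints) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
}

test_that("WAV round trip is lossless up to 16-bit quantization", {
  path <- withr::local_tempfile(fileext = ".wav")
  set.seed(1)
  x <- stats::runif(4000, -0.99, 0.99)
  write_wav(x, 16000, path)
  seg <- load_audio(path, target_rate = 16000)
  expect_equal(seg$rate, 16000)
  expect_length(seg$samples, 4000)
  expect_lt(max(abs(seg$samples - x)), 2^-15 + 1e-9)
})

test_that("loading resamples and downmixes to the working rate", {
  path <- withr::local_tempfile(fileext = ".wav")
  x <- sin(2 * pi * 440 * (0:47999) / 48000)
  write_wav(x, 48000, path)
  seg <- load_audio(path, target_rate = 16000)
  expect_lte(abs(length(seg$samples) - 16000), 1)
  expect_true(all(abs(seg$samples) <= 1))

  stereo <- withr::local_tempfile(fileext = ".wav")
  write_stereo_wav(rep(0.5, 800), rep(-0.5, 800), 16000, stereo)
  seg2 <- load_audio(stereo, target_rate = 16000)
  expect_length(seg2$samples, 800)
  expect_lt(max(abs(seg2$samples)), 1e-4)  # channels average to ~0
})

test_that("unreadable audio raises labeled I/O errors", {
  expect_error(load_audio("no/such/file.wav"), "not found")
  empty <- withr::local_tempfile(fileext = ".wav")
  file.create(empty)
  expect_error(load_audio(empty), "WAV")
})

test_that("RAVDESS filename parsing maps codes and applies exclusions", {
  p <- parse_ravdess_name("03-01-05-01-01-01-12.wav")
  expect_equal(p$label, "anger")
  expect_equal(p$speaker, "12")
  expect_equal(parse_ravdess_name("03-01-02-01-01-01-01.wav")$label, "excluded")
  expect_equal(parse_ravdess_name("03-01-08-01-01-01-01.wav")$label, "excluded")
  expect_equal(parse_ravdess_name("03-01-01-01-01-01-05.wav")$label, "neutral")
  expect_error(parse_ravdess_name("foo.wav"), "malformed")
})

test_that("Emo-DB filename parsing maps letters and excludes boredom", {
  p <- parse_emodb_name("03a01Wa.wav")
  expect_equal(p$label, "anger")
  expect_equal(p$speaker, "03")
  expect_equal(parse_emodb_name("16b10Lb.wav")$label, "excluded")
  expect_equal(parse_emodb_name("08a02Nc.wav")$label, "neutral")
  expect_error(parse_emodb_name("03a01Xa.wav"), "unknown Emo-DB emotion")
  expect_error(parse_emodb_name("bogus.wav"), "malformed")
})

test_that("manifest validation rejects duplicates and bad labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- tibble::tibble(path = c("a.wav", "b.wav"), label = c("joy", "anger"),
                      speaker = "s01", language = "synthetic",
                      corpus = "synthetic")
  write_manifest(m, path)
  expect_equal(nrow(read_manifest(path)), 2)
  bad <- m; bad$path <- c("a.wav", "a.wav")
  write_manifest(bad, path)
  expect_error(read_manifest(path), "unique")
})
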