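#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 16-bit PCM, the format every corpus used here
#' ships in and the format [write_wav()] produces. Multi-channel data is
#' returned as a channel-by-sample matrix; amplitudes are scaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric matrix, channels x n) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  size <- file.info(path)$size
  if (is.na(size) || size < 44) {
    stop("not a readable WAV file (too short): ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    chunk_size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", chunk_size)
      fmt <- list(
        format = readBin(body[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", chunk_size)
    } else {
      # skip unknown chunk (word-aligned)
      invisible(readBin(con, "raw", chunk_size + chunk_size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("WAV file missing fmt/data chunk: ", path, call. = FALSE)
  }
  if (fmt$format != 1L || fmt$bits != 16L) {
    stop("unsupported WAV encoding in ", path,
         " (only 16-bit PCM is supported; got format ", fmt$format,
         ", ", fmt$bits, " bits)", call. = FALSE)
  }
  ints <- readBin(data_raw, "integer", n = length(data_raw) / 2, size = 2,
                  endian = "little", signed = TRUE)
  if (length(ints) == 0) stop("WAV file contains no samples: ", path, call. = FALSE)
  x <- ints / 32768
  n_ch <- fmt$channels
  samples <- matrix(x, nrow = n_ch)
  list(samples = samples, rate = fmt$rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Amplitudes are clipped to \[-1, 1\] before quantization.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sample rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(is.numeric(samples), length(samples) >= 1, rate > 0)
  x <- pmin(1, pmax(-1, samples))
  ints <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  data_size <- length(ints) * 2L
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open WAV for writing: ", path, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")     # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

#' Load an audio file as a mono segment at a target rate
#'
#' Stereo inputs are averaged to mono; any input rate is resampled to
#' `target_rate` (polyphase resampling via [signal::resample()]), so all
#' downstream processing runs at a single configured rate.
#'
#' @param path Path to a WAV file.
#' @param target_rate Working sample rate in Hz (default 16000).
#' @param label Optional emotion label to attach.
#' @return An [audio_segment()].
#' @export
load_audio <- function(path, target_rate = 16000, label = NULL) {
  wav <- read_wav(path)
  x <- if (nrow(wav$samples) > 1) colMeans(wav$samples) else as.numeric(wav$samples)
  if (wav$rate != target_rate) {
    g <- gcd_int(as.integer(target_rate), as.integer(wav$rate))
    x <- signal::resample(x, p = target_rate / g, q = wav$rate / g)
    target_n <- round(length(wav$samples[1, ]) * target_rate / wav$rate)
    if (length(x) > target_n) x <- x[seq_len(target_n)]
  }
  x <- pmin(1, pmax(-1, x))
  audio_segment(x, rate = target_rate, label = label, source = path)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Parse a RAVDESS filename into an emotion label and speaker
#'
#' RAVDESS encodes each file as seven hyphenated two-digit fields
#' (modality-channel-emotion-intensity-statement-repetition-actor). Emotion
#' codes map onto the six target classes; the calm (02) and surprise (08)
#' classes fall outside the target set and are returned as `"excluded"`.
#'
#' @param filename RAVDESS file name (with or without directory / extension).
#' @return A tibble with columns `file`, `label` (emotion or `"excluded"`)
#'   and `speaker`.
#' @export
#' @examples
#' parse_ravdess_name("03-01-05-01-01-01-12.wav")
parse_ravdess_name <- function(filename) {
  base <- sub("\\.wav$", "", basename(filename), ignore.case = TRUE)
  parts <- strsplit(base, "-", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 7 || any(!grepl("^[0-9]{2}$", p)),
                logical(1))
  if (any(bad)) {
    stop("malformed RAVDESS code: ", paste(base[bad], collapse = ", "),
         call. = FALSE)
  }
  code_map <- c("01" = "neutral", "02" = "excluded", "03" = "joy",
                "04" = "sadness", "05" = "anger", "06" = "fear",
                "07" = "disgust", "08" = "excluded")
  emotion <- vapply(parts, `[[`, character(1), 3)
  unknown <- !emotion %in% names(code_map)
  if (any(unknown)) {
    stop("unknown RAVDESS emotion code: ", paste(emotion[unknown], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    file = basename(filename),
    label = unname(code_map[emotion]),
    speaker = vapply(parts, `[[`, character(1), 7)
  )
}

#' Parse an Emo-DB filename into an emotion label and speaker
#'
#' Emo-DB names are `<speaker:2 digits><text code:3><emotion letter><version>`.
#' The German emotion letters map W (Wut) to anger, A (Angst) to fear,
#' F (Freude) to joy, T (Trauer) to sadness, E (Ekel) to disgust and N to
#' neutral. The corpus's seventh class, boredom (L, Langeweile), is not among
#' the six target classes and is returned as `"excluded"`.
#'
#' @param filename Emo-DB file name.
#' @return A tibble with columns `file`, `label` and `speaker`.
#' @export
#' @examples
#' parse_emodb_name("03a01Wa.wav")
parse_emodb_name <- function(filename) {
  base <- sub("\\.wav$", "", basename(filename), ignore.case = TRUE)
  ok <- grepl("^[0-9]{2}[a-z][0-9]{2}[A-Z][a-z0-9]?$", base)
  if (any(!ok)) {
    stop("malformed Emo-DB code: ", paste(base[!ok], collapse = ", "),
         call. = FALSE)
  }
  letter_map <- c(W = "anger", A = "fear", F = "joy", T = "sadness",
                  E = "disgust", N = "neutral", L = "excluded")
  letter <- substr(base, 6, 6)
  unknown <- !letter %in% names(letter_map)
  if (any(unknown)) {
    stop("unknown Emo-DB emotion letter: ", paste(letter[unknown], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    file = basename(filename),
    label = unname(letter_map[letter]),
    speaker = substr(base, 1, 2)
  )
}

#' Scan a corpus directory into a dataset manifest
#'
#' Walks `dir` for `.wav` files, parses labels from the corpus filename
#' convention, and drops files whose emotion falls outside the six target
#' classes. For `corpus = "synthetic"` the manifest written by
#' [make_dataset()] is read instead of re-parsing names.
#'
#' @param dir Corpus directory.
#' @param corpus One of `"ravdess"`, `"emodb"`, `"synthetic"`.
#' @return A manifest tibble with columns `path`, `label`, `speaker`,
#'   `language`, `corpus`.
#' @export
scan_corpus <- function(dir, corpus = c("ravdess", "emodb", "synthetic")) {
  corpus <- match.arg(corpus)
  if (corpus == "synthetic") {
    manifest_path <- file.path(dir, "manifest.csv")
    if (!file.exists(manifest_path)) {
      stop("no manifest.csv in synthetic corpus directory: ", dir, call. = FALSE)
    }
    return(read_manifest(manifest_path))
  }
  files <- list.files(dir, pattern = "\\.wav$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0) stop("no .wav files found under ", dir, call. = FALSE)
  parser <- if (corpus == "ravdess") parse_ravdess_name else parse_emodb_name
  parsed <- parser(files)
  keep <- parsed$label != "excluded"
  tibble::tibble(
    path = files[keep],
    label = parsed$label[keep],
    speaker = parsed$speaker[keep],
    language = if (corpus == "ravdess") "en" else "de",
    corpus = corpus
  )
}

#' Read / write a dataset manifest CSV
#'
#' @param path Manifest path (`path,label,speaker,language,corpus` header).
#' @return A manifest tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("path", "label", "speaker", "language", "corpus")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("manifest missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(as_emotion(df$label))  # validate labels
  if (anyDuplicated(df$path)) stop("manifest paths are not unique", call. = FALSE)
  tibble::as_tibble(df[required])
}

#' @rdname read_manifest
#' @param manifest Manifest tibble to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
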