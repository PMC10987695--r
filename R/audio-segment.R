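#' Audio segment objects
#'
#' An `audio_segment` is the unit of classification: a mono waveform with its
#' sample rate, an optional emotion label, and provenance (source path and
#' offset within the source, in seconds).
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\].
#' @param rate Sample rate in Hz.
#' @param label Optional emotion label (see [emotion_levels()]).
#' @param source Optional source path.
#' @param offset Offset of this segment within its source, in seconds.
#' @return An object of class `audio_segment`.
#' @export
#' @examples
#' s <- audio_segment(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), rate = 8000)
#' s
audio_segment <- function(samples, rate, label = NULL, source = NA_character_,
                          offset = 0) {
  if (!is.numeric(samples) || length(samples) < 1) {
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  }
  stopifnot(is.numeric(rate), length(rate) == 1, rate > 0)
  if (!is.null(label)) label <- as.character(as_emotion(label))
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         label = label, source = source, offset = offset),
    class = "audio_segment"
  )
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment: %d samples @ %g Hz (%.3f s)%s%s>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (!is.null(x$label)) paste0(", label=", x$label) else "",
              if (!is.na(x$source)) paste0(", source=", basename(x$source)) else ""))
  invisible(x)
}

#' @export
length.audio_segment <- function(x) length(x$samples)

is_audio_segment <- function(x) inherits(x, "audio_segment")

#' Duration of an audio segment in seconds
#' @param segment An [audio_segment()].
#' @return Duration in seconds.
#' @export
segment_duration <- function(segment) {
  stopifnot(is_audio_segment(segment))
  length(segment$samples) / segment$rate
}
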