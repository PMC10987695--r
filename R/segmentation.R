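#' Fixed-window specification
#'
#' @param duration Window duration in seconds (default 1.5).
#' @param stride Hop between consecutive window starts in seconds; defaults to
#'   `duration` (non-overlapping). Strides shorter than the duration give
#'   overlapping windows, longer strides give gapped coverage.
#' @param rate Sample rate in Hz.
#' @return A `window_spec` list with the derived `target_len` in samples.
#' @export
window_spec <- function(duration = 1.5, stride = duration, rate = 16000) {
  stopifnot(duration > 0, stride > 0, rate > 0)
  structure(list(duration = duration, stride = stride, rate = rate,
                 target_len = round(duration * rate)),
            class = "window_spec")
}

#' Force a segment to the fixed window length
#'
#' Longer inputs are trimmed symmetrically to the core `duration` seconds:
#' `floor(excess/2)` samples are removed at the start and `ceiling(excess/2)`
#' at the end. Shorter inputs are symmetrically extended with silence:
#' `ceiling(deficit/2)` zeros prepended and `floor(deficit/2)` appended.
#' Inputs already at the target length are returned unchanged.
#'
#' @param segment An [audio_segment()] at the spec's rate.
#' @param spec A [window_spec()].
#' @return An [audio_segment()] of exactly `spec$target_len` samples.
#' @export
#' @examples
#' seg <- audio_segment(rnorm(30000), rate = 16000)
#' length(fix_window(seg, window_spec(1.5))$samples)
fix_window <- function(segment, spec = window_spec(rate = segment$rate)) {
  stopifnot(is_audio_segment(segment), inherits(spec, "window_spec"))
  if (length(segment$samples) == 0) stop("empty audio segment", call. = FALSE)
  if (segment$rate != spec$rate) {
    stop("segment rate (", segment$rate, " Hz) does not match window spec rate (",
         spec$rate, " Hz)", call. = FALSE)
  }
  n <- length(segment$samples)
  target <- spec$target_len
  if (n == target) return(segment)
  if (n > target) {
    excess <- n - target
    drop_start <- excess %/% 2
    x <- segment$samples[(drop_start + 1):(drop_start + target)]
  } else {
    deficit <- target - n
    pad_start <- ceiling(deficit / 2)
    pad_end <- deficit - pad_start
    x <- c(numeric(pad_start), segment$samples, numeric(pad_end))
  }
  audio_segment(x, rate = segment$rate, label = segment$label,
                source = segment$source, offset = segment$offset)
}

#' Cut a longer stream into fixed windows for continuous classification
#'
#' Windows start at 0, `stride`, `2 * stride`, ... seconds, for every start
#' strictly inside the input. Trailing partial windows are symmetrically
#' zero-padded via [fix_window()] so streams of any length yield at least one
#' window. Each output carries its source offset in seconds.
#'
#' @param segment An [audio_segment()] of any length.
#' @param spec A [window_spec()].
#' @return A tibble with columns `offset` (seconds) and `segment`
#'   (list-column of fixed-length [audio_segment()]s).
#' @export
stream_windows <- function(segment, spec = window_spec(rate = segment$rate)) {
  stopifnot(is_audio_segment(segment), inherits(spec, "window_spec"))
  if (segment$rate != spec$rate) {
    stop("segment rate does not match window spec rate", call. = FALSE)
  }
  n <- length(segment$samples)
  stride_n <- round(spec$stride * spec$rate)
  starts <- seq(0L, n - 1L, by = stride_n)
  windows <- purrr::map(starts, function(s) {
    idx <- (s + 1):min(n, s + spec$target_len)
    w <- audio_segment(segment$samples[idx], rate = segment$rate,
                       label = segment$label, source = segment$source,
                       offset = segment$offset + s / spec$rate)
    fix_window(w, spec)
  })
  tibble::tibble(offset = starts / spec$rate, segment = windows)
}
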