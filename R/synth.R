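#' Synthesis configuration
#'
#' Settings for the synthetic emotional-voice generator. Defaults match the
#' working conditions of the rest of the pipeline: 1.5 s segments at
#' 16,000 Hz, which give the 24,000-sample windows and 47-frame short-time
#' blocks the feature battery is sized for.
#'
#' @param n_per_class Utterances per emotion class (>= 1).
#' @param separation Real in \[0, 1\] scaling inter-class profile differences;
#'   0 collapses every class onto the neutral profile.
#' @param duration Segment duration in seconds.
#' @param rate Sample rate in Hz.
#' @param seed Integer seed; all synthesis randomness derives from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_per_class = 10, separation = 1, duration = 1.5,
                         rate = 16000, seed = 1) {
  stopifnot(n_per_class >= 1, duration > 0, rate > 0,
            separation >= 0, separation <= 1)
  structure(list(n_per_class = as.integer(n_per_class), separation = separation,
                 duration = duration, rate = rate, seed = as.integer(seed)),
            class = "synth_config")
}

# Index-keyed substream seed so each (label, index) utterance is reproducible
# independently of generation order. Kept below 2^31.
synth_substream_seed <- function(seed, label, index) {
  code <- emotion_code(label)
  (as.double(seed) * 7919 + code * 1299709 + index * 104729) %% 2147483629
}

#' Generate one synthetic emotional utterance
#'
#' Produces a vocal-like waveform: a harmonic stack whose fundamental follows
#' a slowly drifting contour drawn around the class profile's F0 mean/range,
#' shaped by an attack-decay energy envelope with amplitude modulation at the
#' class rate, plus a broadband noise floor. The class profiles are scaled
#' toward or away from the neutral profile by `separation`. Deterministic
#' given `(label, seed, index)`.
#'
#' @param label Emotion label (see [emotion_levels()]).
#' @param config A [synth_config()].
#' @param index Utterance index within the class, `0 <= index < n_per_class`.
#' @return An [audio_segment()] of exactly `round(duration * rate)` samples.
#' @export
#' @examples
#' seg <- synth_segment("anger", synth_config(seed = 7), index = 0)
#' length(seg$samples)
synth_segment <- function(label, config = synth_config(), index = 0) {
  label <- as.character(as_emotion(label))
  stopifnot(index >= 0, index < config$n_per_class)
  prof <- emotion_profiles(config$separation)
  p <- prof[prof$label == label, ]

  n <- round(config$duration * config$rate)
  t <- (seq_len(n) - 1) / config$rate

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(synth_substream_seed(config$seed, label, index))

  # per-utterance jitter around the class profile (documented SDs)
  f0_u <- max(60, stats::rnorm(1, p$f0_mean, p$f0_range / 4))
  range_u <- max(1, stats::rnorm(1, p$f0_range, p$f0_range / 8))
  energy_u <- min(1, max(0.05, stats::rnorm(1, p$energy, 0.05)))
  am_u <- max(0.5, stats::rnorm(1, p$am_rate, 0.4))
  noise_u <- min(0.9, max(0.01, stats::rnorm(1, p$noise_frac, 0.03)))

  # F0 contour: slow sinusoidal drift across the utterance
  drift_rate <- stats::runif(1, 0.5, 1.5)
  drift_phase <- stats::runif(1, 0, 2 * pi)
  f0_t <- f0_u + (range_u / 2) * sin(2 * pi * drift_rate * t + drift_phase)
  phase_t <- 2 * pi * cumsum(f0_t) / config$rate

  # harmonic stack with 1/h rolloff
  n_harm <- 6
  harm_phases <- stats::runif(n_harm, 0, 2 * pi)
  voice <- rowSums(vapply(seq_len(n_harm), function(h) {
    sin(h * phase_t + harm_phases[h]) / h
  }, numeric(n)))

  # attack-decay envelope with amplitude modulation
  attack <- 0.1 * config$duration
  release <- 0.15 * config$duration
  env <- pmin(1, pmin(t / attack, (config$duration - t) / release))
  env <- pmax(env, 0)
  am_phase <- stats::runif(1, 0, 2 * pi)
  am <- 1 + 0.35 * sin(2 * pi * am_u * t + am_phase)
  voice <- voice * env * am
  voice <- voice / max(abs(voice), 1e-12)

  noise <- stats::rnorm(n)
  noise <- noise / stats::sd(noise)
  p_voice <- mean(voice^2)
  noise <- noise * sqrt(p_voice * noise_u / (1 - noise_u))

  x <- energy_u * (voice + noise)
  x <- x / max(1, max(abs(x)))
  x <- pmin(1, pmax(-1, x))
  audio_segment(x, rate = config$rate, label = label,
                source = sprintf("synthetic:%s:%d", label, index))
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Generate a balanced synthetic dataset in memory
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per utterance: `label`, `speaker`,
#'   `language`, `corpus` and a `segment` list-column of [audio_segment()]s.
#' @export
synth_segments <- function(config = synth_config()) {
  grid <- tidyr::expand_grid(label = emotion_levels(),
                             index = seq_len(config$n_per_class) - 1L)
  grid$segment <- purrr::map2(grid$label, grid$index,
                              function(lab, i) synth_segment(lab, config, i))
  # pseudo-speakers: utterance index cycled through 4 synthetic voices
  grid$speaker <- sprintf("s%02d", grid$index %% 4L + 1L)
  grid$language <- "synthetic"
  grid$corpus <- "synthetic"
  grid[c("label", "index", "speaker", "language", "corpus", "segment")]
}

#' Write a balanced synthetic dataset to disk
#'
#' Writes `n_per_class * 6` WAV files (16-bit PCM mono) plus a
#' `manifest.csv` with one row per file and balanced classes.
#'
#' @param config A [synth_config()].
#' @param out_dir Writable output directory (created if absent).
#' @return The manifest tibble, invisibly the same as `manifest.csv`.
#' @export
make_dataset <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  tbl <- synth_segments(config)
  tbl$path <- file.path(out_dir, sprintf("%s-%03d.wav", tbl$label, tbl$index))
  purrr::walk2(tbl$segment, tbl$path,
               function(seg, p) write_wav(seg$samples, seg$rate, p))
  manifest <- tbl[c("path", "label", "speaker", "language", "corpus")]
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
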