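#' The six emotion classes
#'
#' The classifier targets five basic emotions plus neutral. Labels are kept in
#' alphabetical order of their English names, which also fixes the stable
#' integer encoding 0-5 used throughout the package.
#'
#' @return Character vector of the six admissible labels, in encoding order.
#' @export
#' @examples
#' emotion_levels()
emotion_levels <- function() {
  c("anger", "disgust", "fear", "joy", "neutral", "sadness")
}

#' @rdname emotion_levels
#' @param label Character vector of labels to encode.
#' @return `emotion_code()`: integer codes 0-5.
#' @export
emotion_code <- function(label) {
  label <- as_emotion(label)
  match(as.character(label), emotion_levels()) - 1L
}

#' Coerce to an emotion factor
#'
#' @param x Character or factor of emotion labels.
#' @return Factor with levels [emotion_levels()].
#' @export
as_emotion <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), emotion_levels())
  if (length(bad) > 0) {
    stop("invalid emotion label(s): ", paste(bad, collapse = ", "),
         " (admissible: ", paste(emotion_levels(), collapse = ", "), ")",
         call. = FALSE)
  }
  factor(x, levels = emotion_levels())
}

# Per-class synthesis profiles. These are declared fixtures for the synthetic
# generator -- caricatures of prosodic tendencies (anger loud/high/fast,
# sadness quiet/low/slow), not claims about real emotion acoustics.
# Columns: f0_mean (Hz), f0_range (Hz), energy [0,1], am_rate (Hz),
# noise_frac [0,1] of signal power that is broadband noise.
emotion_profile_table <- function() {
  tibble::tribble(
    ~label,     ~f0_mean, ~f0_range, ~energy, ~am_rate, ~noise_frac,
    "anger",       225,       80,      0.90,     7.0,      0.25,
    "disgust",     120,       30,      0.55,     4.5,      0.30,
    "fear",        265,       60,      0.60,     8.0,      0.20,
    "joy",         240,       90,      0.80,     6.0,      0.10,
    "neutral",     140,       25,      0.50,     3.0,      0.15,
    "sadness",     105,       15,      0.30,     2.0,      0.10
  )
}

#' Emotion synthesis profiles at a given class separation
#'
#' Linearly interpolates every class profile between the neutral profile
#' (`separation = 0`, all classes collapse to one distribution) and the
#' declared per-class profiles (`separation = 1`).
#'
#' @param separation Real in \[0, 1\] scaling inter-class differences.
#' @return A tibble with one row per emotion and the five profile parameters.
#' @export
#' @examples
#' emotion_profiles(0.5)
emotion_profiles <- function(separation = 1) {
  stopifnot(is.numeric(separation), length(separation) == 1,
            separation >= 0, separation <= 1)
  tab <- emotion_profile_table()
  neutral <- tab[tab$label == "neutral", -1]
  for (col in names(neutral)) {
    tab[[col]] <- neutral[[col]] + separation * (tab[[col]] - neutral[[col]])
  }
  tab
}
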