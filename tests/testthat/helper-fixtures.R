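# Shared fixtures, built once per test run. Model-facing datasets use short
# 0.5 s windows so the battery stays exercised end to end while the suite
# runs at desk scale; contract tests on the full 1.5 s geometry live in
# their own blocks.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

tiny_dataset <- function(separation = 1, design = "dnn", n_per_class = 10,
                         seed = 7) {
  fixture(sprintf("ds_%s_%s_%d_%d", design, separation, n_per_class, seed),
          function() {
    man <- synth_segments(synth_config(n_per_class = n_per_class,
                                       separation = separation,
                                       duration = 0.5, seed = seed))
    build_dataset(man, design = design, duration = 0.5)
  })
}

full_segment <- function(label = "anger", seed = 7, index = 0) {
  fixture(sprintf("seg_%s_%d_%d", label, seed, index), function() {
    fix_window(synth_segment(label, synth_config(seed = seed), index),
               window_spec())
  })
}

sine_segment <- function(freq = 440, rate = 16000, n = 24000, amp = 0.8) {
  t <- (seq_len(n) - 1) / rate
  audio_segment(amp * sin(2 * pi * freq * t), rate)
}

harmonic_segment <- function(f0 = 200, rate = 16000, n = 24000, n_harm = 6) {
  t <- (seq_len(n) - 1) / rate
  x <- rowSums(vapply(seq_len(n_harm), function(h) sin(2 * pi * f0 * h * t) / h,
                      numeric(n)))
  audio_segment(x / max(abs(x)), rate)
}

silence_segment <- function(rate = 16000, n = 24000) {
  audio_segment(numeric(n), rate)
}
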