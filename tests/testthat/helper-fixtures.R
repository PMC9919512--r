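# Shared fixtures, built in code.  Heavier fixtures are cached per test
# run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A preprocessed-stage trace whose channels carry scaled copies of a
# tone (plus optional seeded noise) — the canonical 1-D curve fixture
# for the decomposition extractors.
tone_trace <- function(freq, fs = 30, duration = 30,
                       coef = c(r = 0.4, g = 1, b = 0.6),
                       noise_sd = 0, seed = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * freq * t)
  set.seed(seed)
  mk <- function(k) k * s + stats::rnorm(length(t), 0, noise_sd)
  rgb_trace(mk(coef[["r"]]), mk(coef[["g"]]), mk(coef[["b"]]),
            fs = fs, stage = "preprocessed", t = t)
}

# Clean (noise-free) synthetic subject at 72 bpm, cached.
clean_subject_72 <- function() cached("clean72", {
  synth_subject(synth_config(seed = 42, noise_sd = 0, trend_amp = 0))
})

# Default-noise subject at 72 bpm, cached.
noisy_subject_72 <- function() cached("noisy72", {
  synth_subject(synth_config(seed = 42))
})

preprocessed_clean_72 <- function() cached("pre_clean72", {
  preprocess_trace(clean_subject_72()$trace)
})

# FFT amplitude of the tone at frequency f (assumes f on the DFT grid).
fft_amplitude <- function(x, fs, f) {
  n <- length(x)
  bin <- round(f * n / fs)
  2 * Mod(stats::fft(x - mean(x)))[bin + 1L] / n
}

# Manually constructed peak series (times in seconds).
peak_series_at <- function(times_s, fs = 30) {
  structure(list(indices = round(times_s * fs) + 1L, times_s = times_s,
                 fs = fs), class = "peak_series")
}

# NN series with prescribed beat-time modulation, built directly.
modulated_nn <- function(n_beats, base_ms = 800, f_mod = 0, amp_ms = 0,
                         jitter_sd = 0, seed = 1) {
  set.seed(seed)
  t <- 0
  nn <- numeric(n_beats)
  tb <- numeric(n_beats)
  for (i in seq_len(n_beats)) {
    nn[i] <- base_ms + amp_ms * sin(2 * pi * f_mod * t) +
      stats::rnorm(1, 0, jitter_sd)
    t <- t + nn[i] / 1000
    tb[i] <- t
  }
  nn_series(nn, tb)
}
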