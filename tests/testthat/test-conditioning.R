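# Preprocessing chain (detrend, moving average, band-pass) and
# postprocessing operators (wavelet filter, EMD, outlier suppression).

test_that("smoothness-priors detrending removes trend, keeps the pulse band", {
  # constants and ramps are pure trend
  expect_equal(spa_detrend(rep(5, 100)), rep(0, 100), tolerance = 1e-8)
  ramp <- seq(0, 10, length.out = 300)
  expect_lt(max(abs(spa_detrend(ramp))), 0.01 * diff(range(ramp)))

  # sparse solve agrees with a dense linear-algebra oracle
  set.seed(11)
  x <- cumsum(rnorm(120)) + sin(2 * pi * 1.5 * (0:119) / 30)
  n <- length(x)
  D2 <- diff(diag(n), differences = 2)
  trend_dense <- solve(diag(n) + 300^2 * crossprod(D2), x)
  expect_equal(spa_detrend(x, 300), x - as.numeric(trend_dense),
               tolerance = 1e-8)

  # a 1.5 Hz unit tone riding on a ramp survives with amplitude ~ 1
  t <- (0:899) / 30
  y <- 3 * t + sin(2 * pi * 1.5 * t)
  out <- spa_detrend(y, 300)
  basis <- cbind(sin(2 * pi * 1.5 * t), cos(2 * pi * 1.5 * t))
  amp <- sqrt(sum(stats::lm.fit(basis, out)$coefficients^2))
  expect_lt(abs(amp - 1), 0.05)

  expect_error(spa_detrend(c(1, NA, 3)), "non-finite")
})

test_that("moving average uses shrinking centered edge windows", {
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 3),
               c(1.5, 2, 3, 4, 4.5))
  x <- rnorm(20)
  expect_identical(moving_average(x, 1L), x)
  expect_equal(moving_average(rep(2.5, 15), 5), rep(2.5, 15))
  expect_error(moving_average(1:3, 5), "window larger")
})

test_that("band-pass preserves in-band tones and rejects out-of-band", {
  t <- (0:1799) / 30
  inband <- sin(2 * pi * 1.5 * t)
  out <- bandpass(inband, 30)
  a <- fft_amplitude(out, 30, 1.5)
  expect_true(a >= 0.95 && a <= 1.05)

  low <- sin(2 * pi * 0.2 * t)
  expect_lt(max(abs(bandpass(low, 30))), 0.1)

  expect_equal(bandpass(rep(0, 600), 30), rep(0, 600))
  expect_error(bandpass(inband, 30, band_lo = 5, band_hi = 20), "band")
})

test_that("preprocessing chain is linear and removes DC", {
  cfg <- filter_config()
  chain <- function(v) {
    v <- spa_detrend(v, cfg$spa_lambda)
    v <- moving_average(v, cfg$ma_window)
    bandpass(v, 30, cfg$band_lo, cfg$band_hi, cfg$bp_order)
  }
  set.seed(21)
  x <- cumsum(rnorm(600)); y <- rnorm(600); a <- 1.7; b <- -0.4
  lhs <- chain(a * x + b * y)
  rhs <- a * chain(x) + b * chain(y)
  expect_lt(max(abs(lhs - rhs)), 1e-9 * max(abs(lhs)))
  expect_lt(abs(mean(chain(x))), 1e-6 * stats::sd(x))

  # the full trace-level chain matches the per-channel operators
  sub <- clean_subject_72()
  pre <- preprocess_trace(sub$trace, cfg)
  expect_equal(pre$g, chain(sub$trace$g), tolerance = 1e-12)
  expect_identical(pre$stage, "preprocessed")
})

test_that("wavelet filter suppresses off-ridge tones, preserves the pulse", {
  fs <- 30
  t <- (0:899) / fs
  clean <- sin(2 * pi * 1.2 * t)
  noisy <- clean + 0.3 * sin(2 * pi * 5 * t)
  out <- wavelet_filter(noisy, fs)
  expect_equal(dominant_frequency(out, fs, c(0.5, 6)), 1.2,
               tolerance = 1 / 30 + 1e-9)
  # the 5 Hz component drops by >= 10 dB
  rej <- fft_amplitude(out, fs, 5) / fft_amplitude(noisy, fs, 5)
  expect_lt(20 * log10(rej), -10)

  # a clean in-band tone passes nearly unchanged (waveform correlation)
  out_c <- wavelet_filter(clean, fs)
  expect_gte(stats::cor(out_c, clean), 0.99)

  expect_equal(wavelet_filter(rep(0, 600), fs), rep(0, 600))
  expect_error(wavelet_filter(clean[1:4], fs), "shorter")
})

test_that("EMD is complete and isolates a single tone in its first mode", {
  fs <- 30
  t <- (0:899) / fs
  tone <- sin(2 * pi * 1 * t)
  dec <- emd_decompose(tone)
  rec <- Reduce(`+`, dec$imfs, dec$residue)
  expect_lt(max(abs(rec - tone)), 1e-8 * diff(range(tone)))
  expect_gte(stats::var(dec$imfs[[1]]) / stats::var(tone), 0.9)

  # strictly monotone input: no modes, residue = input
  ramp <- seq(1, 50, length.out = 100)
  dec_r <- emd_decompose(ramp)
  expect_length(dec_r$imfs, 0)
  expect_identical(dec_r$residue, ramp)

  expect_error(emd_decompose(1:5), "at least 10")
  expect_error(emd_decompose(c(rnorm(20), NA)), "non-finite")
})

test_that("pulse-mode selection picks the in-band mode or falls back", {
  fs <- 30
  t <- (0:899) / fs
  pulse <- sin(2 * pi * 1.2 * t)
  drift <- sin(2 * pi * 0.1 * t)
  made <- function(imfs) structure(list(imfs = imfs,
                                        residue = numeric(length(t))),
                                   class = "imf_set")
  sel <- select_pulse_imf(made(list(pulse, drift)), fs)
  expect_identical(sel, pulse)
  # single in-band mode: identity
  expect_identical(select_pulse_imf(made(list(pulse)), fs), pulse)
  # nothing in band: band-passed reconstruction, with a warning
  hi <- sin(2 * pi * 6 * t)
  expect_warning(out <- select_pulse_imf(made(list(drift, hi)), fs),
                 "band")
  expect_length(out, length(t))
})

test_that("outlier suppression shares the moving-average contract", {
  x <- rnorm(50)
  expect_identical(suppress_outliers(x, 1L), x)
  expect_equal(suppress_outliers(c(1, 2, 3, 4, 5), 3),
               c(1.5, 2, 3, 4, 4.5))
  expect_equal(suppress_outliers(rep(1, 10), 3), rep(1, 10))
})

test_that("postprocessing keeps the dominant pulse frequency", {
  sub <- clean_subject_72()
  pre <- preprocess_trace(sub$trace)
  sig <- extract_ippg(pre, "POS")
  pp <- postprocess_ippg(sig)
  n <- length(pp$values)
  f_true <- 1.2
  expect_lt(abs(dominant_frequency(pp$values, pp$fs, c(0.65, 4)) - f_true),
            pp$fs / n + 1e-9)
})
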