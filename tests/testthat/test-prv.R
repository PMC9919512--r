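# Peak detection, NN correction, and the 14 PRV features.

test_that("detect_peaks finds sinusoid maxima at the right spacing", {
  fs <- 30
  t <- (0:899) / fs
  x <- sin(2 * pi * 1 * t)
  pk <- detect_peaks(x, fs)
  expect_true(length(pk$indices) %in% c(29, 30))
  expect_true(all(abs(diff(pk$indices) - 30) <= 1))
  expect_error(detect_peaks(rep(0, 900), fs), "fewer than 2 peaks")
})

test_that("detected peaks match the synthetic template ground truth", {
  gen <- generate_nn(synth_config(seed = 12, jitter_sd = 5))
  bvp <- nn_to_bvp(gen$nn, fs = 30)
  pk <- detect_peaks(bvp$bvp, 30)
  truth <- bvp$peak_times_s
  # match each truth peak to the nearest detection
  err <- vapply(truth, function(tt) min(abs(pk$times_s - tt)), numeric(1))
  expect_lt(max(err), 1 / 30 + 1e-9)
})

test_that("ectopic intervals are flagged, replaced, and bounded", {
  # clean 800 ms train
  pk <- peak_series_at(cumsum(rep(0.8, 40)))
  nn <- peaks_to_nn(pk)
  expect_equal(nn$intervals_ms, rep(800, 39), tolerance = 1e-9)
  expect_identical(nn$corrected_count, 0L)

  # one missed beat: the doubled interval is replaced
  times <- cumsum(c(rep(0.8, 10), 1.6, rep(0.8, 10)))
  nn2 <- peaks_to_nn(peak_series_at(times))
  expect_identical(nn2$corrected_count, 1L)
  expect_lt(max(abs(nn2$intervals_ms - 800)), 40)
  expect_true(all(nn2$intervals_ms >= 250 & nn2$intervals_ms <= 1540))

  # wildly random spacing: corrupt-signal error
  set.seed(13)
  bad <- cumsum(runif(30, 0.3, 1.5))
  expect_error(peaks_to_nn(peak_series_at(bad)), "corrupt")
})

test_that("time features match hand-computed oracles", {
  nn <- nn_series(c(800, 810, 790, 805), cumsum(c(800, 810, 790, 805)) / 1000)
  tf <- time_features(nn)
  expect_equal(tf$RMSSD, sqrt(725 / 3), tolerance = 1e-12)
  expect_equal(tf$PR, mean(60000 / c(800, 810, 790, 805)),
               tolerance = 1e-12)
  expect_equal(tf$SDNN, stats::sd(c(800, 810, 790, 805)),
               tolerance = 1e-12)

  # constant series: degenerate histogram
  nnc <- nn_series(rep(800, 50), cumsum(rep(0.8, 50)))
  tfc <- time_features(nnc)
  expect_equal(tfc$RMSSD, 0)
  expect_equal(tfc$SDNN, 0)
  expect_equal(tfc$TI, 1)
  expect_equal(tfc$TINN, 1000 / 128, tolerance = 1e-9)

  # alternating +-x: RMSSD against the direct formula
  x <- 15
  alt <- 800 + x * rep_len(c(-1, 1), 60)
  nna <- nn_series(alt, cumsum(alt) / 1000)
  expect_equal(time_features(nna)$RMSSD, sqrt(mean(diff(alt)^2)),
               tolerance = 1e-12)

  expect_error(time_features(nn_series(c(800, 805), c(0.8, 1.6))),
               "at least 4")
})

test_that("frequency features localize single-band modulation", {
  nn_lf <- modulated_nn(200, f_mod = 0.1, amp_ms = 50, seed = 14)
  ff_lf <- freq_features(nn_lf)
  expect_gte(ff_lf$LFnu, 0.9)
  nn_hf <- modulated_nn(200, f_mod = 0.3, amp_ms = 50, seed = 14)
  ff_hf <- freq_features(nn_hf)
  expect_gte(ff_hf$HFnu, 0.9)
  expect_equal(ff_lf$LFnu + ff_lf$HFnu, 1, tolerance = 1e-9)
  expect_equal(ff_lf$LF_HF, ff_lf$LF / ff_lf$HF, tolerance = 1e-12)
  expect_error(freq_features(modulated_nn(20)), "30 s")
})

test_that("Poincare dispersion matches the rotated-coordinates oracle", {
  x <- c(800, 810, 790, 805)
  nn <- nn_series(x, cumsum(x) / 1000)
  pc <- poincare(nn)
  a <- x[1:3]; b <- x[2:4]
  expect_equal(pc$SD1, stats::sd((a - b) / sqrt(2)), tolerance = 1e-12)
  expect_equal(pc$SD2, stats::sd((a + b) / sqrt(2)), tolerance = 1e-12)
  expect_equal(pc$SD1_SD2, pc$SD1 / pc$SD2, tolerance = 1e-12)

  # constant: zero dispersion, undefined ratio (not an error)
  nnc <- nn_series(rep(800, 10), cumsum(rep(0.8, 10)))
  pcc <- poincare(nnc)
  expect_equal(pcc$SD1, 0)
  expect_equal(pcc$SD2, 0)
  expect_true(is.na(pcc$SD1_SD2))
})

test_that("shifting all intervals moves PR but not the dispersion features", {
  nn0 <- modulated_nn(100, f_mod = 0.1, amp_ms = 30, jitter_sd = 10,
                      seed = 15)
  x <- nn0$intervals_ms
  nn1 <- nn_series(x + 100, nn0$beat_times_s)
  f0 <- time_features(nn0); f1 <- time_features(nn1)
  expect_equal(f1$RMSSD, f0$RMSSD, tolerance = 1e-9)
  expect_equal(f1$SDNN, f0$SDNN, tolerance = 1e-9)
  p0 <- poincare(nn0); p1 <- poincare(nn1)
  expect_equal(p1$SD1, p0$SD1, tolerance = 1e-9)
  expect_equal(p1$SD2, p0$SD2, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f1$PR, f0$PR)))
})

test_that("pipeline closure: waveform round trip reproduces the NN series", {
  gen <- generate_nn(synth_config(seed = 16, jitter_sd = 5))
  bvp <- nn_to_bvp(gen$nn, fs = 30)
  nn_hat <- peaks_to_nn(detect_peaks(bvp$bvp, 30))
  # the waveform's own truth: successive template peak spacings (these
  # differ from the NN series by the within-beat peak-phase shift when
  # intervals vary)
  truth <- diff(bvp$peak_times_s) * 1000
  m <- min(length(truth), length(nn_hat$intervals_ms))
  err <- nn_hat$intervals_ms[1:m] - truth[1:m]
  expect_lt(max(abs(err)), 1000 / 30 + 1e-9)
})

test_that("prv_features populates all 14 fields with metadata", {
  nn <- modulated_nn(120, f_mod = 0.1, amp_ms = 30, jitter_sd = 10,
                     seed = 17)
  f <- prv_features(nn)
  for (nm in c("PR", "RMSSD", "SDNN", "TI", "TINN", "VLF", "LF", "HF",
               "LF_HF", "LFnu", "HFnu", "SD1", "SD2", "SD1_SD2"))
    expect_true(is.finite(f[[nm]]), label = paste("finite", nm))
  expect_true(f$meta$vlf_unreliable)  # ~96 s of beats
  df <- as.data.frame(f)
  expect_identical(dim(df), c(1L, 14L))

  p <- tempfile(fileext = ".json")
  on.exit(unlink(p))
  write_prv_features(f, p)
  j <- jsonlite::read_json(p)
  expect_equal(j$PR, f$PR, tolerance = 1e-9)
})
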