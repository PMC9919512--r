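# The eight extraction algorithms and their shared machinery.

pre_trace <- function(r, g, b, fs = 30) {
  rgb_trace(r, g, b, fs = fs, stage = "preprocessed")
}

test_that("GRD is the green-red difference", {
  t <- (0:99) / 30
  s <- sin(2 * pi * t)
  expect_equal(grd(pre_trace(s, s, s))$values, rep(0, 100))
  expect_equal(grd(pre_trace(c(0, 0, 0), c(1, 2, 3), c(0, 0, 0)))$values,
               c(1, 2, 3))
  expect_equal(grd(pre_trace(c(0.2, 0.1, 0.1), c(0.5, 0.7, 0.1),
                             c(0, 0, 0)))$values,
               c(0.3, 0.6, 0.0))
})

test_that("AGRD normalizes by the raw channels and the raw-trace norm", {
  # preprocessed == raw gives an identically zero signal
  raw <- rgb_trace(c(100, 100, 100), c(150, 150, 150), c(200, 200, 200),
                   fs = 30, stage = "raw")
  expect_equal(agrd(raw, raw)$values, rep(0, 3), tolerance = 1e-12)

  # ||c0|| = 5 for c0 = (3,4,0); g/g0 = 1.1, r/r0 = 1 -> 5 * 0.1 = 0.5
  raw2 <- rgb_trace(rep(3, 3), rep(4, 3), rep(0, 3), fs = 30)
  pre2 <- pre_trace(rep(3, 3), rep(4.4, 3), rep(0, 3))
  expect_equal(agrd(raw2, pre2)$values, rep(0.5, 3), tolerance = 1e-12)

  # vanished green term leaves -||c0|| r/r0
  pre3 <- pre_trace(rep(3, 3), rep(0, 3), rep(0, 3))
  expect_equal(agrd(raw2, pre3)$values, rep(-5, 3), tolerance = 1e-12)

  # raw channel magnitude floor
  raw0 <- rgb_trace(rep(0, 3), rep(4, 3), rep(1, 3), fs = 30)
  expect_error(agrd(raw0, pre2), "below floor at sample 1")
})

test_that("running std matches a brute-force two-pass oracle", {
  set.seed(31)
  x <- rnorm(300)
  L <- 48L
  rs <- running_std(x, L)
  brute <- vapply(L:300, function(t) stats::sd(x[(t - L + 1L):t]),
                  numeric(1))
  expect_equal(rs[L:300], brute, tolerance = 1e-10)
  expect_equal(rs[1:(L - 1L)], rep(rs[L], L - 1L))
  expect_error(running_std(x, 301L), "L")
})

test_that("CHROM cancels r = g inputs and scales linearly", {
  t <- (0:899) / 30
  s <- sin(2 * pi * 1.3 * t) + 0.3 * sin(2 * pi * 0.9 * t)
  # r = g: x1 = 0.26 r, x2 = 1.28 r, ratio cancels the projection exactly
  out <- chrom(pre_trace(s, s, 0 * s))
  expect_lt(max(abs(out$values)), 1e-10)

  # g alone: x1 = -0.51 g, x2 = 0.51 g, sigma ratio 1 -> -1.02 g
  g <- sin(2 * pi * 1.3 * t)
  out_g <- chrom(pre_trace(0 * g, g, 0 * g))
  expect_equal(out_g$values, -1.02 * g, tolerance = 1e-9)

  # degenerate constant trace: clamped ratio, zero output, warning
  expect_warning(out_c <- chrom(pre_trace(rep(1, 60), rep(1, 60),
                                          rep(1, 60))),
                 "clamped")
  expect_equal(out_c$values, rep(0, 60))

  # scale equivariance
  a <- 2.7
  out_s <- chrom(pre_trace(a * s, a * g, 0 * s))
  base <- chrom(pre_trace(s, g, 0 * s))
  expect_equal(out_s$values, a * base$values, tolerance = 1e-9)
})

test_that("POS is intensity-invariant and passes green-only input as 2g", {
  t <- (0:899) / 30
  g <- sin(2 * pi * 1.3 * t)
  # r = g = b (pure intensity): both projections vanish (every window
  # is degenerate, hence the clamp warning)
  out_i <- suppressWarnings(pos(pre_trace(g, g, g)))
  expect_lt(max(abs(out_i$values)), 1e-12)

  # g alone: x1 = x2 = g, ratio 1 -> 2 g
  out_g <- pos(pre_trace(0 * g, g, 0 * g))
  expect_equal(out_g$values, 2 * g, tolerance = 1e-9)

  # adding the same series to all channels changes nothing
  sub <- clean_subject_72()
  pre <- preprocess_trace(sub$trace)
  drift <- 0.5 * sin(2 * pi * 0.8 * pre$t)
  pre2 <- pre_trace(pre$r + drift, pre$g + drift, pre$b + drift)
  expect_equal(pos(pre2)$values, pos(pre)$values, tolerance = 1e-8)
})

test_that("PCA picks the pulse-band component and flags rank-1 input", {
  t <- (0:899) / 30
  set.seed(5)
  g <- sin(2 * pi * 1.2 * t)
  tr <- pre_trace(0.1 * rnorm(900), g, 0.1 * rnorm(900))
  fit <- pca_extract(tr)
  expect_lt(abs(dominant_frequency(fit$signal$values, 30, c(0.65, 4)) - 1.2),
            30 / 900 + 1e-9)
  expect_true(fit$signal$polarity_oriented)

  # r = g = b: rank-1, first PC explains ~ all variance
  tr1 <- pre_trace(g, g, g)
  fit1 <- pca_extract(tr1)
  ev <- fit1$model$basis
  v <- apply(fit1$model$components, 2, stats::var)
  expect_gte(v[1] / sum(v), 0.999)

  expect_error(pca_extract(pre_trace(rep(1, 60), rep(1, 60), rep(1, 60))),
               "variance")
})

test_that("ICA separates known mixtures deterministically", {
  fs <- 30
  t <- (0:1199) / fs
  s1 <- sin(2 * pi * 1.1 * t)
  s2 <- sin(2 * pi * 0.2 * t)
  set.seed(6)
  s3 <- 0.01 * rnorm(length(t))
  A <- matrix(c(0.9, 0.4, 0.2,
                0.3, 1.0, 0.5,
                0.2, 0.6, 1.0), 3, 3, byrow = TRUE)
  X <- cbind(s1, s2, s3) %*% t(A)
  tr <- pre_trace(X[, 1], X[, 2], X[, 3])
  fit <- ica_extract(tr, method_params(seed = 3))
  expect_gte(abs(stats::cor(fit$signal$values, s1)), 0.95)

  # identical seed -> identical output
  fit2 <- ica_extract(tr, method_params(seed = 3))
  expect_identical(fit$signal$values, fit2$signal$values)

  # near-diagonal mixing: in-band source recovered almost exactly
  Xd <- cbind(s1, s2, s3) %*% diag(c(1, 0.8, 0.6))
  trd <- pre_trace(Xd[, 1], Xd[, 2], Xd[, 3])
  fitd <- ica_extract(trd, method_params(seed = 3))
  expect_gte(abs(stats::cor(fitd$signal$values, s1)), 0.99)
})

test_that("Laplacian eigenmap unfolds the RGB curve at the tone frequency", {
  tr <- tone_trace(1.2, duration = 30, noise_sd = 0.02, seed = 8)
  fit <- le_extract(tr)
  expect_lt(abs(dominant_frequency(fit$signal$values, 30, c(0.65, 4)) - 1.2),
            30 / length(tr) + 1e-9)
  expect_error(le_extract(tone_trace(1.2, duration = 30),
                          method_params(le_k = 1000L)),
               "more samples than le_k")
})

test_that("stochastic proximity embedding preserves pairwise proximities", {
  # two distinct points repeated: optimal map distance equals their
  # standardized RGB distance
  n <- 60
  r <- rep(c(0.0, 1.0), n / 2)
  g <- rep(c(0.2, 0.9), n / 2)
  b <- rep(c(0.1, 0.5), n / 2)
  tr <- pre_trace(r, g, b)
  X <- scale(cbind(r, g, b))
  r_ab <- sqrt(sum((X[1, ] - X[2, ])^2))
  fit <- spe_extract(tr, method_params(seed = 4))
  d_ab <- abs(mean(fit$model$embedding[seq(1, n, 2)]) -
              mean(fit$model$embedding[seq(2, n, 2)]))
  expect_lt(abs(d_ab - r_ab) / r_ab, 0.05)

  # determinism under the seed
  fit2 <- spe_extract(tr, method_params(seed = 4))
  expect_identical(fit$model$embedding, fit2$model$embedding)

  # tone fixture: embedding oscillates at the tone frequency
  trt <- tone_trace(1.2, duration = 30, noise_sd = 0.02, seed = 9)
  fitt <- spe_extract(trt, method_params(seed = 4))
  expect_lt(abs(dominant_frequency(fitt$signal$values, 30, c(0.65, 4)) - 1.2),
            30 / length(trt) + 1e-9)
})

test_that("polarity orientation flips pulse-down signals only", {
  sub <- clean_subject_72()
  pre <- preprocess_trace(sub$trace)
  up <- -pre$g   # green is pulse-down, so -g is pulse-up
  s_up <- ippg_signal(up, 30, "GRD")
  expect_equal(orient_polarity(s_up, pre)$values, up)
  s_down <- ippg_signal(pre$g, 30, "GRD")
  expect_equal(orient_polarity(s_down, pre)$values, -pre$g)
  expect_warning(o <- orient_polarity(ippg_signal(rep(0, length(pre$g)),
                                                  30, "GRD"), pre),
                 "zero-variance")
  expect_true(o$polarity_oriented)
})

test_that("the dispatcher validates method names and orients all outputs", {
  sub <- clean_subject_72()
  pre <- preprocess_trace(sub$trace)
  expect_error(extract_ippg(pre, "xyz"),
               "GRD, AGRD, PCA, ICA, LE, SPE, CHROM, POS")
  expect_error(extract_ippg(pre, "AGRD"), "raw trace")
  for (m in c("GRD", "CHROM", "POS")) {
    s <- extract_ippg(pre, m)
    expect_true(s$polarity_oriented)
    expect_identical(s$method, m)
  }
})
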