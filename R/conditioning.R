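# Signal conditioning: preprocessing of raw RGB traces (smoothness-priors
# detrending, moving average, band-pass) and postprocessing of extracted
# pulse signals (two-step wavelet filter, empirical mode decomposition,
# outlier suppression).

#' Conditioning parameters
#'
#' @param spa_lambda regularization of the smoothness-priors detrender
#'   (dimensionless, > 0).  The implied high-pass cutoff scales with the
#'   sampling rate; the default of 300 puts it near 0.06 Hz at 30 Hz,
#'   well below the pulse band.
#' @param ma_window moving-average width in samples, odd; the default 5 at
#'   30 fps spans about 0.17 s, below the 4 Hz pulse-band period.
#' @param band_lo,band_hi pulse band in Hz (defaults 0.65 and 4, i.e.
#'   39-240 bpm).
#' @param bp_order Butterworth band-pass order (applied forward-backward
#'   for zero phase).
#' @param wavelet_window running-window length for the adaptive wavelet
#'   filter, seconds.
#' @param emd_max_imfs cap on the number of intrinsic mode functions.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(spa_lambda = 300, ma_window = 5L,
                          band_lo = 0.65, band_hi = 4,
                          bp_order = 4L, wavelet_window = 15,
                          emd_max_imfs = 10L) {
  stopifnot(spa_lambda > 0, ma_window >= 1L, ma_window %% 2L == 1L,
            band_lo > 0, band_lo < band_hi, bp_order >= 2L,
            wavelet_window > 0, emd_max_imfs >= 1L)
  structure(list(spa_lambda = spa_lambda, ma_window = as.integer(ma_window),
                 band_lo = band_lo, band_hi = band_hi,
                 bp_order = as.integer(bp_order),
                 wavelet_window = wavelet_window,
                 emd_max_imfs = as.integer(emd_max_imfs)),
            class = "filter_config")
}

#' Smoothness-priors detrending
#'
#' Removes the slowly varying baseline by subtracting the trend
#' `z_trend = (I + lambda^2 D2' D2)^-1 z`, where `D2` is the second-order
#' difference operator.  Solved with a sparse banded system; constants and
#' linear ramps are removed exactly.
#'
#' @param x numeric vector, length >= 3.
#' @param spa_lambda regularization parameter, > 0.
#' @return detrended vector (same length, mean approximately zero).
#' @export
spa_detrend <- function(x, spa_lambda = 300) {
  n <- length(x)
  if (n < 3L) stop("spa_detrend: need at least 3 samples")
  if (!all(is.finite(x))) stop("spa_detrend: non-finite input")
  D2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                           diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                            rep(1, n - 2L)))
  A <- Matrix::Diagonal(n) + spa_lambda^2 * Matrix::crossprod(D2)
  trend <- as.numeric(Matrix::solve(A, x))
  x - trend
}

#' Centered moving average with shrinking edge windows
#'
#' Window shrinks near the edges to the available samples (no padding), so
#' no phantom edge trend is introduced.  `window = 1` is the identity.
#'
#' @param x numeric vector.
#' @param window odd window width in samples, <= `length(x)`.
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(x, window) {
  n <- length(x)
  if (window > n) stop("moving_average: window larger than series")
  if (window %% 2L != 1L) stop("moving_average: window must be odd")
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Zero-phase Butterworth band-pass
#'
#' Forward-backward (zero-phase) Butterworth filter restricted to the
#' pulse band.  The residual numerical DC offset left by finite-length
#' filtering is removed, so the output mean is exactly zero.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param band_lo,band_hi band edges, Hz; must satisfy
#'   `0 < band_lo < band_hi < fs/2`.
#' @param order band-pass filter order (even).
#' @return filtered vector, same length.
#' @export
bandpass <- function(x, fs, band_lo = 0.65, band_hi = 4, order = 4L) {
  if (!(band_lo > 0 && band_lo < band_hi && band_hi < fs / 2))
    stop("bandpass: need 0 < band_lo < band_hi < fs/2")
  if (order %% 2L != 0L) stop("bandpass: order must be even")
  bf <- signal::butter(order %/% 2L, c(band_lo, band_hi) / (fs / 2),
                       type = "pass")
  y <- as.numeric(signal::filtfilt(bf, x))
  y - mean(y)
}

#' Preprocess a raw RGB trace
#'
#' Applies, per channel: smoothness-priors detrending, moving average,
#' band-pass.  The chain is linear, removes trend and DC, and preserves
#' the pulse band.
#'
#' @param trace an [rgb_trace] with `stage = "raw"`.
#' @param config a [filter_config].
#' @return an [rgb_trace] with `stage = "preprocessed"`.
#' @export
preprocess_trace <- function(trace, config = filter_config()) {
  stopifnot(inherits(trace, "rgb_trace"))
  chain <- function(x) {
    x <- spa_detrend(x, config$spa_lambda)
    x <- moving_average(x, config$ma_window)
    bandpass(x, trace$fs, config$band_lo, config$band_hi, config$bp_order)
  }
  out <- structure(list(t = trace$t, r = chain(trace$r), g = chain(trace$g),
                        b = chain(trace$b), fs = trace$fs,
                        stage = "preprocessed"),
                   class = "rgb_trace")
  out
}

# ---------------------------------------------------------------------
# Continuous wavelet filter (adaptive two-step)

# Morlet CWT on a log-spaced scale grid, via FFT (Torrence & Compo
# normalization).  Returns the coefficient matrix (scales x time) and the
# grid; `fourier_factor` converts scale to Fourier period.
morlet_cwt <- function(x, fs, n_scales = 32L, f_lo = 0.5, f_hi = 5,
                       omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  periods <- 1 / exp(seq(log(f_hi), log(f_lo), length.out = n_scales))
  scales <- periods / fourier_factor
  npad <- 2^ceiling(log2(n))
  xh <- stats::fft(c(x - mean(x), rep(0, npad - n)))
  k <- c(seq(0, floor(npad / 2)), seq(-(ceiling(npad / 2) - 1), -1))
  omega <- 2 * pi * k / (npad * dt)
  W <- matrix(0 + 0i, n_scales, n)
  for (j in seq_len(n_scales)) {
    s <- scales[j]
    psi_hat <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega - omega0)^2 / 2) * (omega > 0)
    W[j, ] <- stats::fft(xh * psi_hat, inverse = TRUE)[seq_len(n)] / npad
  }
  list(W = W, scales = scales, freqs = 1 / periods, dj = diff(log2(periods))[1],
       dt = dt, omega0 = omega0)
}

# Delta-function reconstruction from (possibly weighted) Morlet
# coefficients.
morlet_icwt <- function(cw) {
  c_delta <- 0.776                       # Morlet, omega0 = 6
  psi0 <- pi^(-0.25)
  fac <- cw$dj * sqrt(cw$dt) / (c_delta * psi0)
  fac * colSums(Re(cw$W) / sqrt(cw$scales))
}

#' Adaptive two-step wavelet filter
#'
#' Step one: a Morlet continuous wavelet transform is taken and, within a
#' temporal running window, the scale of maximum average squared
#' coefficient energy is located; coefficients are weighted by a wide
#' Gaussian window in scale centered on that ridge.  Step two: the weight
#' map is smoothed with a general Gaussian filter along time.  The signal
#' is rebuilt by the inverse transform.  Noise at scales away from the
#' pulse ridge is attenuated while the dominant in-band frequency is
#' preserved.
#'
#' @param x numeric pulse signal.
#' @param fs sampling rate, Hz.
#' @param wavelet_window running-window length, seconds (default 15);
#'   inputs shorter than the window use their full duration.
#' @param scale_sd Gaussian scale-window SD, octaves.
#' @param time_sd SD of the second (temporal) Gaussian smoothing, seconds.
#' @param n_scales,f_lo,f_hi scale grid: count and frequency coverage, Hz.
#' @return filtered vector, same length as `x`.
#' @export
wavelet_filter <- function(x, fs, wavelet_window = 15, scale_sd = 1,
                           time_sd = 2, n_scales = 32L, f_lo = 0.5,
                           f_hi = 5) {
  n <- length(x)
  if (n < 2 * fs / f_hi + 2)
    stop("wavelet_filter: input shorter than two pulse periods")
  if (all(x == 0)) return(x)
  cw <- morlet_cwt(x, fs, n_scales = n_scales, f_lo = f_lo, f_hi = f_hi)
  E <- Re(cw$W)^2 + Im(cw$W)^2
  win <- min(n, max(3L, round(wavelet_window * fs)))
  if (win %% 2L == 0L) win <- win - 1L
  Ebar <- t(apply(E, 1L, moving_average, window = win))
  ridge <- apply(Ebar, 2L, which.max)
  log2s <- log2(cw$scales)
  # Gaussian weight in scale around the per-sample ridge
  Wgt <- exp(-(outer(log2s, log2s[ridge], "-"))^2 / (2 * scale_sd^2))
  # second step: general Gaussian smoothing of the weight map along time
  tk <- round(3 * time_sd * fs)
  if (tk >= 1L) {
    kern <- stats::dnorm(seq(-tk, tk), sd = time_sd * fs)
    kern <- kern / sum(kern)
    Wgt <- t(apply(Wgt, 1L, function(row) {
      padded <- c(rep(row[1L], tk), row, rep(row[length(row)], tk))
      stats::convolve(padded, rev(kern), type = "filter")
    }))
  }
  cw$W <- cw$W * Wgt
  morlet_icwt(cw)
}

# ---------------------------------------------------------------------
# Empirical mode decomposition

# Indices of strict local maxima / minima (simple plateau handling: first
# sample of a plateau counts).
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(), min = integer()))
  d <- diff(x)
  d[d == 0] <- .Machine$double.eps  # break plateaus deterministically
  s <- sign(d)
  idx <- which(diff(s) != 0) + 1L
  list(max = idx[s[idx - 1L] > 0], min = idx[s[idx - 1L] < 0])
}

# Cubic-spline envelope through extrema, with end conditions taken from
# the signal endpoints to limit edge swings.
spline_envelope <- function(idx, x) {
  n <- length(x)
  xi <- c(1L, idx, n)
  yi <- c(x[1L], x[idx], x[n])
  o <- !duplicated(xi)
  stats::spline(xi[o], yi[o], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Classic sifting: upper and lower cubic-spline envelopes through the
#' local extrema, subtract the envelope mean, repeat until a Cauchy-type
#' criterion (`SD < 0.3`) or the sifting cap is hit; the mode is removed
#' and sifting restarts on the remainder until the residue is monotone or
#' the mode cap is reached.  The decomposition is complete by
#' construction: the modes and residue sum back to the input to floating
#' point accuracy.
#'
#' @param x numeric vector, length >= 10, finite.
#' @param max_imfs cap on the number of modes.
#' @param max_siftings sifting cap per mode.
#' @param sd_stop Cauchy stop threshold.
#' @return list of class `imf_set`: `imfs` (list of vectors, possibly
#'   empty) and `residue`.
#' @export
emd_decompose <- function(x, max_imfs = 10L, max_siftings = 10L,
                          sd_stop = 0.3) {
  if (length(x) < 10L) stop("emd_decompose: need at least 10 samples")
  if (!all(is.finite(x))) stop("emd_decompose: non-finite input")
  residue <- x
  imfs <- list()
  for (i in seq_len(max_imfs)) {
    ex <- local_extrema(residue)
    if (length(ex$max) < 2L || length(ex$min) < 2L) break  # monotone-ish
    h <- residue
    for (s in seq_len(max_siftings)) {
      ex <- local_extrema(h)
      if (length(ex$max) < 2L || length(ex$min) < 2L) break
      m <- (spline_envelope(ex$max, h) + spline_envelope(ex$min, h)) / 2
      h_new <- h - m
      sd_c <- sum(m^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      if (sd_c < sd_stop) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residue <- residue - h
  }
  structure(list(imfs = imfs, residue = residue), class = "imf_set")
}

#' Select the pulse-band intrinsic mode function
#'
#' Returns the single mode whose spectral peak lies inside the pulse band
#' and whose in-band prominence (in-band peak power over total mode power)
#' is maximal.  When no mode qualifies the band-passed reconstruction of
#' the input is returned unchanged, with a warning.
#'
#' @param imfset an `imf_set` from [emd_decompose].
#' @param fs sampling rate, Hz.
#' @param band `c(lo, hi)` pulse band, Hz.
#' @return numeric vector (the selected mode or the fallback).
#' @export
select_pulse_imf <- function(imfset, fs, band = c(0.65, 4)) {
  stopifnot(inherits(imfset, "imf_set"))
  reconstruct <- function() {
    out <- imfset$residue
    for (m in imfset$imfs) out <- out + m
    out
  }
  if (length(imfset$imfs) == 0L) {
    warning("select_pulse_imf: no modes; passing residue through")
    return(imfset$residue)
  }
  scores <- vapply(imfset$imfs, function(m) {
    pr <- inband_prominence(m, fs, band)
    if (pr$in_band) pr$score else 0
  }, numeric(1))
  if (all(scores <= 0)) {
    warning("select_pulse_imf: no mode peaks in band; returning band-passed input")
    return(bandpass(reconstruct(), fs, band[1], band[2]))
  }
  imfset$imfs[[which.max(scores)]]
}

#' Outlier suppression
#'
#' A final moving-average pass that smooths out residual high-frequency
#' peaks in the extracted pulse signal.  Identical contract to
#' [moving_average].
#'
#' @inheritParams moving_average
#' @export
suppress_outliers <- function(x, window) moving_average(x, window)

#' Postprocess an extracted pulse signal
#'
#' Chain: adaptive wavelet filter, band-pass, empirical mode
#' decomposition with pulse-mode selection, outlier suppression.
#'
#' @param sig an [ippg_signal] (or numeric vector with `fs` given).
#' @param fs sampling rate; taken from `sig` when it is an `ippg_signal`.
#' @param config a [filter_config].
#' @return object of the same kind as `sig` with filtered values.
#' @export
postprocess_ippg <- function(sig, fs = NULL, config = filter_config()) {
  is_obj <- inherits(sig, "ippg_signal")
  x <- if (is_obj) sig$values else sig
  if (is_obj) fs <- sig$fs
  if (is.null(fs)) stop("postprocess_ippg: fs required")
  x <- wavelet_filter(x, fs, wavelet_window = config$wavelet_window)
  x <- bandpass(x, fs, config$band_lo, config$band_hi, config$bp_order)
  dec <- emd_decompose(x, max_imfs = config$emd_max_imfs)
  x <- select_pulse_imf(dec, fs, c(config$band_lo, config$band_hi))
  x <- suppress_outliers(x, config$ma_window)
  if (is_obj) {
    sig$values <- x
    sig
  } else x
}
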