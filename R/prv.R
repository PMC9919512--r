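# Pulse-rate and pulse-rate-variability analysis: systolic-peak
# detection, ectopic correction into a normal-to-normal interval series,
# and the 14 features in the time, frequency and nonlinear domains.

#' Detect systolic peaks
#'
#' Local maxima exceeding an adaptive prominence threshold: a fraction of
#' the rolling 90th-percentile amplitude over a sliding window, with a
#' minimum peak separation of 0.25 s (the 4 Hz pulse-rate ceiling).
#'
#' @param sig polarity-oriented [ippg_signal] or numeric vector.
#' @param fs sampling rate (taken from `sig` when it is an
#'   `ippg_signal`).
#' @param min_distance_s minimum separation between peaks, seconds.
#' @param prominence_frac threshold as a fraction of the rolling
#'   90th-percentile amplitude.
#' @param window_s rolling window for the adaptive threshold, seconds.
#' @return list of class `peak_series`: `indices` (1-based sample
#'   indices), `times_s`, `fs`.
#' @export
detect_peaks <- function(sig, fs = NULL, min_distance_s = 0.25,
                         prominence_frac = 0.3, window_s = 10) {
  if (inherits(sig, "ippg_signal")) { fs <- sig$fs; x <- sig$values }
  else x <- as.numeric(sig)
  if (is.null(fs)) stop("detect_peaks: fs required")
  n <- length(x)
  if (n < 2 * fs) stop("detect_peaks: need at least 2 s of signal")
  # candidate local maxima
  d <- diff(x)
  d[d == 0] <- .Machine$double.eps
  s <- sign(d)
  cand <- which(diff(s) < 0) + 1L
  # topographic prominence: height above the higher of the two valley
  # minima separating the peak from the nearest higher peaks (or the
  # signal ends).  Suppresses dicrotic bumps riding on the pulse wave.
  prom <- vapply(seq_along(cand), function(j) {
    i <- cand[j]
    hj <- x[i]
    left <- cand[cand < i & x[cand] > hj]
    lo_l <- if (length(left)) min(x[max(left):i]) else min(x[1:i])
    right <- cand[cand > i & x[cand] > hj]
    lo_r <- if (length(right)) min(x[i:min(right)]) else min(x[i:n])
    hj - max(lo_l, lo_r)
  }, numeric(1))
  # adaptive threshold: rolling upper-quantile amplitude, sampled at 1 s
  # anchors and interpolated
  half <- round(window_s * fs / 2)
  anchors <- unique(c(seq(1L, n, by = max(1L, round(fs))), n))
  q <- vapply(anchors, function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    stats::quantile(w, 0.9, names = FALSE)
  }, numeric(1))
  thr <- prominence_frac *
    stats::approx(anchors, q, xout = seq_len(n), rule = 2)$y
  keep_cand <- prom > thr[cand] & x[cand] > 0
  cand <- cand[keep_cand]
  # enforce minimum distance, keeping higher peaks first
  min_d <- round(min_distance_s * fs)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_d)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  if (length(kept) < 2L)
    stop("detect_peaks: fewer than 2 peaks found")
  structure(list(indices = kept, times_s = (kept - 1L) / fs, fs = fs),
            class = "peak_series")
}

#' Convert peaks to an artifact-corrected NN series
#'
#' Interbeat intervals are the successive peak-time differences in ms.
#' Intervals deviating more than `max_dev` from the running five-interval
#' median, or falling outside the physiological range, are treated as
#' ectopic and replaced by cubic-spline interpolation over the remaining
#' intervals (a documented approximation of interactive correction tools,
#' not a clone of any).  More than `max_flag_frac` flagged intervals is a
#' corrupt-signal error.
#'
#' @param peaks a `peak_series` from [detect_peaks].
#' @param max_dev relative deviation from the running median that flags
#'   an interval (default 0.3).
#' @param max_flag_frac maximum tolerated fraction of flagged intervals.
#' @param nn_range admissible NN range after correction, ms.
#' @return an [nn_series].
#' @export
peaks_to_nn <- function(peaks, max_dev = 0.3, max_flag_frac = 0.2,
                        nn_range = c(250, 1540)) {
  stopifnot(inherits(peaks, "peak_series"))
  if (length(peaks$indices) < 3L)
    stop("peaks_to_nn: need at least 3 peaks")
  ibi <- diff(peaks$times_s) * 1000
  k <- min(5L, length(ibi))
  if (k %% 2L == 0L) k <- k - 1L
  med <- stats::runmed(ibi, k = k, endrule = "median")
  flagged <- abs(ibi - med) / med > max_dev |
    ibi < nn_range[1] | ibi > nn_range[2]
  if (mean(flagged) > max_flag_frac)
    stop(sprintf("peaks_to_nn: %.0f%% of intervals flagged; signal too corrupt",
                 100 * mean(flagged)))
  nn <- ibi
  if (any(flagged)) {
    good <- which(!flagged)
    if (length(good) < 4L) stop("peaks_to_nn: too few clean intervals")
    nn[flagged] <- stats::spline(good, ibi[good], method = "fmm",
                                 xout = which(flagged))$y
    nn <- pmin(pmax(nn, nn_range[1]), nn_range[2])
  }
  nn_series(nn, peaks$times_s[-1L], corrected_count = sum(flagged))
}

#' Time-domain features
#'
#' * `PR`: mean of the instantaneous rate `60000 / NN_i`, 1/min.
#' * `RMSSD`: root mean square of successive interval differences, ms.
#' * `SDNN`: standard deviation of the intervals (N-1 denominator), ms.
#' * `TI`: triangular index, interval count over the maximum histogram
#'   bin count (bin width 1/128 s).
#' * `TINN`: baseline width of the best least-squares triangular fit to
#'   the interval histogram, ms.
#'
#' @param nn an [nn_series] (>= 4 intervals).
#' @param bin_ms histogram bin width in ms (1000/128 by convention).
#' @return named list with `PR`, `RMSSD`, `SDNN`, `TI`, `TINN`.
#' @export
time_features <- function(nn, bin_ms = 1000 / 128) {
  x <- nn$intervals_ms
  if (length(x) < 4L) stop("time_features: need at least 4 intervals")
  pr <- mean(60000 / x)
  rmssd <- sqrt(mean(diff(x)^2))
  sdnn <- stats::sd(x)
  # histogram on bin-aligned breaks
  breaks <- seq(floor(min(x) / bin_ms) * bin_ms,
                ceiling(max(x) / bin_ms) * bin_ms + bin_ms, by = bin_ms)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  ti <- length(x) / max(h$counts)
  tinn <- tinn_fit(h, bin_ms)
  list(PR = pr, RMSSD = rmssd, SDNN = sdnn, TI = ti, TINN = tinn)
}

# Exhaustive least-squares triangular interpolation of the NN histogram:
# triangle rises from 0 at N to the mode count at the mode bin center and
# falls back to 0 at M, with N and M on bin edges.  Returns M - N in ms.
tinn_fit <- function(h, bin_ms) {
  counts <- h$counts
  centers <- h$mids
  edges <- h$breaks
  m <- which.max(counts)
  cm <- centers[m]
  y <- max(counts)
  n_cand <- edges[edges < cm]
  m_cand <- edges[edges > cm]
  best <- c(err = Inf, width = bin_ms)
  for (N in n_cand) for (M in m_cand) {
    tri <- ifelse(centers <= cm,
                  pmax(0, y * (centers - N) / (cm - N)),
                  pmax(0, y * (M - centers) / (M - cm)))
    tri[centers < N | centers > M] <- 0
    err <- sum((counts - tri)^2)
    if (err < best["err"]) best <- c(err = err, width = M - N)
  }
  unname(best["width"])
}

# Welch power spectral density: Hann window, mean removal per segment,
# one-sided scaling in x-units^2 per Hz.
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, round(32 * fs))
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  U <- sum(w^2)
  acc <- numeric(seg_len)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + abs(stats::fft(seg))^2
  }
  P <- acc / (length(starts) * fs * U)
  m <- floor(seg_len / 2)
  P1 <- P[seq_len(m + 1L)]
  if (m >= 2L) P1[2:m] <- 2 * P1[2:m]
  list(freq = (seq_len(m + 1L) - 1L) * fs / seg_len, psd = P1)
}

# Integral of the linear interpolant of the PSD over [lo, hi).
band_power <- function(freq, psd, lo, hi, n_grid = 400L) {
  lo <- max(lo, freq[2] * 1e-9, freq[1])
  hi <- min(hi, max(freq))
  if (hi <= lo) return(0)
  g <- seq(lo, hi, length.out = n_grid)
  y <- stats::approx(freq, psd, xout = g, rule = 2)$y
  sum(diff(g) * (y[-1] + y[-n_grid]) / 2)
}

#' Frequency-domain features
#'
#' The NN series is cubic-spline resampled onto a uniform 4 Hz grid along
#' the beat-time axis, mean-removed, and its Welch spectrum (Hann
#' window, segments of at most 32 s, 50% overlap) integrated over the
#' very-low (0.0033-0.04 Hz), low (0.04-0.15 Hz) and high (0.15-0.4 Hz)
#' frequency bands by the trapezoid rule.
#'
#' @param nn an [nn_series] spanning at least 30 s of beats.
#' @param resample_fs uniform resampling rate, Hz.
#' @return named list: `VLF`, `LF`, `HF` (ms^2), `LF_HF`, `LFnu`, `HFnu`.
#' @export
freq_features <- function(nn, resample_fs = 4) {
  tb <- nn$beat_times_s
  span <- max(tb) - min(tb)
  if (span < 30) stop("freq_features: need at least 30 s of beats")
  grid <- seq(min(tb), max(tb), by = 1 / resample_fs)
  xr <- stats::spline(tb, nn$intervals_ms, xout = grid, method = "fmm")$y
  xr <- xr - mean(xr)
  sp <- welch_psd(xr, resample_fs)
  vlf <- band_power(sp$freq, sp$psd, 0.0033, 0.04)
  lf <- band_power(sp$freq, sp$psd, 0.04, 0.15)
  hf <- band_power(sp$freq, sp$psd, 0.15, 0.40)
  list(VLF = vlf, LF = lf, HF = hf,
       LF_HF = lf / hf, LFnu = lf / (lf + hf), HFnu = hf / (lf + hf))
}

#' Poincare-map features
#'
#' Dispersion of the lag-1 return map `(NN_i, NN_(i+1))` by the
#' ellipse-fitting identities: `SD1` is the standard deviation
#' perpendicular to the identity line, `SD2` along it (both N-1
#' denominators).  A zero `SD2` yields an undefined (`NA`) ratio rather
#' than an error.
#'
#' @param nn an [nn_series] (>= 3 intervals).
#' @return named list: `SD1`, `SD2` (ms), `SD1_SD2`.
#' @export
poincare <- function(nn) {
  x <- nn$intervals_ms
  if (length(x) < 3L) stop("poincare: need at least 3 intervals")
  a <- x[-length(x)]
  b <- x[-1L]
  sd1 <- stats::sd((a - b) / sqrt(2))
  sd2 <- stats::sd((a + b) / sqrt(2))
  list(SD1 = sd1, SD2 = sd2,
       SD1_SD2 = if (sd2 == 0) NA_real_ else sd1 / sd2)
}

#' All 14 PRV features of one recording
#'
#' @param nn an [nn_series].
#' @return object of class `prv_features`: the named features plus
#'   `meta` (corrected interval count, beat count, span, and a flag
#'   marking the VLF power as unreliable for recordings much shorter
#'   than the VLF period).
#' @export
prv_features <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  tf <- time_features(nn)
  ff <- freq_features(nn)
  pc <- poincare(nn)
  span <- max(nn$beat_times_s) - min(nn$beat_times_s)
  structure(c(tf, ff, pc,
              list(meta = list(n_beats = length(nn$intervals_ms) + 1L,
                               corrected_count = nn$corrected_count,
                               span_s = span,
                               vlf_unreliable = span < 300))),
            class = "prv_features")
}

#' @export
print.prv_features <- function(x, ...) {
  cat("<prv_features>\n")
  for (nm in PRV_FEATURE_NAMES)
    cat(sprintf("  %-8s %.4g\n", nm, x[[nm]]))
  cat(sprintf("  (%d beats, %d corrected, %.1f s%s)\n",
              x$meta$n_beats, x$meta$corrected_count, x$meta$span_s,
              if (x$meta$vlf_unreliable) ", VLF unreliable" else ""))
  invisible(x)
}

#' @export
as.data.frame.prv_features <- function(x, ...) {
  as.data.frame(x[PRV_FEATURE_NAMES])
}

#' Serialize PRV features
#'
#' `write_prv_features` writes a one-row CSV (or JSON when the path ends
#' in `.json`, including the metadata).
#'
#' @param features a [prv_features].
#' @param path output path, `.csv` or `.json`.
#' @export
write_prv_features <- function(features, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(c(features[PRV_FEATURE_NAMES],
                           list(meta = features$meta)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(features), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Full pulse-signal to features path
#'
#' Convenience wrapper: peak detection, NN correction, features.
#'
#' @param sig polarity-oriented [ippg_signal].
#' @param ... passed to [detect_peaks].
#' @return a [prv_features].
#' @export
signal_to_prv <- function(sig, ...) {
  prv_features(peaks_to_nn(detect_peaks(sig, ...)))
}
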