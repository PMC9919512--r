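#' @keywords internal
"_PACKAGE"

#' Per-frame averaged RGB trace
#'
#' The central carrier of the pipeline: spatially averaged red, green and
#' blue intensities of the skin pixels inside the face region, one sample
#' per video frame.  A raw trace (`stage = "raw"`) holds native 8-bit
#' intensities in \[0, 255\]; after detrending and filtering
#' (`stage = "preprocessed"`) the values are unit-free and zero-mean.
#'
#' @param r,g,b numeric vectors of equal length (>= 2), channel means.
#' @param fs sampling rate in Hz (frames per second), > 0.
#' @param stage `"raw"` or `"preprocessed"`.
#' @param t optional time axis in seconds; defaults to `(0:(n-1))/fs`.
#' @return An object of class `rgb_trace`: a list with elements
#'   `t`, `r`, `g`, `b`, `fs`, `stage`.
#' @export
rgb_trace <- function(r, g, b, fs, stage = c("raw", "preprocessed"), t = NULL) {
  stage <- match.arg(stage)
  n <- length(r)
  if (n < 2L || length(g) != n || length(b) != n)
    stop("rgb_trace: channels must have equal length >= 2")
  if (!all(is.finite(r), is.finite(g), is.finite(b)))
    stop("rgb_trace: non-finite channel values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("rgb_trace: fs must be a positive scalar (Hz)")
  if (stage == "raw") {
    rng <- range(r, g, b)
    if (rng[1] < 0 || rng[2] > 255)
      stop("rgb_trace: raw intensities must lie in [0, 255]")
  }
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  structure(list(t = as.numeric(t), r = as.numeric(r), g = as.numeric(g),
                 b = as.numeric(b), fs = fs, stage = stage),
            class = "rgb_trace")
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat(sprintf("<rgb_trace> %d samples @ %.6g Hz (%.1f s), stage=%s\n",
              length(x$r), x$fs, length(x$r) / x$fs, x$stage))
  invisible(x)
}

#' @export
length.rgb_trace <- function(x) length(x$r)

#' Read / write an RGB trace as CSV
#'
#' The on-disk format is a plain CSV with header `t,r,g,b`, one row per
#' frame, `.` as decimal separator.
#'
#' @param path file path.
#' @param stage trace stage recorded in the returned object.
#' @param fs optional sampling rate; inferred from the median spacing of
#'   the `t` column when omitted.
#' @return `read_rgb_trace` returns an [rgb_trace]; `write_rgb_trace`
#'   returns `path` invisibly.
#' @export
read_rgb_trace <- function(path, stage = "raw", fs = NULL) {
  d <- utils::read.csv(path)
  need <- c("t", "r", "g", "b")
  if (!all(need %in% names(d)))
    stop("RGB trace CSV must have columns t,r,g,b: ", path)
  if (is.null(fs)) {
    dt <- stats::median(diff(d$t))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer fs from t column")
    fs <- 1 / dt
    # snap to integer frame rates blurred by decimal round-tripping
    if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  }
  rgb_trace(d$r, d$g, d$b, fs = fs, stage = stage, t = d$t)
}

#' @rdname read_rgb_trace
#' @param trace an [rgb_trace].
#' @export
write_rgb_trace <- function(trace, path) {
  utils::write.csv(data.frame(t = trace$t, r = trace$r, g = trace$g,
                              b = trace$b),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extracted pulse signal
#'
#' One-dimensional blood-volume-pulse signal extracted from an RGB trace,
#' labelled with the extraction method.  The polarity convention is
#' systolic-peak-up; `polarity_oriented` records whether the orientation
#' step has been applied (sign-ambiguous decompositions need it).
#'
#' @param values numeric vector, unit-free pulse signal.
#' @param fs sampling rate, Hz.
#' @param method method label, one of
#'   `"GRD","AGRD","PCA","ICA","LE","SPE","CHROM","POS"` (or `"REF"` for a
#'   contact reference resampled onto a uniform grid).
#' @param polarity_oriented logical flag.
#' @return An object of class `ippg_signal`.
#' @export
ippg_signal <- function(values, fs, method, polarity_oriented = FALSE) {
  if (!all(is.finite(values))) stop("ippg_signal: non-finite values")
  structure(list(values = as.numeric(values), fs = fs, method = method,
                 polarity_oriented = isTRUE(polarity_oriented)),
            class = "ippg_signal")
}

#' @export
print.ippg_signal <- function(x, ...) {
  cat(sprintf("<ippg_signal> method=%s, %d samples @ %.6g Hz%s\n",
              x$method, length(x$values), x$fs,
              if (x$polarity_oriented) ", oriented" else ""))
  invisible(x)
}

#' Artifact-corrected interbeat-interval series
#'
#' Normal-to-normal (NN) intervals in milliseconds together with the beat
#' times of the interval endpoints, after ectopic-beat correction.
#'
#' @param intervals_ms NN intervals, ms.
#' @param beat_times_s time of the beat closing each interval, seconds.
#' @param corrected_count number of intervals replaced by interpolation.
#' @return An object of class `nn_series`.
#' @export
nn_series <- function(intervals_ms, beat_times_s, corrected_count = 0L) {
  n <- length(intervals_ms)
  if (length(beat_times_s) != n)
    stop("nn_series: intervals and beat times must align")
  if (n && any(intervals_ms <= 0)) stop("nn_series: non-positive interval")
  structure(list(intervals_ms = as.numeric(intervals_ms),
                 beat_times_s = as.numeric(beat_times_s),
                 corrected_count = as.integer(corrected_count)),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d intervals, mean %.1f ms, %d corrected\n",
              length(x$intervals_ms), mean(x$intervals_ms),
              x$corrected_count))
  invisible(x)
}

#' Write an NN series as CSV (`t_beat_s,nn_ms`)
#' @param nn an [nn_series].
#' @param path file path.
#' @export
write_nn_series <- function(nn, path) {
  utils::write.csv(data.frame(t_beat_s = nn$beat_times_s,
                              nn_ms = nn$intervals_ms),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Canonical order of the 14 pulse-rate-variability features.
PRV_FEATURE_NAMES <- c("PR", "RMSSD", "SDNN", "TI", "TINN",
                       "VLF", "LF", "HF", "LF_HF", "LFnu", "HFnu",
                       "SD1", "SD2", "SD1_SD2")

#' The eight supported extraction method names
#' @export
IPPG_METHODS <- c("GRD", "AGRD", "PCA", "ICA", "LE", "SPE", "CHROM", "POS")
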