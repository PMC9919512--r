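# Small FFT-based spectral utilities shared by the conditioning,
# extraction and PRV modules.

#' One-sided periodogram
#'
#' @param x numeric vector (mean is removed before transforming).
#' @param fs sampling rate, Hz.
#' @return list with `freq` (Hz) and `power` (periodogram ordinates).
#' @export
periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  sp <- abs(stats::fft(x))^2 / n
  m <- floor(n / 2)
  list(freq = (seq_len(m + 1L) - 1L) * fs / n, power = sp[seq_len(m + 1L)])
}

#' Dominant frequency of a signal
#'
#' Frequency of the largest periodogram ordinate, optionally restricted to
#' a band.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param band optional `c(lo, hi)` in Hz.
#' @return frequency in Hz (resolution `fs/length(x)`).
#' @export
dominant_frequency <- function(x, fs, band = NULL) {
  p <- periodogram(x, fs)
  keep <- if (is.null(band)) p$freq > 0 else
    p$freq >= band[1] & p$freq <= band[2]
  if (!any(keep)) return(NA_real_)
  p$freq[keep][which.max(p$power[keep])]
}

# In-band spectral prominence: largest in-band periodogram ordinate
# divided by total power.  Used to pick the pulse component among
# decomposition outputs.  Returns 0 when the spectral peak itself lies
# outside the band.
inband_prominence <- function(x, fs, band) {
  p <- periodogram(x, fs)
  tot <- sum(p$power)
  if (tot <= 0) return(list(score = 0, peak_freq = NA_real_, in_band = FALSE))
  keep <- p$freq >= band[1] & p$freq <= band[2] & p$freq > 0
  if (!any(keep)) return(list(score = 0, peak_freq = NA_real_, in_band = FALSE))
  pk_all <- which.max(p$power[p$freq > 0]) # global peak (excluding DC)
  f_all <- p$freq[p$freq > 0][pk_all]
  pk <- which.max(p$power[keep])
  list(score = max(p$power[keep]) / tot,
       peak_freq = p$freq[keep][pk],
       in_band = f_all >= band[1] && f_all <= band[2])
}
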