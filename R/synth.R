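# Seeded synthetic fixtures: NN series with prescribed variability, pulse
# waveforms, skin-coupled RGB traces and rendered face videos.  Every
# generator is deterministic given the seed in the config.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic cardiovascular fixture generator
#'
#' Defaults emulate a webcam acquisition (30 fps, 8-bit RGB) of a resting
#' adult: mean pulse rate 72 bpm, low-frequency (Mayer-wave range) and
#' high-frequency (respiratory range) sinusoidal modulation of the
#' interbeat intervals plus broadband beat-to-beat jitter, green-dominant
#' pulsatile coupling into the colour channels, white sensor noise, a slow
#' illumination drift, and optional step-like motion artifacts.
#'
#' @param seed integer RNG seed.
#' @param fs frame rate, Hz.
#' @param duration recording length, seconds (>= 30).
#' @param mean_pr mean pulse rate, beats/min; `mean_pr/60` must lie in the
#'   physiological pulse band \[0.65, 4\] Hz.
#' @param lf_freq,lf_amp low-frequency interval modulation: frequency in
#'   \[0.04, 0.15) Hz and amplitude in ms.
#' @param hf_freq,hf_amp high-frequency modulation: frequency in
#'   \[0.15, 0.4) Hz and amplitude in ms.
#' @param jitter_sd SD of white beat-to-beat jitter, ms.
#' @param coupling named numeric `c(r=,g=,b=)`: pulsatile amplitude of each
#'   channel in intensity units (green strongest by default; the pulse is
#'   subtracted from the baseline, as more blood absorbs more light).
#' @param baseline named numeric, resting skin-tone intensities in
#'   \[0, 255\].
#' @param noise_sd SD of additive white sensor noise, intensity units.
#' @param trend_amp amplitude of the slow illumination drift, intensity
#'   units.
#' @param motion_events list of `c(time, duration, amplitude)` triplets:
#'   step offsets applied to all channels simultaneously (intensity-like
#'   artifacts that projection methods such as POS should reject).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, fs = 30, duration = 60, mean_pr = 72,
                         lf_freq = 0.1, lf_amp = 40,
                         hf_freq = 0.25, hf_amp = 25,
                         jitter_sd = 10,
                         coupling = c(r = 0.4, g = 1.0, b = 0.6),
                         baseline = c(r = 200, g = 140, b = 110),
                         noise_sd = 0.05, trend_amp = 2,
                         motion_events = list()) {
  pr_hz <- mean_pr / 60
  if (pr_hz < 0.65 || pr_hz > 4)
    stop("mean_pr must lie in the pulse band 39-240 bpm")
  if (lf_amp > 0 && (lf_freq < 0.04 || lf_freq >= 0.15))
    stop("lf_freq must lie in [0.04, 0.15) Hz")
  if (hf_amp > 0 && (hf_freq < 0.15 || hf_freq >= 0.4))
    stop("hf_freq must lie in [0.15, 0.4) Hz")
  if (duration < 30)
    stop("duration must be >= 30 s (frequency-domain truth is undefined below)")
  stopifnot(fs > 0, jitter_sd >= 0, noise_sd >= 0, trend_amp >= 0)
  structure(list(seed = as.integer(seed), fs = fs, duration = duration,
                 mean_pr = mean_pr, lf_freq = lf_freq, lf_amp = lf_amp,
                 hf_freq = hf_freq, hf_amp = hf_amp, jitter_sd = jitter_sd,
                 coupling = coupling, baseline = baseline,
                 noise_sd = noise_sd, trend_amp = trend_amp,
                 motion_events = motion_events),
            class = "synth_config")
}

#' Generate a ground-truthed NN-interval series
#'
#' Interval model: `NN_i = 60000/mean_pr + lf_amp sin(2 pi lf_freq t_i)
#' + hf_amp sin(2 pi hf_freq t_i) + jitter_i`, with `t_i` the opening beat
#' time and jitter white Gaussian.  Beat times accumulate until
#' `duration` is reached.
#'
#' Alongside the realized series the generator reports its own truth
#' bookkeeping.  `mean_pr`, `sdnn` and `rmssd` are the definitional true
#' values of the realized series (for a given finite series the true
#' SDNN *is* the standard deviation of its intervals); `sdnn_expected`
#' and `rmssd_expected` are the closed-form ensemble expectations of the
#' interval model (sinusoidal modes contribute `amp^2/2` variance; white
#' jitter spreads its variance uniformly up to the beat Nyquist
#' frequency), around which realized values fluctuate by a few percent
#' at a few hundred beats.  Band shares are ensemble values.
#'
#' @param config a [synth_config].
#' @return list with elements `nn` ([nn_series]), `beat_times_s`
#'   (including the opening beat), and `truth` (named list: `mean_pr`,
#'   `sdnn`, `rmssd`, `sdnn_expected`, `rmssd_expected`, `lfnu`, `hfnu`,
#'   `lf_share`, `hf_share`).
#' @export
generate_nn <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  t0_ms <- 60000 / config$mean_pr
  with_seed(config$seed, {
    # generous upper bound on beat count
    n_max <- ceiling(config$duration / (t0_ms / 1000)) + 50L
    jit <- stats::rnorm(n_max, 0, config$jitter_sd)
    t_beat <- numeric(n_max + 1L)
    nn <- numeric(n_max)
    i <- 0L
    t_cur <- 0
    while (t_cur < config$duration && i < n_max) {
      i <- i + 1L
      nn_i <- t0_ms +
        config$lf_amp * sin(2 * pi * config$lf_freq * t_cur) +
        config$hf_amp * sin(2 * pi * config$hf_freq * t_cur) +
        jit[i]
      nn_i <- max(nn_i, 250)  # physiological floor
      nn[i] <- nn_i
      t_cur <- t_cur + nn_i / 1000
      t_beat[i + 1L] <- t_cur
    }
    nn <- nn[seq_len(i)]
    t_beat <- t_beat[seq_len(i + 1L)]
  })

  tbar_s <- t0_ms / 1000
  var_lf <- config$lf_amp^2 / 2
  var_hf <- config$hf_amp^2 / 2
  var_j <- config$jitter_sd^2
  sdnn_true <- sqrt(var_lf + var_hf + var_j)
  rmssd_true <- sqrt(2 * config$lf_amp^2 * sin(pi * config$lf_freq * tbar_s)^2 +
                     2 * config$hf_amp^2 * sin(pi * config$hf_freq * tbar_s)^2 +
                     2 * var_j)
  # white jitter spectral share inside each analysis band
  f_nyq <- 1 / (2 * tbar_s)
  j_lf <- var_j * (0.15 - 0.04) / f_nyq
  j_hf <- var_j * (0.40 - 0.15) / f_nyq
  lf_pow <- var_lf + j_lf
  hf_pow <- var_hf + j_hf
  truth <- list(mean_pr = mean(60000 / nn),
                sdnn = stats::sd(nn),
                rmssd = sqrt(mean(diff(nn)^2)),
                sdnn_expected = sdnn_true, rmssd_expected = rmssd_true,
                lf_share = lf_pow / (var_lf + var_hf + var_j),
                hf_share = hf_pow / (var_lf + var_hf + var_j),
                lfnu = lf_pow / (lf_pow + hf_pow),
                hfnu = hf_pow / (lf_pow + hf_pow))
  list(nn = nn_series(nn, t_beat[-1L]), beat_times_s = t_beat, truth = truth)
}

# Pulse-wave template on beat phase u in [0, 1): asymmetric systolic peak
# plus a dicrotic bump.  Main peak sits at phase BVP_PEAK_PHASE.
BVP_PEAK_PHASE <- 0.3
bvp_template <- function(u) {
  exp(-(u - BVP_PEAK_PHASE)^2 / (2 * 0.09^2)) +
    0.35 * exp(-(u - 0.65)^2 / (2 * 0.12^2))
}

#' Render a pulse waveform from an NN series
#'
#' Concatenates a two-Gaussian beat template (systolic peak + dicrotic
#' bump), each beat time-scaled to its NN interval, sampled at `fs`.
#'
#' @param nn an [nn_series] (or the list returned by [generate_nn]).
#' @param fs sampling rate, Hz; must exceed twice the instantaneous pulse
#'   frequency.
#' @param duration optional truncation, seconds (defaults to the span of
#'   the beat series).
#' @return list: `bvp` (numeric, unit peak amplitude), `t` (seconds),
#'   `fs`, `peak_times_s` (ground-truth systolic peak times).
#' @export
nn_to_bvp <- function(nn, fs, duration = NULL) {
  if (is.list(nn) && !inherits(nn, "nn_series") && !is.null(nn$nn)) nn <- nn$nn
  stopifnot(inherits(nn, "nn_series"))
  iv_s <- nn$intervals_ms / 1000
  if (fs < 2 * max(1 / iv_s))
    stop("fs too low for the pulse rate (need fs >= 2 * PR in Hz)")
  starts <- nn$beat_times_s - iv_s      # opening beat of each interval
  total <- if (is.null(duration)) max(nn$beat_times_s) else duration
  t <- seq(0, total - 1 / fs, by = 1 / fs)
  k <- findInterval(t, c(starts, max(nn$beat_times_s)),
                    rightmost.closed = TRUE)
  k[k < 1L] <- 1L
  k[k > length(iv_s)] <- length(iv_s)
  u <- (t - starts[k]) / iv_s[k]
  u <- pmin(pmax(u, 0), 1)
  bvp <- bvp_template(u)
  peaks <- starts + BVP_PEAK_PHASE * iv_s
  peaks <- peaks[peaks < total]
  list(bvp = bvp, t = t, fs = fs, peak_times_s = peaks)
}

#' Couple a pulse waveform into a raw RGB trace
#'
#' Channel model: `c(t) = baseline_c - coupling_c * bvp(t) + trend
#' + noise + motion`, clipped to \[0, 255\].  The pulse enters with a
#' negative sign (increased blood volume absorbs more light) and the green
#' channel carries the largest amplitude by default.  Motion events add
#' the same step offset to all three channels, mimicking intensity-like
#' artifacts.
#'
#' @param bvp list from [nn_to_bvp] (or a plain numeric vector).
#' @param config a [synth_config].
#' @param fs sampling rate; required when `bvp` is a bare vector.
#' @return An [rgb_trace] with `stage = "raw"`.
#' @export
bvp_to_rgb <- function(bvp, config, fs = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.list(bvp)) { fs <- bvp$fs; v <- bvp$bvp } else v <- bvp
  if (is.null(fs)) stop("fs required when bvp is a plain vector")
  n <- length(v)
  t <- (seq_len(n) - 1L) / fs
  trend <- config$trend_amp *
    (0.7 * sin(2 * pi * 0.015 * t + 0.4) + 0.3 * sin(2 * pi * 0.031 * t + 1.1))
  motion <- numeric(n)
  for (ev in config$motion_events) {
    on <- t >= ev[1] & t < ev[1] + ev[2]
    motion[on] <- motion[on] + ev[3]
  }
  chans <- with_seed(config$seed + 1L, {
    lapply(c(r = "r", g = "g", b = "b"), function(ch) {
      config$baseline[[ch]] - config$coupling[[ch]] * v + trend + motion +
        stats::rnorm(n, 0, config$noise_sd)
    })
  })
  clipped <- sum(vapply(chans, function(x) sum(x < 0 | x > 255), 0L))
  if (clipped > 0.01 * 3 * n)
    warning(sprintf("bvp_to_rgb: %d samples clipped (> 1%%)", clipped))
  chans <- lapply(chans, function(x) pmin(pmax(x, 0), 255))
  rgb_trace(chans$r, chans$g, chans$b, fs = fs, stage = "raw", t = t)
}

#' Frame sequence container
#'
#' @param frames list of `height x width x 3` numeric arrays with values
#'   in \[0, 255\], channel order R, G, B.
#' @param fs frame rate, Hz.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fs) {
  stopifnot(length(frames) >= 1L, fs > 0)
  d <- dim(frames[[1L]])
  if (length(d) != 3L || d[3] != 3L)
    stop("frames must be height x width x 3 arrays")
  for (f in frames)
    if (!identical(dim(f), d)) stop("all frames must share dimensions")
  structure(list(frames = frames, fs = fs,
                 height = d[1], width = d[2]),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames %dx%d @ %.6g fps\n",
              length(x$frames), x$width, x$height, x$fs))
  invisible(x)
}

#' Render a minimal face video from an RGB trace
#'
#' Draws a skin-toned elliptical "face" on a dark non-skin background;
#' every face pixel follows the given trace, with fixed darker patches
#' (eyes, mouth) that provide trackable corners.  The face can translate
#' at a constant velocity to exercise the tracker.
#'
#' @param trace an [rgb_trace] (raw stage) driving the face pixels.
#' @param width,height frame size in pixels.
#' @param face_axes ellipse semi-axes `c(ax, ay)` in pixels.
#' @param velocity_px_s translation velocity `c(vx, vy)`, pixels/second.
#' @return list: `frames` (a [frame_sequence]) and `meta` — fixture ground
#'   truth with per-frame face centers, the semi-axes and the face-pixel
#'   count.
#' @export
render_video <- function(trace, width = 160L, height = 120L,
                         face_axes = c(28, 38), velocity_px_s = c(0, 0)) {
  stopifnot(inherits(trace, "rgb_trace"))
  n <- length(trace)
  if (n / trace$fs > 60) stop("render_video supports at most 60 s")
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  bg <- array(0, dim = c(height, width, 3L))
  bg[, , 1] <- 40; bg[, , 2] <- 45; bg[, , 3] <- 60
  c0 <- c(width / 2, height / 2)
  centers <- cbind(c0[1] + velocity_px_s[1] * trace$t,
                   c0[2] + velocity_px_s[2] * trace$t)
  ax <- face_axes[1]; ay <- face_axes[2]
  frames <- vector("list", n)
  npx <- NA_integer_
  clamp01 <- function(v) pmin(pmax(v, 0), 1)
  for (i in seq_len(n)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    # anti-aliased ellipse: ~1 px soft edge so sub-pixel translation
    # moves real image content (needed by gradient-based tracking)
    rho <- sqrt(((xs - cx) / ax)^2 + ((ys - cy) / ay)^2)
    af <- clamp01((1 - rho) * min(ax, ay) + 0.5)
    # fixed facial texture (eyes, mouth), darker than skin, soft-edged
    de1 <- sqrt((xs - (cx - ax * 0.4))^2 + (ys - (cy - ay * 0.3))^2) - 3.5
    de2 <- sqrt((xs - (cx + ax * 0.4))^2 + (ys - (cy - ay * 0.3))^2) - 3.5
    dm <- (sqrt(((xs - cx) / (ax * 0.45))^2 +
                ((ys - (cy + ay * 0.45)) / 3.5)^2) - 1) * 3.5
    at <- clamp01(0.5 - de1) + clamp01(0.5 - de2) + clamp01(0.5 - dm)
    at <- clamp01(at)
    fr <- bg
    val <- c(trace$r[i], trace$g[i], trace$b[i])
    for (ch in 1:3) {
      face_val <- val[ch] * (1 - 0.65 * at)
      fr[, , ch] <- fr[, , ch] * (1 - af) + face_val * af
    }
    frames[[i]] <- fr
    if (i == 1L) npx <- sum(af >= 1)
  }
  list(frames = frame_sequence(frames, trace$fs),
       meta = list(centers = centers, axes = face_axes,
                   face_pixels = npx))
}

#' One-call synthetic subject
#'
#' Convenience wrapper: NN series -> pulse waveform -> raw RGB trace, with
#' all ground truth gathered in one place.
#'
#' @param config a [synth_config].
#' @return list: `config`, `nn`, `truth`, `bvp`, `trace`.
#' @export
synth_subject <- function(config = synth_config()) {
  gen <- generate_nn(config)
  bvp <- nn_to_bvp(gen$nn, fs = config$fs, duration = config$duration)
  trace <- bvp_to_rgb(bvp, config)
  list(config = config, nn = gen$nn, truth = gen$truth, bvp = bvp,
       trace = trace)
}
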