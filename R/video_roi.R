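# From frames to raw RGB traces: skin-blob face detection,
# Lucas-Kanade (KLT) feature tracking, combined RGB/H/CbCr skin masking,
# and spatial averaging over the skin pixels of the face box.
#
# Boxes are c(x, y, w, h) in 0-based, half-open pixel coordinates
# (x grows rightward along columns, y downward along rows).

#' Skin-color thresholds
#'
#' The combined RGB / hue / CbCr rule: a pixel is skin when it
#' simultaneously satisfies (1) the RGB rule `R > r_min, G > g_min,
#' B > b_min, max-min > spread_min, |R-G| > rg_diff_min, R > G, R > B`;
#' (2) the hue rule `H <= h_max` or `H >= h_wrap` (degrees); and (3) the
#' chrominance rule `Cb in cb_range, Cr in cr_range` (BT.601, offset
#' 128).  Defaults are the commonly published bounds for this family of
#' skin models; every threshold is exposed because published variants
#' differ.
#'
#' @param r_min,g_min,b_min minimum channel intensities.
#' @param spread_min minimum `max(R,G,B) - min(R,G,B)`.
#' @param rg_diff_min minimum `|R - G|`.
#' @param h_max,h_wrap hue acceptance region, degrees.
#' @param cb_range,cr_range chrominance bounds.
#' @return list of class `skin_thresholds`.
#' @export
skin_thresholds <- function(r_min = 95, g_min = 40, b_min = 20,
                            spread_min = 15, rg_diff_min = 15,
                            h_max = 50, h_wrap = 340,
                            cb_range = c(77, 127), cr_range = c(133, 173)) {
  structure(list(r_min = r_min, g_min = g_min, b_min = b_min,
                 spread_min = spread_min, rg_diff_min = rg_diff_min,
                 h_max = h_max, h_wrap = h_wrap,
                 cb_range = cb_range, cr_range = cr_range),
            class = "skin_thresholds")
}

# Vectorized skin rule on channel matrices (values 0-255).
skin_rule <- function(R, G, B, th) {
  mx <- pmax(R, G, B)
  mn <- pmin(R, G, B)
  delta <- mx - mn
  rgb_ok <- R > th$r_min & G > th$g_min & B > th$b_min &
    delta > th$spread_min & abs(R - G) > th$rg_diff_min & R > G & R > B
  # hue (degrees); gray pixels get an arbitrary H but fail the spread rule
  d <- delta
  d[d == 0] <- 1
  hr <- 60 * ((G - B) / d)
  hg <- 60 * ((B - R) / d + 2)
  hb <- 60 * ((R - G) / d + 4)
  H <- ifelse(mx == R, hr, ifelse(mx == G, hg, hb))
  H <- (H + 360) %% 360
  h_ok <- H <= th$h_max | H >= th$h_wrap
  cb <- 128 - 0.168736 * R - 0.331264 * G + 0.5 * B
  cr <- 128 + 0.5 * R - 0.418688 * G - 0.081312 * B
  c_ok <- cb >= th$cb_range[1] & cb <= th$cb_range[2] &
    cr >= th$cr_range[1] & cr <= th$cr_range[2]
  rgb_ok & h_ok & c_ok
}

#' Skin mask of one frame
#'
#' Boolean pixel map, true only inside `box` where the pixel satisfies
#' the configured skin rule in RGB, hue and CbCr simultaneously.
#'
#' @param frame `height x width x 3` array, values 0-255.
#' @param box `c(x, y, w, h)` 0-based half-open; `NULL` means the whole
#'   frame.
#' @param thresholds a [skin_thresholds].
#' @return logical `height x width` matrix.
#' @export
skin_mask <- function(frame, box = NULL, thresholds = skin_thresholds()) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  if (is.null(box)) box <- c(0, 0, w, h)
  cols <- (box[1] + 1L):(box[1] + box[3])
  rows <- (box[2] + 1L):(box[2] + box[4])
  if (min(rows) < 1L || max(rows) > h || min(cols) < 1L || max(cols) > w)
    stop("skin_mask: box outside frame")
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- skin_rule(frame[rows, cols, 1], frame[rows, cols, 2],
                             frame[rows, cols, 3], thresholds)
  if (!any(m)) stop("skin_mask: empty skin mask")
  m
}

# Largest 4-connected component of a logical matrix; returns its linear
# indices (column-major).
largest_component <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  id <- integer(h * w)
  id[idx] <- seq_along(idx)
  # edges to the neighbor below and to the right
  down <- idx[(idx %% h) != 0 & c(mask[idx + 1L])]
  right <- idx[idx <= h * (w - 1L)]
  right <- right[mask[right + h]]
  el <- rbind(cbind(id[down], id[down + 1L]),
              cbind(id[right], id[right + h]))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)
  idx[comp$membership == which.max(comp$csize)]
}

#' Detect the face in a frame
#'
#' Locates the largest connected skin-colored blob and returns its
#' bounding box.  This detector suits controlled scenes with a single
#' face on a non-skin background (as produced by [render_video]); it
#' stands where a generic pretrained face detector would be plugged in.
#'
#' @param frame `height x width x 3` array.
#' @param thresholds a [skin_thresholds].
#' @param min_pixels smallest acceptable blob size.
#' @param frame_index index used in error messages.
#' @return box `c(x, y, w, h)`, 0-based half-open.
#' @export
detect_face <- function(frame, thresholds = skin_thresholds(),
                        min_pixels = 50L, frame_index = 1L) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("detect_face: frame must be a height x width x 3 array")
  h <- dim(frame)[1]
  m <- tryCatch(skin_mask(frame, NULL, thresholds), error = function(e) NULL)
  if (is.null(m))
    stop("detect_face: no face found in frame ", frame_index)
  px <- largest_component(m)
  if (length(px) < min_pixels)
    stop("detect_face: no face found in frame ", frame_index)
  rows <- ((px - 1L) %% h) + 1L
  cols <- ((px - 1L) %/% h) + 1L
  c(x = min(cols) - 1L, y = min(rows) - 1L,
    w = max(cols) - min(cols) + 1L, h = max(rows) - min(rows) + 1L)
}

# --- Lucas-Kanade tracking ------------------------------------------

gray_frame <- function(frame) {
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# central-difference gradients
grad_x <- function(I) {
  G <- I * 0
  G[, 2:(ncol(I) - 1)] <- (I[, 3:ncol(I)] - I[, 1:(ncol(I) - 2)]) / 2
  G
}
grad_y <- function(I) {
  G <- I * 0
  G[2:(nrow(I) - 1), ] <- (I[3:nrow(I), ] - I[1:(nrow(I) - 2), ]) / 2
  G
}

# box-filter sum over (2r+1)^2 windows via 2-D cumulative sums
box_sum <- function(M, r) {
  h <- nrow(M); w <- ncol(M)
  P <- matrix(0, h + 1L, w + 1L)
  P[-1L, -1L] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
  i <- seq_len(h); j <- seq_len(w)
  lo_i <- pmax(i - r, 1L); hi_i <- pmin(i + r, h)
  lo_j <- pmax(j - r, 1L); hi_j <- pmin(j + r, w)
  P[hi_i + 1L, hi_j + 1L] - P[lo_i, hi_j + 1L] -
    P[hi_i + 1L, lo_j] + P[lo_i, lo_j]
}

# bilinear sampling; x = column, y = row (1-based, fractional)
bilinear <- function(img, xs, ys) {
  h <- nrow(img); w <- ncol(img)
  x0 <- pmin(pmax(floor(xs), 1), w - 1)
  y0 <- pmin(pmax(floor(ys), 1), h - 1)
  dx <- pmin(pmax(xs - x0, 0), 1)
  dy <- pmin(pmax(ys - y0, 0), 1)
  i00 <- (x0 - 1) * h + y0
  img[i00] * (1 - dx) * (1 - dy) + img[i00 + h] * dx * (1 - dy) +
    img[i00 + 1] * (1 - dx) * dy + img[i00 + h + 1] * dx * dy
}

# Shi-Tomasi corners inside a box: top `n_points` minimum-eigenvalue
# responses with a minimum mutual separation.
select_corners <- function(I, box, n_points = 40L, min_sep = 5,
                           margin = 7L) {
  Ix <- grad_x(I); Iy <- grad_y(I)
  a <- box_sum(Ix * Ix, 1L)
  b <- box_sum(Ix * Iy, 1L)
  cc <- box_sum(Iy * Iy, 1L)
  resp <- (a + cc - sqrt((a - cc)^2 + 4 * b^2)) / 2
  h <- nrow(I); w <- ncol(I)
  cols <- max(box[1] + 1L + margin, 1L):min(box[1] + box[3] - margin, w)
  rows <- max(box[2] + 1L + margin, 1L):min(box[2] + box[4] - margin, h)
  sub <- resp[rows, cols]
  ord <- order(sub, decreasing = TRUE)
  pts <- matrix(numeric(0), 0L, 2L)
  for (o in ord[seq_len(min(length(ord), 40L * n_points))]) {
    rr <- rows[((o - 1L) %% length(rows)) + 1L]
    cx <- cols[((o - 1L) %/% length(rows)) + 1L]
    if (sub[((o - 1L) %% length(rows)) + 1L,
            ((o - 1L) %/% length(rows)) + 1L] <= 1e-6) break
    if (!nrow(pts) ||
        min((pts[, 1] - cx)^2 + (pts[, 2] - rr)^2) >= min_sep^2)
      pts <- rbind(pts, c(cx, rr))
    if (nrow(pts) >= n_points) break
  }
  pts  # columns: x, y
}

# One Lucas-Kanade step for a set of points between two gray frames.
# Returns the per-point displacement and a validity flag.
lk_flow <- function(I1, I2, pts, win_half = 4L, max_iter = 10L,
                    max_disp = 12, max_resid = 25) {
  Ix <- grad_x(I1); Iy <- grad_y(I1)
  off <- expand.grid(ox = -win_half:win_half, oy = -win_half:win_half)
  h <- nrow(I1); w <- ncol(I1)
  n <- nrow(pts)
  disp <- matrix(NA_real_, n, 2L)
  ok <- logical(n)
  for (p in seq_len(n)) {
    px <- pts[p, 1]; py <- pts[p, 2]
    xs <- px + off$ox; ys <- py + off$oy
    if (min(xs) < 2 || max(xs) > w - 1 || min(ys) < 2 || max(ys) > h - 1)
      next
    gx <- bilinear(Ix, xs, ys)
    gy <- bilinear(Iy, xs, ys)
    t1 <- bilinear(I1, xs, ys)
    G <- matrix(c(sum(gx * gx), sum(gx * gy), sum(gx * gy), sum(gy * gy)),
                2L)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-3) next
    d <- c(0, 0)
    for (it in seq_len(max_iter)) {
      x2 <- xs + d[1]; y2 <- ys + d[2]
      if (min(x2) < 1 || max(x2) > w || min(y2) < 1 || max(y2) > h) break
      e <- t1 - bilinear(I2, x2, y2)
      delta <- solve(G, c(sum(gx * e), sum(gy * e)))
      d <- d + delta
      if (sqrt(sum(delta^2)) < 0.01) break
    }
    if (sqrt(sum(d^2)) > max_disp) next
    resid <- t1 - bilinear(I2, xs + d[1], ys + d[2])
    if (sqrt(mean(resid^2)) > max_resid) next
    disp[p, ] <- d
    ok[p] <- TRUE
  }
  list(disp = disp, ok = ok)
}

#' Track the face box across frames
#'
#' KLT tracking: Shi-Tomasi corner features are selected inside the
#' initial box and followed with iterative Lucas-Kanade optical flow;
#' the box translates with the median feature displacement.  When fewer
#' than half of the seeded points survive, the face is re-detected with
#' the blob detector and the features re-seeded; if re-detection also
#' fails, the last valid box is carried forward and the frame flagged.
#'
#' @param frames a [frame_sequence] (>= 1 frame).
#' @param initial_box box from [detect_face] on the first frame.
#' @param thresholds a [skin_thresholds] for re-detection.
#' @param n_points number of corner features.
#' @return list of class `roi_track`: `boxes` (n x 4 matrix, 0-based
#'   half-open), `lost_frames` (indices where tracking was carried
#'   forward), `n_points_final`.
#' @export
track_face <- function(frames, initial_box,
                       thresholds = skin_thresholds(), n_points = 40L) {
  stopifnot(inherits(frames, "frame_sequence"))
  n <- length(frames$frames)
  boxes <- matrix(NA_real_, n, 4L,
                  dimnames = list(NULL, c("x", "y", "w", "h")))
  boxes[1L, ] <- as.numeric(initial_box)
  if (n == 1L)
    return(structure(list(boxes = boxes, lost_frames = integer(),
                          n_points_final = NA_integer_),
                     class = "roi_track"))
  I_prev <- gray_frame(frames$frames[[1L]])
  pts <- select_corners(I_prev, initial_box, n_points = n_points)
  n_seed <- nrow(pts)
  if (n_seed < 4L) stop("track_face: too few trackable features in box")
  lost <- integer()
  box <- as.numeric(initial_box)
  for (i in 2:n) {
    I_cur <- gray_frame(frames$frames[[i]])
    fl <- lk_flow(I_prev, I_cur, pts)
    surv <- which(fl$ok)
    if (length(surv) >= max(4L, ceiling(n_seed / 2))) {
      d <- c(stats::median(fl$disp[surv, 1]),
             stats::median(fl$disp[surv, 2]))
      box[1:2] <- box[1:2] + d
      pts <- pts[surv, , drop = FALSE] + matrix(fl$disp[surv, ],
                                                ncol = 2L)
      n_seed <- nrow(pts)
    } else {
      redet <- tryCatch(
        detect_face(frames$frames[[i]], thresholds, frame_index = i),
        error = function(e) NULL)
      if (!is.null(redet)) {
        box <- as.numeric(redet)
        pts <- select_corners(I_cur, box, n_points = n_points)
        n_seed <- nrow(pts)
        if (n_seed < 4L)
          stop("track_face: tracking lost and re-seeding failed at frame ", i)
      } else {
        lost <- c(lost, i)            # carry forward the last valid box
      }
    }
    # clamp the box inside the frame
    box[1] <- min(max(box[1], 0), frames$width - box[3])
    box[2] <- min(max(box[2], 0), frames$height - box[4])
    boxes[i, ] <- box
    I_prev <- I_cur
  }
  structure(list(boxes = boxes, lost_frames = lost,
                 n_points_final = nrow(pts)),
            class = "roi_track")
}

# Morphological erosion of a logical mask by `r` pixels (square
# structuring element).
erode_mask <- function(mask, r) {
  if (r < 1L) return(mask)
  box_sum(mask * 1, r) == (2 * r + 1)^2
}

#' Spatially averaged RGB trace of a frame sequence
#'
#' Per frame, each channel is the arithmetic mean over the skin-masked
#' pixels inside the tracked box (normalization by the skin-pixel
#' count); the time axis is `frame_index / fs`.  The mask is eroded by
#' `erode_px` pixels before averaging so that mixed skin/background
#' boundary pixels, whose colour depends on sub-pixel face position, do
#' not modulate the mean.
#'
#' @param frames a [frame_sequence].
#' @param roi_track an `roi_track` from [track_face] (or a single box
#'   recycled over frames).
#' @param masks optional list of per-frame logical masks; computed with
#'   [skin_mask] when `NULL`.
#' @param thresholds a [skin_thresholds].
#' @param erode_px mask erosion radius in pixels (0 disables; erosion is
#'   skipped whenever it would empty the mask).
#' @return an [rgb_trace] with `stage = "raw"`.
#' @export
extract_rgb_trace <- function(frames, roi_track, masks = NULL,
                              thresholds = skin_thresholds(),
                              erode_px = 2L) {
  stopifnot(inherits(frames, "frame_sequence"))
  n <- length(frames$frames)
  boxes <- if (inherits(roi_track, "roi_track")) roi_track$boxes
           else matrix(as.numeric(roi_track), n, 4L, byrow = TRUE)
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    fr <- frames$frames[[i]]
    box <- round(boxes[i, ])
    m <- if (is.null(masks)) skin_mask(fr, box, thresholds) else masks[[i]]
    if (erode_px >= 1L) {
      me <- erode_mask(m, as.integer(erode_px))
      if (any(me)) m <- me
    }
    if (!any(m)) stop("extract_rgb_trace: empty skin mask at frame ", i)
    for (ch in 1:3) out[i, ch] <- mean(fr[, , ch][m])
  }
  rgb_trace(out[, 1], out[, 2], out[, 3], fs = frames$fs, stage = "raw")
}

#' Video frames to raw trace in one call
#'
#' Detect on the first frame, track, mask, average.
#'
#' @param frames a [frame_sequence].
#' @param thresholds a [skin_thresholds].
#' @return list: `trace` ([rgb_trace]), `track` (`roi_track`).
#' @export
video_to_trace <- function(frames, thresholds = skin_thresholds()) {
  box <- detect_face(frames$frames[[1L]], thresholds, frame_index = 1L)
  trk <- track_face(frames, box, thresholds)
  list(trace = extract_rgb_trace(frames, trk, thresholds = thresholds),
       track = trk)
}
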