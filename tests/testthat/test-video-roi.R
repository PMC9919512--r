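# Face detection, tracking, skin masking, and trace extraction.

solid_frame <- function(rgb, h = 20, w = 20) {
  fr <- array(0, dim = c(h, w, 3))
  fr[, , 1] <- rgb[1]; fr[, , 2] <- rgb[2]; fr[, , 3] <- rgb[3]
  fr
}

# a short rendered face clip driven by a constant skin-tone trace
face_clip <- function(n = 12, velocity = c(0, 0)) {
  tr <- rgb_trace(rep(200, n), rep(140, n), rep(110, n), fs = 30)
  render_video(tr, velocity_px_s = velocity)
}

test_that("the skin rule accepts skin tones and rejects non-skin", {
  fr <- solid_frame(c(200, 140, 110))
  m <- skin_mask(fr, c(5, 5, 10, 10))
  expect_true(all(m[6:15, 6:15]))
  expect_false(any(m[1:5, ]))  # outside the box

  expect_error(skin_mask(solid_frame(c(0, 0, 0)), c(5, 5, 10, 10)),
               "empty skin mask")

  # half skin, half pure green: mask true exactly on the skin half
  fr2 <- solid_frame(c(200, 140, 110))
  fr2[, 11:20, 1] <- 0; fr2[, 11:20, 2] <- 255; fr2[, 11:20, 3] <- 0
  m2 <- skin_mask(fr2, c(0, 0, 20, 20))
  expect_true(all(m2[, 1:10]))
  expect_false(any(m2[, 11:20]))
})

test_that("detect_face boxes the rendered face and rejects black frames", {
  vid <- face_clip(n = 2)
  fr <- vid$frames$frames[[1]]
  box <- detect_face(fr)
  ctr <- c(box[1] + box[3] / 2, box[2] + box[4] / 2)
  truth <- vid$meta$centers[1, ]
  expect_lt(abs(ctr[1] - truth[1]), 0.1 * 2 * vid$meta$axes[1])
  expect_lt(abs(ctr[2] - truth[2]), 0.1 * 2 * vid$meta$axes[2])
  # box covers the ellipse
  expect_gte(box[3], 2 * vid$meta$axes[1] - 4)
  expect_gte(box[4], 2 * vid$meta$axes[2] - 4)

  expect_error(detect_face(solid_frame(c(0, 0, 0)), frame_index = 7L),
               "no face found in frame 7")
})

test_that("tracking is static for a static face and follows translation", {
  vid <- face_clip(n = 10)
  box <- detect_face(vid$frames$frames[[1]])
  trk <- track_face(vid$frames, box)
  expect_equal(nrow(trk$boxes), 10)
  expect_true(all(abs(sweep(trk$boxes, 2, as.numeric(box))) <= 1))

  # rightward translation: box x increases monotonically
  vid_m <- face_clip(n = 15, velocity = c(30, 0))
  box_m <- detect_face(vid_m$frames$frames[[1]])
  trk_m <- track_face(vid_m$frames, box_m)
  expect_true(all(diff(trk_m$boxes[, 1]) > -0.25))
  expect_gt(trk_m$boxes[15, 1] - trk_m$boxes[1, 1], 0.8 * 30 * 14 / 30)

  # single frame: track of length 1 with the initial box
  f1 <- frame_sequence(vid$frames$frames[1], fs = 30)
  trk1 <- track_face(f1, box)
  expect_equal(nrow(trk1$boxes), 1)
  expect_equal(as.numeric(trk1$boxes[1, ]), as.numeric(box))
})

test_that("trace extraction averages masked pixels exactly", {
  # every masked pixel identical
  frames <- frame_sequence(list(solid_frame(c(100, 150, 200)),
                                solid_frame(c(100, 150, 200))), fs = 30)
  mask <- matrix(FALSE, 20, 20); mask[8:12, 8:12] <- TRUE
  tr <- extract_rgb_trace(frames, c(0, 0, 20, 20),
                          masks = list(mask, mask), erode_px = 0)
  expect_equal(tr$r, c(100, 100))
  expect_equal(tr$g, c(150, 150))
  expect_equal(tr$b, c(200, 200))
  expect_equal(tr$t, c(0, 1 / 30))

  # midpoint of a black and a white pixel
  fr <- solid_frame(c(0, 0, 0), h = 2, w = 2)
  fr[1, 2, ] <- 255
  m2 <- matrix(FALSE, 2, 2); m2[1, 1] <- TRUE; m2[1, 2] <- TRUE
  tr2 <- extract_rgb_trace(frame_sequence(list(fr, fr), 30),
                           c(0, 0, 2, 2), masks = list(m2, m2),
                           erode_px = 0)
  expect_equal(tr2$r, c(127.5, 127.5))

  # mask monotonicity: shrinking to a subset with identical pixel
  # values leaves the trace unchanged
  m3 <- mask; m3[8, ] <- FALSE
  tr3 <- extract_rgb_trace(frames, c(0, 0, 20, 20),
                           masks = list(m3, m3), erode_px = 0)
  expect_equal(tr3$g, tr$g)

  # empty mask propagates as an error
  expect_error(extract_rgb_trace(frames, c(0, 0, 20, 20),
                                 masks = list(mask, matrix(FALSE, 20, 20)),
                                 erode_px = 0),
               "empty skin mask at frame 2")
})

test_that("trace values stay within the masked pixel range (boundedness)", {
  vid <- face_clip(n = 6)
  rt <- video_to_trace(vid$frames)
  expect_true(all(rt$trace$g >= 0 & rt$trace$g <= 255))
  # determinism: identical frames and config give an identical trace
  rt2 <- video_to_trace(vid$frames)
  expect_identical(rt$trace$g, rt2$trace$g)
})
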