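# Point clouds, bed-plane estimation, rectification, filling, segmentation.

test_that("back-projection follows the pinhole model", {
  K <- list(fx = 500, fy = 500, cx = 0.5, cy = 0.5)
  f <- matrix(1000, 2, 2)
  pc <- depth_to_point_cloud(f, K)
  expect_equal(nrow(pc), 4)
  expect_true(all(abs(abs(pc$x) - 1) < 1e-12))
  expect_true(all(abs(abs(pc$y) - 1) < 1e-12))
  expect_true(all(pc$z == 1000))

  # principal-point identity
  K2 <- list(fx = 100, fy = 100, cx = 1, cy = 1) # 0-based center of pixel (2,2)
  f2 <- matrix(0, 3, 3)
  f2[2, 2] <- 1000
  pc2 <- depth_to_point_cloud(f2, K2)
  expect_equal(nrow(pc2), 1) # zero-depth pixels excluded
  expect_equal(c(pc2$x, pc2$y, pc2$z), c(0, 0, 1000))

  expect_warning(pc0 <- depth_to_point_cloud(matrix(0, 4, 4), K), "invalid")
  expect_equal(nrow(pc0), 0)
})

# build an exact plane-only frame for given tilt
plane_frame <- function(rows = 48, cols = 36, tilt = 10, depth = 2000, fx = 60) {
  K <- list(fx = fx, fy = fx, cx = (cols - 1) / 2, cy = (rows - 1) / 2)
  v0 <- matrix(seq_len(rows) - 1, rows, cols)
  th <- tilt * pi / 180
  g <- sin(th) * (v0 - K$cy) / K$fy + cos(th)
  list(frame = (depth * cos(th)) / g, K = K,
       normal = c(0, sin(th), cos(th)), d = depth * cos(th))
}

test_that("an exact tilted plane is recovered to within 0.1 degree", {
  pf <- plane_frame(tilt = 12)
  v <- depth_video(array(pf$frame, c(dim(pf$frame), 3)), frame_rate = 10,
                   intrinsics = pf$K)
  pl <- estimate_bed_plane(v)
  ang <- acos(min(1, sum(pl$normal * pf$normal))) * 180 / pi
  expect_lt(ang, 0.1)
  expect_lt(abs(pl$d - pf$d), 0.5)
})

test_that("plane recovery tolerates a body and sensor noise", {
  sc <- quick_scene(duration = 60, seed = 11, bed_tilt = 9)
  v <- render_depth_video(sc, generate_event_schedule(sc, still_plan()))
  pl <- estimate_bed_plane(v)
  truth <- c(0, sin(9 * pi / 180), cos(9 * pi / 180))
  ang <- acos(min(1, sum(pl$normal * truth))) * 180 / pi
  expect_lt(ang, 1)
  expect_lt(abs(pl$d - sc$bed_plane_depth * cos(9 * pi / 180)), 2)
})

test_that("rectification recovers elevations above the bed", {
  pf <- plane_frame(tilt = 10)
  # add a 20-mm hump in the middle (closer to the camera along g)
  v0 <- matrix(seq_len(48) - 1, 48, 36)
  th <- 10 * pi / 180
  g <- sin(th) * (v0 - pf$K$cy) / pf$K$fy + cos(th)
  hump <- matrix(0, 48, 36)
  hump[20:28, 14:22] <- 20
  frame <- (pf$d - hump) / g
  vid <- depth_video(array(frame, c(48, 36, 3)), frame_rate = 10, intrinsics = pf$K)
  pl <- estimate_bed_plane(vid)
  elev <- rectify_frame(frame, pl, pf$K)
  expect_lt(max(abs(elev[hump == 0])), 1)          # bed pixels ~ 0
  expect_equal(mean(elev[hump == 20]), 20, tolerance = 1)

  # zero-tilt rectification is the identity up to the plane offset
  pf0 <- plane_frame(tilt = 0)
  vid0 <- depth_video(array(pf0$frame, c(48, 36, 3)), frame_rate = 10, intrinsics = pf0$K)
  pl0 <- estimate_bed_plane(vid0)
  e0 <- rectify_frame(pf0$frame, pl0, pf0$K)
  expect_lt(max(abs(e0)), 0.5)

  # invalid pixels propagate
  f_na <- pf$frame
  f_na[5, 5] <- 0
  expect_true(is.na(rectify_frame(f_na, pl, pf$K)[5, 5]))
})

test_that("fill_and_smooth fills from neighbours and averages as stated", {
  m <- matrix(100, 8, 8)
  expect_equal(fill_and_smooth(m, kernel = 1), m, ignore_attr = TRUE)

  m_na <- m
  m_na[4, 4] <- NA
  expect_equal(fill_and_smooth(m_na, kernel = 1)[4, 4], 100)
  filled <- fill_and_smooth(m_na, kernel = 1)
  expect_equal(filled[-4, ], m[-4, ], ignore_attr = TRUE) # valid values unchanged

  # 3x3 average on a step edge equals the hand-computed window mean
  step <- matrix(rep(c(0, 0, 0, 0, 9, 9, 9, 9), each = 8), 8, 8)
  sm <- fill_and_smooth(step, kernel = 3)
  expect_equal(sm[4, 3], 0)                    # fully inside the low side
  expect_equal(sm[4, 4], mean(step[3:5, 3:5])) # window touches the high column
  expect_equal(sm[4, 4], 3)
  expect_equal(sm[4, 5], 6)                    # window holds two high columns

  # idempotence on fully valid constant frames
  expect_equal(fill_and_smooth(fill_and_smooth(m), kernel = 3), m, ignore_attr = TRUE)

  mostly_na <- matrix(NA_real_, 10, 10)
  mostly_na[1:2, ] <- 50
  out <- fill_and_smooth(mostly_na, kernel = 1)
  expect_true(attr(out, "low_quality"))
  expect_equal(max(abs(out - 50)), 0, tolerance = 1e-6)
})

test_that("segmentation finds the body, its axis and the thoracic disk", {
  sc <- quick_scene(duration = 60, seed = 13)
  src <- render_night(sc, generate_event_schedule(sc, still_plan()))
  sig <- extract_night_signals(src)
  seg <- sig$segmentation
  expect_lt(abs(seg$body_axis$head[1] - sc$body_axis$head[1]), 5)
  expect_lt(abs(seg$body_axis$foot[1] - sc$body_axis$foot[1]), 5)
  expect_lt(abs(seg$body_axis$head[2] - sc$body_axis$head[2]), 5)
  # symmetric body: ROI center on the axis
  expect_lt(abs(seg$thorax_roi$center[2] - sc$body_axis$head[2]), 2)
  # masks are disjoint and inside the body
  expect_false(any(seg$thorax_mask & seg$lower_body_mask))
  expect_true(all(seg$body_mask[seg$thorax_mask]))
  expect_true(all(seg$body_mask[seg$lower_body_mask]))
  # roi disk inside (a 1-px dilation of) the thorax mask
  dil <- EBImage::dilate(seg$thorax_mask * 1, EBImage::makeBrush(3, "box")) > 0
  expect_true(all(dil[seg$roi_mask]))
})

test_that("an empty scene yields a no-body error", {
  flat <- matrix(0, 48, 36)
  expect_error(segment_body(flat), "no body detected")
})

test_that("segmentation is stable across frames of a still body", {
  sc <- quick_scene(duration = 90, seed = 14, noise_sd = 1)
  v <- render_depth_video(sc, generate_event_schedule(sc, still_plan()))
  pl <- estimate_bed_plane(v)
  segs <- lapply(c(10, 300, 600), function(i) {
    fr <- fill_and_smooth(rectify_frame(v$frames[, , i], pl, v$intrinsics))
    segment_body(fr)
  })
  jac <- function(a, b) sum(a & b) / sum(a | b)
  expect_gt(jac(segs[[1]]$body_mask, segs[[2]]$body_mask), 0.95)
  expect_gt(jac(segs[[2]]$body_mask, segs[[3]]$body_mask), 0.95)
})

test_that("ROI breathing series is invariant to bed tilt (rectification works)", {
  mk <- function(tilt, seed = 15) {
    sc <- quick_scene(duration = 600, seed = seed, bed_tilt = tilt)
    sch <- generate_event_schedule(sc, still_plan(respiratory_rate = 12))
    sig <- extract_night_signals(render_night(sc, sch))
    sig$breathing$value
  }
  flat <- mk(0)
  tilted <- mk(10)
  # same schedule and seed: identical breathing waveform up to noise
  rms <- sqrt(mean((flat - tilted)^2))
  expect_lt(rms, 0.05 * sqrt(mean(flat^2)))
})
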