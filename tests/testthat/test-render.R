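# Synthetic depth-video renderer.

test_that("rendering is bit-identical for the same seed and differs across seeds", {
  sc <- quick_scene(duration = 60, seed = 5)
  sch <- generate_event_schedule(sc, still_plan())
  v1 <- render_depth_video(sc, sch)
  v2 <- render_depth_video(sc, sch)
  expect_identical(v1$frames, v2$frames)

  sc2 <- quick_scene(duration = 60, seed = 6)
  v3 <- render_depth_video(sc2, generate_event_schedule(sc2, still_plan()))
  expect_false(identical(v1$frames, v3$frames))
})

test_that("chunk access order does not change rendered frames", {
  sc <- quick_scene(duration = 90, seed = 7)
  src <- render_night(sc, generate_event_schedule(sc, still_plan()))
  c3 <- somnocam:::source_chunk(src, 3)
  c1 <- somnocam:::source_chunk(src, 1)
  c3_again <- somnocam:::source_chunk(src, 3)
  expect_identical(c3, c3_again)
  expect_identical(c1, somnocam:::source_chunk(src, 1))
})

test_that("a noise-free still scene breathes purely at the configured rate", {
  sc <- quick_scene(duration = 120, noise_sd = 0, invalid_pixel_rate = 0, seed = 1)
  sch <- generate_event_schedule(sc, still_plan())
  v <- render_depth_video(sc, sch)
  # mean torso depth over time: use the central torso rows directly
  torso_rows <- 16:24
  series <- apply(v$frames[torso_rows, 14:22, ], 3, mean)
  series <- series - mean(series)
  n <- length(series)
  sp <- Mod(fft(series))[2:(n %/% 2)]^2
  freq <- (seq_along(sp)) * sc$frame_rate / n
  expect_equal(freq[which.max(sp)], sc$breathing_rate / 60, tolerance = 0.02)
})

test_that("a central apnea flattens the torso oscillation inside its window", {
  sc <- quick_scene(duration = 90, noise_sd = 0, invalid_pixel_rate = 0, seed = 2)
  sch <- generate_event_schedule(sc, still_plan())
  sch$respiratory <- tibble::tibble(onset = 40, duration = 15, type = "central",
                                    amplitude_fraction = 0)
  v <- render_depth_video(sc, sch)
  series <- apply(v$frames[16:24, 14:22, ], 3, mean)
  t <- v$timestamps
  inside <- series[t >= 42 & t <= 53]
  outside <- series[t >= 10 & t <= 35]
  expect_lt(diff(range(inside)), 0.15 * diff(range(outside)))
})

test_that("a leg movement dominates the leg region against a quiet baseline", {
  # 2-s, 20-mm movement; max frame-to-frame change in the leg region during
  # the event must exceed 10x its typical out-of-event value at 0.5 mm noise
  sc <- quick_scene(duration = 90, noise_sd = 0.5, invalid_pixel_rate = 0, seed = 3)
  sch <- generate_event_schedule(sc, still_plan())
  sch$leg_movements <- tibble::tibble(onset = 45, duration = 2, limb = "both",
                                      displacement = 20, train_id = NA_integer_)
  v <- render_depth_video(sc, sch)
  leg_rows <- 30:43
  d <- abs(v$frames[leg_rows, , -1] - v$frames[leg_rows, , -v$n_frames])
  t <- v$timestamps[-1]
  in_ev <- t >= 45 & t <= 47
  expect_gt(max(d[, , in_ev]), 10 * mean(d[, , !in_ev]))
})

test_that("whole-body movements translate the body and are detectable as such", {
  sc <- quick_scene(duration = 150, seed = 4)
  sch <- generate_event_schedule(sc, still_plan())
  sch$whole_body <- tibble::tibble(onset = 60, duration = 3, shift_px = 3,
                                   wiggle_mm = 30)
  src <- render_night(sc, sch)
  sig <- extract_night_signals(src)
  expect_equal(nrow(sig$whole_body), 1)
  expect_lt(abs(sig$whole_body$onset - 60), 1.5)

  # a leg-only twitch is not a whole-body movement
  sch2 <- generate_event_schedule(sc, still_plan())
  sch2$leg_movements <- tibble::tibble(onset = 60, duration = 2, limb = "left",
                                       displacement = 25, train_id = NA_integer_)
  sig2 <- extract_night_signals(render_night(sc, sch2))
  expect_equal(nrow(sig2$whole_body), 0)
})

test_that("invalid pixels appear at the configured rate as zeros", {
  sc <- quick_scene(duration = 60, invalid_pixel_rate = 0.02, seed = 9)
  v <- render_depth_video(sc, generate_event_schedule(sc, still_plan()))
  rate <- mean(v$frames == 0)
  expect_equal(rate, 0.02, tolerance = 0.002)
})

test_that("an oversized body axis is rejected", {
  expect_error(
    scene_config(image_size = c(16L, 12L),
                 body_axis = list(head = c(row = 2, col = 6), foot = c(row = 40, col = 6))),
    "image_size"
  )
})

test_that("event-rate conservation holds across seeded runs", {
  rates <- vapply(1:20, function(s) {
    sc <- quick_scene(duration = 3600, seed = s)
    sch <- generate_event_schedule(sc, still_plan(respiratory_rate = 12))
    nrow(sch$respiratory)
  }, numeric(1))
  expect_true(all(rates == 12)) # exact-count scheduling
})
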