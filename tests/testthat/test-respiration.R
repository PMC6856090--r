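# Breathing signal, envelope, event detection, indices.

test_that("envelope matches closed forms", {
  fs <- 10
  t <- seq(0, 60, by = 1 / fs)
  x <- 3 * sin(2 * pi * 0.25 * t)
  env <- compute_envelope(x, window_s = 5, sample_rate = fs)
  mid <- seq(50, length(x) - 50)
  expect_equal(mean(env[mid]), 3, tolerance = 0.02)
  expect_true(all(abs(env[mid] - 3) < 0.1))

  expect_true(all(compute_envelope(rep(0, 600), 5, fs) == 0))
  expect_error(compute_envelope(x, window_s = 0.05, sample_rate = fs), "2 samples")
})

test_that("envelope tracks slow amplitude modulation within 10%", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  amp <- 2 + sin(2 * pi * t / 300) # 300-s modulation
  x <- amp * sin(2 * pi * 0.25 * t)
  env <- compute_envelope(x, window_s = 5, sample_rate = fs)
  mid <- seq(100, length(x) - 100)
  expect_true(all(abs(env[mid] - amp[mid]) / amp[mid] < 0.1))
})

test_that("constant-amplitude breathing yields no events; scripted apnea is found", {
  fs <- 10
  t <- seq(0, 1200 - 1 / fs, by = 1 / fs)
  x <- 3 * sin(2 * pi * 0.25 * t)
  env <- compute_envelope(x, 5, fs)
  expect_equal(nrow(detect_respiratory_events(env, fs)), 0)

  # 15-s total cessation at 600 s
  x2 <- x
  x2[t >= 600 & t < 615] <- 0
  ev <- detect_respiratory_events(compute_envelope(x2, 5, fs), fs)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset - 600), 2)
  expect_lt(ev$min_amplitude_fraction, 0.1)

  expect_error(detect_respiratory_events(rep(0, 12000), fs), "unscorable")
})

test_that("event detection matches a plain exhaustive oracle on a full night envelope", {
  cfg <- quick_config(duration = 2400, seed = 8,
                      plan = list(respiratory_rate = 18, whole_body_rate = 0,
                                  sleep_latency_min = 0, awakenings = 0))
  sim <- simulate_night(cfg)
  an <- analyze_night(sim$video, cfg)
  env <- an$envelope
  fs <- 10
  # oracle: direct thresholding of the full envelope against the same rolling
  # baseline, maximal below-threshold spans collected by a plain loop
  baseline <- somnocam:::rolling_median_na(env, round(100 * fs))
  below <- env < 0.5 * baseline
  edge <- 26
  below[seq_len(edge)] <- FALSE
  below[(length(below) - edge + 1):length(below)] <- FALSE
  spans <- list()
  i <- 1
  while (i <= length(below)) {
    if (below[i]) {
      j <- i
      while (j < length(below) && below[j + 1]) j <- j + 1
      spans[[length(spans) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  lens <- vapply(spans, function(s) (s[2] - s[1] + 1) / fs, numeric(1))
  oracle_n <- sum(lens >= 10 & lens <= 120)
  expect_equal(nrow(an$respiratory_events), oracle_n)
  expect_equal(nrow(an$respiratory_events), nrow(sim$schedule$respiratory))
})

test_that("detection count is monotone in drop_fraction and scale invariant", {
  cfg <- quick_config(duration = 1800, seed = 10,
                      plan = list(respiratory_rate = 14, whole_body_rate = 0,
                                  sleep_latency_min = 0, awakenings = 0))
  sim <- simulate_night(cfg)
  an <- analyze_night(sim$video, cfg)
  env <- an$envelope
  fs <- 10
  counts <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(dfr) {
    nrow(detect_respiratory_events(env, fs, drop_fraction = dfr))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0)) # lowering drop_fraction never adds events

  ev1 <- detect_respiratory_events(env, fs)
  ev2 <- detect_respiratory_events(7.3 * env, fs)
  expect_equal(ev1, ev2) # baseline-relative thresholding
})

test_that("respiratory indices are correct arithmetic", {
  ev <- tibble::tibble(onset = seq(900, by = 800, length.out = 28), duration = 15)
  idx <- compute_respiratory_indices(ev, 0, 7 * 3600)
  expect_equal(idx$krei, 4.0)

  expect_equal(compute_respiratory_indices(ev[0, ], 0, 3600)$krei, 0)

  # 30 events in sleep epochs; TST 6 h of an 8-h window
  hyp <- tibble::tibble(epoch_index = 1:960,
                        label = rep(c("sleep", "wake"), c(720, 240)))
  ev30 <- tibble::tibble(onset = seq(100, by = 700, length.out = 30), duration = 15)
  idx30 <- compute_respiratory_indices(ev30, 0, 8 * 3600, hyp)
  expect_equal(idx30$krei, 3.75)
  expect_equal(idx30$krei_sleep, 5.0)

  # no hypnogram or zero sleep: flagged unavailable
  expect_true(is.na(compute_respiratory_indices(ev30, 0, 8 * 3600)$krei_sleep))
  all_wake <- tibble::tibble(epoch_index = 1:960, label = "wake")
  expect_true(is.na(compute_respiratory_indices(ev30, 0, 8 * 3600, all_wake)$krei_sleep))

  # events outside the lights window do not count
  out <- tibble::tibble(onset = c(-100, 100, 9e4), duration = 15)
  expect_equal(compute_respiratory_indices(out, 0, 3600)$n_events, 1L)
})

test_that("extracted breathing signal recovers the configured oscillation", {
  sc <- quick_scene(duration = 120, noise_sd = 0, invalid_pixel_rate = 0, seed = 2)
  sch <- generate_event_schedule(sc, still_plan())
  video <- render_depth_video(sc, sch)
  br <- extract_breathing_signal(video, smooth_s = 0)
  mid <- br$value[200:1000]
  p2p <- compute_envelope(br, 5, 10)[200:1000] * 2
  expect_equal(median(p2p), sc$breathing_amplitude, tolerance = 0.1 * sc$breathing_amplitude)
  # spectral peak at the configured breathing rate
  per <- estimate_breathing_period(br)
  expect_equal(1 / per, sc$breathing_rate / 60, tolerance = 0.05)
})

test_that("constant frames give an all-zero breathing signal after detrending", {
  v <- depth_video(array(1800, c(24, 18, 400)), frame_rate = 10)
  seg <- list(roi_mask = matrix(TRUE, 24, 18))
  class(seg) <- "body_segmentation"
  br <- extract_breathing_signal(v, segmentation = seg)
  expect_true(all(abs(br$value) < 1e-9))
})

test_that("scripted central apnea silences the rendered torso oscillation", {
  sc <- quick_scene(duration = 120, noise_sd = 0, invalid_pixel_rate = 0, seed = 3)
  plan <- still_plan(respiratory_rate = 30) # forces one event in 2 min window
  sch <- generate_event_schedule(sc, plan)
  # overwrite with one central event at a known position
  sch$respiratory <- tibble::tibble(onset = 60, duration = 15, type = "central",
                                    amplitude_fraction = 0)
  video <- render_depth_video(sc, sch)
  br <- extract_breathing_signal(video, smooth_s = 0)
  inside <- br$value[br$time > 62 & br$time < 73]
  outside <- br$value[br$time > 20 & br$time < 50]
  expect_lt(sd(inside), 0.1 * sd(outside))
})
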