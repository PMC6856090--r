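# Shared builders for synthetic test scenes. Tests run at reduced scale
# (48x36 px, 10 frames/s) so whole nights stay cheap; the 30-fps/900-frame
# epoch bookkeeping has its own dedicated test.

quick_scene <- function(duration = 120, seed = 1L, frame_rate = 10,
                        noise_sd = 1, invalid_pixel_rate = 0.01, ...) {
  scene_config(
    frame_rate = frame_rate, duration = duration, image_size = c(48L, 36L),
    noise_sd = noise_sd, invalid_pixel_rate = invalid_pixel_rate,
    seed = seed, ...
  )
}

# a plan with no wake and no spontaneous movement: pure sleep background
still_plan <- function(...) {
  event_plan(whole_body_rate = 0, sleep_latency_min = 0, awakenings = 0, ...)
}

quick_config <- function(duration = 3600, seed = 1L, ...) {
  run_config(
    scene = list(duration = duration, frame_rate = 10,
                 image_size = c(48L, 36L)),
    seed = seed, ...
  )
}

# analysis options matching the quick scenes
quick_opts <- function(...) signal_options(...)

# deterministic random movement trains for PLM grouping tests, with intervals
# drawn to straddle the 5-s and 90-s periodicity boundaries
random_train <- function(n, rng_intervals = c(3, 4.99, 5, 5.01, 20, 45, 89.99, 90, 90.01, 120)) {
  iv <- sample(rng_intervals, n - 1, replace = TRUE)
  onsets <- cumsum(c(0, iv))
  tibble::tibble(onset = onsets, duration = pmin(1, diff(c(onsets, onsets[n] + 2)) / 2))
}

# independent brute-force oracle for PLM grouping: enumerate all maximal
# contiguous windows whose members are eligible (not adjacent to a < 5 s
# interval) and whose internal intervals all lie in [5, 90]
plm_oracle <- function(onsets, min_i = 5, max_i = 90, min_run = 4) {
  n <- length(onsets)
  id <- rep(NA_integer_, n)
  if (n == 0) return(id)
  iv <- diff(onsets)
  excl <- rep(FALSE, n)
  excl[which(iv < min_i)] <- TRUE
  excl[which(iv < min_i) + 1L] <- TRUE
  ok <- iv >= min_i & iv <= max_i
  sid <- 0L
  for (a in seq_len(n)) {
    for (b in a:n) {
      valid <- !any(excl[a:b]) && (a == b || all(ok[a:(b - 1)]))
      if (!valid) next
      if (b - a + 1L < min_run) next
      left_ext <- a > 1 && !excl[a - 1] && ok[a - 1]
      right_ext <- b < n && !excl[b + 1] && ok[b]
      if (!left_ext && !right_ext && all(is.na(id[a:b]))) {
        sid <- sid + 1L
        id[a:b] <- sid
      }
    }
  }
  id
}
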