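# Epoch motion features and the undersampled boosted-tree classifier.

# constant-depth video with optional injected frame changes
flat_video <- function(n_frames, rows = 16, cols = 12, depth = 1500, fps = 30) {
  depth_video(array(depth, c(rows, cols, n_frames)), frame_rate = fps)
}

test_that("epoch features are zero for identical frames and 900 frames form one epoch", {
  v <- flat_video(900)
  ft <- compute_epoch_features(v)
  expect_equal(nrow(ft), 1)
  expect_true(all(as.matrix(ft[, -1]) == 0))
  expect_equal(ncol(ft) - 1, 4 + 4 + 4 * 16)
})

test_that("a single uniform frame change gives max = c and mean = c/899", {
  v <- flat_video(900)
  v$frames[, , 500:900] <- v$frames[, , 500:900] + 7 # one changed pair at 499->500
  ft <- compute_epoch_features(v)
  expect_equal(ft$fd_max, 7, tolerance = 1e-9)
  expect_equal(ft$fd_mean, 7 / 899, tolerance = 1e-9)
  expect_equal(ft$fd_min, 0)
})

test_that("a partial trailing epoch is dropped with a message", {
  v <- flat_video(950)
  expect_message(ft <- compute_epoch_features(v), "partial trailing epoch")
  expect_equal(nrow(ft), 1)
})

test_that("change confined to one raster cell stays in that cell", {
  v <- flat_video(300, rows = 16, cols = 12, fps = 10)
  # cell r1c1 covers rows 1-4, cols 1-3
  v$frames[1:4, 1:3, 150:300] <- v$frames[1:4, 1:3, 150:300] + 12
  ft <- compute_epoch_features(v)
  expect_gt(ft$cell_r1c1_mean, 0)
  other <- grep("^cell_(?!r1c1)", names(ft), perl = TRUE, value = TRUE)
  expect_true(all(as.matrix(ft[, grep("_max$", other, value = TRUE)]) == 0))
})

test_that("feature tables are deterministic for identical video", {
  sc <- quick_scene(duration = 90, seed = 3)
  sch <- generate_event_schedule(sc, still_plan())
  src <- render_night(sc, sch)
  f1 <- compute_epoch_features(src)
  f2 <- compute_epoch_features(src)
  expect_identical(f1, f2)
})

# ---- classifier -------------------------------------------------------------

fake_table <- function(n, p_wake, informative = TRUE, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    lab <- ifelse(runif(n) < p_wake, "wake", "sleep")
    mu <- if (informative) ifelse(lab == "wake", 1.5, 0) else 0
    tibble::tibble(
      epoch_index = seq_len(n),
      f_motion = rnorm(n, mu, sd),
      f_local = rnorm(n, mu / 2, sd),
      f_noise = rnorm(n),
      label = lab
    )
  })
}

test_that("a linearly separable toy set is learned perfectly", {
  tab <- fake_table(200, 0.3, sd = 0.01, seed = 2)
  m <- train_sleep_wake(tab, rounds = 10, seed = 1)
  pred <- predict_hypnogram(m, tab)
  expect_equal(pred$label, tab$label)
})

test_that("labels independent of features give chance-level held-out accuracy", {
  tab <- fake_table(1000, 0.5, informative = FALSE, seed = 3)
  m <- train_sleep_wake(tab[1:500, ], rounds = 20, seed = 1)
  pred <- predict_hypnogram(m, tab[501:1000, ])
  truth <- tab$label[501:1000]
  bal <- mean(c(
    mean(pred$label[truth == "wake"] == "wake"),
    mean(pred$label[truth == "sleep"] == "sleep")
  ))
  expect_lt(abs(bal - 0.5), 0.07)
})

test_that("undersampling improves wake recall under heavy class imbalance", {
  tab <- fake_table(2000, 0.05, sd = 1.6, seed = 4)
  test <- fake_table(2000, 0.05, sd = 1.6, seed = 5)
  m_rus <- train_sleep_wake(tab, rounds = 30, seed = 1, undersample = TRUE)
  m_raw <- train_sleep_wake(tab, rounds = 30, seed = 1, undersample = FALSE)
  recall <- function(m) {
    pred <- predict_hypnogram(m, test)
    mean(pred$label[test$label == "wake"] == "wake")
  }
  expect_gt(recall(m_rus), recall(m_raw))
})

test_that("training is deterministic in the seed and models serialise losslessly", {
  tab <- fake_table(400, 0.2, seed = 6)
  m1 <- train_sleep_wake(tab, rounds = 15, seed = 9)
  m2 <- train_sleep_wake(tab, rounds = 15, seed = 9)
  expect_identical(predict_hypnogram(m1, tab), predict_hypnogram(m2, tab))

  f <- withr::local_tempfile(fileext = ".rds")
  write_sleep_wake_model(m1, f)
  m3 <- read_sleep_wake_model(f)
  expect_identical(predict_hypnogram(m1, tab), predict_hypnogram(m3, tab))
})

test_that("training and prediction reject unusable input", {
  tab <- fake_table(100, 0.3, seed = 7)
  one_class <- dplyr::mutate(tab, label = "sleep")
  expect_error(train_sleep_wake(one_class), "both classes")
  m <- train_sleep_wake(tab, rounds = 5, seed = 1)
  expect_error(predict_hypnogram(m, tab[, -2]), "feature columns")
})

test_that("confusion metrics match hand-computed values", {
  # constructed table: TP 950, FN 50, TN 325, FP 675
  ref <- rep(c("sleep", "wake"), c(1000, 1000))
  pred <- c(rep("sleep", 950), rep("wake", 50), rep("sleep", 675), rep("wake", 325))
  m <- evaluate_sleep_wake(pred, ref)
  expect_equal(m$sleep_sensitivity, 0.95)
  expect_equal(m$wake_detection_rate, 0.325)
  expect_equal(m$ppv, 950 / 1625, tolerance = 1e-9)
  expect_equal(m$npv, 325 / 375, tolerance = 1e-9)

  ident <- evaluate_sleep_wake(ref, ref)
  expect_equal(ident$sleep_sensitivity, 1.0)
  expect_equal(ident$wake_detection_rate, 1.0)

  lazy <- evaluate_sleep_wake(rep("sleep", 2000), ref)
  expect_equal(lazy$sleep_sensitivity, 1.0)
  expect_equal(lazy$wake_detection_rate, 0.0)
  expect_error(evaluate_sleep_wake(pred[1:10], ref), "length")
})
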