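# Epoch motion features and the sleep/wake classifier: an ensemble of
# depth-limited decision trees boosted with per-round random undersampling of
# the majority class (RUSBoost), addressing the heavy sleep >> wake imbalance
# of nocturnal recordings.

#' Per-epoch motion features
#'
#' For every complete 30-s epoch (900 frames at 30 frames/s) three feature
#' blocks are computed from absolute frame-to-frame changes: (a) mean, median,
#' min and max of the per-frame-pair mean change series within the epoch
#' (899 pairs per 900-frame epoch); (b) the same statistics over the
#' per-pixel time-averaged change image; (c) the per-cell statistics of that
#' image under an `R x C` raster (default 4 x 4). Invalid pixels are excluded
#' from all means. Changes are computed on rectified elevation maps by
#' default; `mode = "raw"` uses raw depth values instead.
#'
#' @param x A [depth_video] or `depth_video_source`.
#' @param plane Optional [estimate_bed_plane()] result (elevation mode).
#' @param raster Raster grid `c(R, C)`.
#' @param lights_off Epoch grid anchor, s.
#' @param epoch_s Epoch length, s.
#' @param mode `"elevation"` (default) or `"raw"`.
#' @return An epoch feature tibble: `epoch_index` plus `4 + 4 + 4*R*C`
#'   feature columns in fixed order. A partial trailing epoch is dropped with
#'   a log message.
#' @export
compute_epoch_features <- function(x, plane = NULL, raster = c(4, 4),
                                   lights_off = 0, epoch_s = 30,
                                   mode = c("elevation", "raw")) {
  mode <- match.arg(mode)
  if (inherits(x, "depth_video_source") && lights_off != 0) {
    abort("lazily rendered sources use lights_off = 0")
  }
  fs <- x$frame_rate
  per <- as.integer(round(epoch_s * fs))
  stopifnot(per == x$chunk_size) # chunking is epoch-aligned by construction
  if (mode == "elevation") {
    if (is.null(plane)) plane <- estimate_bed_plane(x)
    g <- as.numeric(plane_g_factor(plane, x$dim, x$intrinsics))
    d <- plane$d
  }
  cells <- raster_cells(x$dim, raster)
  n_ep <- x$n_frames %/% per
  if (x$n_frames %% per != 0) {
    message("dropped 1 partial trailing epoch (", x$n_frames %% per, " frames)")
  }
  rows <- vector("list", n_ep)
  for (i in seq_len(n_ep)) {
    M <- source_chunk(x, i)
    V <- M > 0
    E <- if (mode == "elevation") d - M * g else M
    E[!V] <- 0
    nt <- ncol(E)
    D <- abs(E[, -1, drop = FALSE] - E[, -nt, drop = FALSE])
    VP <- V[, -1, drop = FALSE] & V[, -nt, drop = FALSE]
    rows[[i]] <- epoch_features_from_pairs(D, VP, cells, raster)
  }
  dplyr::bind_cols(
    tibble::tibble(epoch_index = seq_len(n_ep)),
    tibble::as_tibble(do.call(rbind, rows))
  )
}

feature_matrix <- function(table) {
  drop <- intersect(c("epoch_index", "label", "night_id"), names(table))
  as.matrix(table[, setdiff(names(table), drop), drop = FALSE])
}

#' Train the sleep/wake classifier
#'
#' Boosted decision trees with per-round random undersampling of the majority
#' class: each boosting round draws, with probability proportional to the
#' current boosting weights, a subsample of the majority class matching the
#' minority class at `undersample_ratio`, fits a depth-limited tree on the
#' balanced sample, computes the weighted training error on the full set,
#' and updates the instance weights multiplicatively (AdaBoost.M1 with the
#' conventional tree weight `0.5 log((1 - e)/e)`). A round reaching zero
#' weighted error stops training early (recorded in the model).
#'
#' @param table Epoch feature tibble with a `label` column (`wake`/`sleep`).
#' @param rounds Boosting rounds.
#' @param tree_depth Maximum tree depth.
#' @param undersample_ratio Majority:minority sample ratio per round (1 =
#'   balanced).
#' @param seed Integer seed; training is deterministic given it.
#' @param undersample Set `FALSE` for a plain AdaBoost baseline without
#'   undersampling (used to quantify what the undersampling buys).
#' @return A `sleep_wake_model`: trees, tree weights, feature names,
#'   training metadata.
#' @export
train_sleep_wake <- function(table, rounds = 50, tree_depth = 4,
                             undersample_ratio = 1, seed = 1L,
                             undersample = TRUE) {
  if (!"label" %in% names(table)) abort("training table needs a `label` column")
  y <- as.character(table$label)
  classes <- sort(unique(y))
  if (length(classes) != 2) abort("training needs both classes (wake and sleep)")
  if (rounds < 1) abort("`rounds` must be >= 1")
  X <- feature_matrix(table)
  n <- nrow(X)
  df <- data.frame(X, .y = factor(y, levels = classes))

  withr::with_seed(as.integer(seed), {
    w <- rep(1 / n, n)
    trees <- list()
    alphas <- numeric(0)
    early_stop <- NA_integer_
    maj <- names(which.max(table(y)))
    mino <- setdiff(classes, maj)
    for (m in seq_len(rounds)) {
      if (undersample) {
        i_min <- which(y == mino)
        i_maj <- which(y == maj)
        k <- min(length(i_maj), round(undersample_ratio * length(i_min)))
        pick <- sample(i_maj, k, prob = w[i_maj])
        idx <- c(i_min, pick)
      } else {
        idx <- seq_len(n)
      }
      fit <- rpart::rpart(
        .y ~ ., data = df[idx, , drop = FALSE], weights = w[idx] / sum(w[idx]),
        method = "class",
        control = rpart::rpart.control(maxdepth = tree_depth, cp = 0,
                                       minsplit = 2, minbucket = 1,
                                       xval = 0, maxcompete = 0,
                                       maxsurrogate = 0)
      )
      pred <- as.character(predict(fit, df, type = "class"))
      err <- sum(w[pred != y]) / sum(w)
      if (err >= 0.5) {
        # no better than chance under current weights: restart weights
        w <- rep(1 / n, n)
        next
      }
      alpha <- if (err == 0) 10 else 0.5 * log((1 - err) / err)
      trees[[length(trees) + 1]] <- fit
      alphas <- c(alphas, alpha)
      if (err == 0) {
        early_stop <- m
        break
      }
      w <- w * exp(alpha * ifelse(pred != y, 1, -1))
      w <- w / sum(w)
    }
  })
  if (length(trees) == 0) abort("boosting failed: no tree beat chance")
  structure(
    list(
      trees = trees, alphas = alphas, classes = classes,
      feature_names = colnames(X),
      meta = list(rounds = rounds, tree_depth = tree_depth,
                  undersample_ratio = undersample_ratio, seed = seed,
                  undersample = undersample, early_stop = early_stop,
                  n_train = n, version = "1")
    ),
    class = "sleep_wake_model"
  )
}

#' @export
print.sleep_wake_model <- function(x, ...) {
  cat("<sleep_wake_model> ", length(x$trees), " trees (depth <= ",
      x$meta$tree_depth, "), classes: ", paste(x$classes, collapse = "/"),
      if (!is.na(x$meta$early_stop)) paste0(", early stop at round ", x$meta$early_stop),
      "\n", sep = "")
  invisible(x)
}

#' Model summary
#'
#' @param x A `sleep_wake_model`.
#' @param ... Unused.
#' @return One-row tibble of training metadata.
#' @export
glance.sleep_wake_model <- function(x, ...) {
  tibble::tibble(
    n_trees = length(x$trees), rounds = x$meta$rounds,
    tree_depth = x$meta$tree_depth,
    undersample_ratio = x$meta$undersample_ratio,
    undersample = x$meta$undersample,
    early_stop = x$meta$early_stop, n_train = x$meta$n_train,
    seed = x$meta$seed
  )
}

#' Predict per-epoch sleep/wake labels
#'
#' Weighted vote of the boosted trees, mapped to `wake`/`sleep`. Deterministic.
#'
#' @param model A [train_sleep_wake()] model.
#' @param table Epoch feature tibble with the training feature columns.
#' @return Tibble with `epoch_index` and predicted `label`.
#' @export
predict_hypnogram <- function(model, table) {
  X <- feature_matrix(table)
  if (!identical(colnames(X), model$feature_names)) {
    abort("feature columns do not match the model's training features")
  }
  df <- data.frame(X)
  score <- rep(0, nrow(X))
  pos <- model$classes[2]
  for (i in seq_along(model$trees)) {
    p <- as.character(predict(model$trees[[i]], df, type = "class"))
    score <- score + model$alphas[i] * ifelse(p == pos, 1, -1)
  }
  lab <- ifelse(score >= 0, pos, model$classes[1])
  tibble::tibble(
    epoch_index = if ("epoch_index" %in% names(table)) table$epoch_index else seq_len(nrow(X)),
    label = lab
  )
}

#' Save / load a sleep/wake model
#'
#' Versioned single-file serialisation; a reloaded model yields identical
#' predictions.
#'
#' @param model A `sleep_wake_model`.
#' @param path File path.
#' @return `read_sleep_wake_model()` returns the model.
#' @export
write_sleep_wake_model <- function(model, path) {
  stopifnot(inherits(model, "sleep_wake_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_sleep_wake_model
#' @export
read_sleep_wake_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sleep_wake_model")) abort("not a sleep_wake_model file")
  m
}

#' Epoch-level sleep/wake agreement metrics
#'
#' 2x2 confusion metrics with sleep as the positive class: sleep sensitivity
#' (fraction of reference sleep epochs predicted sleep), wake detection rate
#' (fraction of reference wake epochs predicted wake), positive and negative
#' predictive value of sleep detection, and the raw counts.
#'
#' @param predicted,reference Equal-length label vectors (or tibbles with a
#'   `label` column) in `wake`/`sleep`.
#' @return One-row tibble: `sleep_sensitivity`, `wake_detection_rate`, `ppv`,
#'   `npv`, `tp`, `fn`, `tn`, `fp`, `accuracy`.
#' @export
evaluate_sleep_wake <- function(predicted, reference) {
  p <- if (is.data.frame(predicted)) predicted$label else as.character(predicted)
  r <- if (is.data.frame(reference)) reference$label else as.character(reference)
  if (length(p) != length(r)) abort("predicted and reference differ in length")
  tp <- sum(p == "sleep" & r == "sleep")
  fn <- sum(p == "wake" & r == "sleep")
  tn <- sum(p == "wake" & r == "wake")
  fp <- sum(p == "sleep" & r == "wake")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  tibble::tibble(
    sleep_sensitivity = div(tp, tp + fn),
    wake_detection_rate = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    tp = tp, fn = fn, tn = tn, fp = fp,
    accuracy = div(tp + tn, length(p))
  )
}
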