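# Chunked extraction of the breathing signal, leg-motion signal, whole-body
# movement trace and epoch motion features from a depth video or a lazily
# rendered source. Frames are processed one 30-s scoring epoch at a time so
# full nights never have to fit in memory.

#' Options for night-level signal extraction
#'
#' @param seg_threshold Body elevation threshold for segmentation, mm.
#' @param torso_span,leg_span Axis spans passed to [segment_body()].
#' @param head_end Axis orientation rule for [segment_body()].
#' @param fill_kernel Moving-average kernel for the reference frame.
#' @param wb_pixel_change_mm Per-pixel frame-to-frame change counting as
#'   moved, mm.
#' @param wb_area_fraction Fraction of body pixels that must move for a
#'   whole-body movement.
#' @param wb_min_duration_s Minimum whole-body movement duration, s.
#' @param wb_flag_margin_s Margin around whole-body movements within which
#'   frames are flagged (excluded from breathing baseline and events).
#' @param resegment Re-run segmentation after each whole-body movement (the
#'   body may have moved); the update takes effect at the next epoch boundary.
#' @param raster Raster grid `c(R, C)` for epoch motion features.
#' @param highpass_hz Detrending cutoff for the breathing signal.
#' @param smooth_s Band-limiting moving-average width for the breathing
#'   signal, s: sensor noise is white while breathing lives below ~0.5 Hz, so
#'   a short average cuts the envelope noise floor without touching the band.
#' @return A list of options.
#' @export
signal_options <- function(seg_threshold = 30, torso_span = c(0.25, 0.55),
                           leg_span = c(0.60, 1.00), head_end = "auto",
                           fill_kernel = 3,
                           wb_pixel_change_mm = 10, wb_area_fraction = 0.3,
                           wb_min_duration_s = 1, wb_flag_margin_s = 2,
                           resegment = TRUE, raster = c(4, 4),
                           highpass_hz = 0.05, smooth_s = 0.5) {
  list(
    seg_threshold = seg_threshold, torso_span = torso_span,
    leg_span = leg_span, head_end = head_end, fill_kernel = fill_kernel,
    wb_pixel_change_mm = wb_pixel_change_mm,
    wb_area_fraction = wb_area_fraction,
    wb_min_duration_s = wb_min_duration_s,
    wb_flag_margin_s = wb_flag_margin_s,
    resegment = resegment, raster = as.integer(raster),
    highpass_hz = highpass_hz, smooth_s = smooth_s
  )
}

# Reference frame of one chunk: per-pixel median of valid samples, filled and
# lightly smoothed, ready for segmentation.
chunk_reference_frame <- function(E, V, dim, kernel) {
  En <- E
  En[!V] <- NA_real_
  med <- apply(En, 1, median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  suppressWarnings(fill_and_smooth(matrix(med, dim[1], dim[2]), kernel = kernel))
}

# pixel indices of each raster cell (1..R*C, cells numbered column-major)
raster_cells <- function(dim, raster) {
  r_bin <- ceiling(seq_len(dim[1]) / (dim[1] / raster[1]))
  c_bin <- ceiling(seq_len(dim[2]) / (dim[2] / raster[2]))
  id <- as.integer(outer(r_bin, (c_bin - 1) * raster[1], "+"))
  split(seq_along(id), id)
}

stat4 <- function(x, prefix) {
  x <- x[is.finite(x)]
  if (length(x) == 0) x <- 0
  out <- c(mean(x), median(x), min(x), max(x))
  names(out) <- paste0(prefix, "_", c("mean", "median", "min", "max"))
  out
}

# Feature vector of one epoch from its within-epoch pair matrices:
# D = |frame-to-frame elevation change| (npx x n_pairs), VP = pair validity.
# `cells` is the list of pixel indices per raster cell (see raster_cells).
epoch_features_from_pairs <- function(D, VP, cells, raster) {
  fd <- colSums(D * VP) / pmax(colSums(VP), 1)
  mpx <- rowSums(D * VP) / rowSums(VP) # NaN where a pixel was never valid
  cellstats <- unlist(lapply(seq_len(raster[1] * raster[2]), function(k) {
    r <- (k - 1) %% raster[1] + 1
    c <- (k - 1) %/% raster[1] + 1
    stat4(mpx[cells[[k]]], sprintf("cell_r%dc%d", r, c))
  }))
  c(stat4(fd, "fd"), stat4(mpx, "px"), cellstats)
}

#' Extract all nightly signals from a depth recording
#'
#' Runs the full front end over a [depth_video] or [render_night()] source in
#' one chunked pass: bed-plane rectification, body segmentation on a reference
#' frame (median of the first 30 s, re-run after each whole-body movement),
#' the thoracic-disk breathing signal, the lower-body leg-motion signal, the
#' whole-body movement trace, and per-epoch motion features.
#'
#' @param x A [depth_video] or `depth_video_source`.
#' @param opts A [signal_options()] list.
#' @param plane Optional precomputed [estimate_bed_plane()] result.
#' @param lights_off Recording time of lights-off, s (epoch grid anchor).
#'   Lazily rendered sources require `lights_off = 0`.
#' @return A `night_signals` list: `breathing` (tibble `time`, `value`
#'   detrended mm, `flagged`), `leg` (tibble `time`, `value` mm/frame),
#'   `frame_change` and `body_change_frac` (per frame pair), `whole_body`
#'   events, `features` (epoch feature tibble), `segmentation` (initial),
#'   `plane`, `sample_rate`, and quality flags.
#' @export
extract_night_signals <- function(x, opts = signal_options(), plane = NULL,
                                  lights_off = 0) {
  if (inherits(x, "depth_video_source") && lights_off != 0) {
    abort("lazily rendered sources use lights_off = 0")
  }
  fs <- x$frame_rate
  dims <- x$dim
  npx <- prod(dims)
  if (is.null(plane)) plane <- estimate_bed_plane(x)
  g <- as.numeric(plane_g_factor(plane, dims, x$intrinsics))
  cells <- raster_cells(dims, opts$raster)
  nch <- n_source_chunks(x)
  cs <- x$chunk_size
  n_f <- x$n_frames

  seg <- NULL
  seg_log <- list()
  roi_idx <- leg_idx <- body_idx <- NULL
  ref_elev <- NULL # per-pixel reference elevation of the current segmentation
  update_seg <- function(E, V, at_chunk) {
    ref <- chunk_reference_frame(E, V, dims, opts$fill_kernel)
    s <- segment_body(ref, threshold = opts$seg_threshold,
                      torso_span = opts$torso_span, leg_span = opts$leg_span,
                      head_end = opts$head_end)
    seg <<- s
    roi_idx <<- which(s$roi_mask)
    leg_idx <<- which(s$lower_body_mask)
    body_idx <<- which(s$body_mask)
    ref_elev <<- as.numeric(ref)
    seg_log[[length(seg_log) + 1]] <<- list(chunk = at_chunk, segmentation = s)
    invisible(s)
  }

  breathing_raw <- numeric(n_f)
  roi_empty <- logical(n_f)
  leg_val <- numeric(max(n_f - 1L, 0))
  frame_change <- numeric(max(n_f - 1L, 0))
  body_frac <- numeric(max(n_f - 1L, 0))
  feat_rows <- list()
  feat_epochs <- integer(0)

  prev <- NULL # list(E, V) of the last frame of the previous chunk
  pending_reseg <- FALSE
  wb_thresh_len <- max(1L, as.integer(round(opts$wb_min_duration_s * fs)))
  gap_max <- max(1L, as.integer(ceiling(0.5 * fs)))
  # movement-cluster state across chunks (global pair indices); clusters merge
  # across gaps < 0.5 s, mirroring the offline event assembly
  wb_in <- FALSE
  wb_start <- 0L
  wb_last <- 0L
  wb_gap <- 0L

  pair_stats <- function(dE, vp) {
    lv <- if (length(leg_idx)) sum(dE[leg_idx] * vp[leg_idx]) / max(sum(vp[leg_idx]), 1) else 0
    fc <- sum(dE * vp) / max(sum(vp), 1)
    bf <- if (length(body_idx)) {
      sum((dE[body_idx] > opts$wb_pixel_change_mm) & vp[body_idx]) /
        max(sum(vp[body_idx]), 1)
    } else 0
    c(lv, fc, bf)
  }

  for (i in seq_len(nch)) {
    from <- (i - 1L) * cs + 1L
    to <- min(i * cs, n_f)
    M <- source_chunk(x, i)
    V <- M > 0
    E <- plane$d - M * g
    E[!V] <- 0
    nt <- ncol(E)

    if (is.null(seg)) {
      update_seg(E, V, i)
    } else if (pending_reseg && !wb_in && opts$resegment) {
      update_seg(E, V, i)
      pending_reseg <- FALSE
    }

    # ROI mean of reference-subtracted elevation: centering each pixel on its
    # static reference keeps the mean unbiased when random invalid pixels drop
    # out of a region whose absolute elevations span tens of millimetres
    Vr <- V[roi_idx, , drop = FALSE]
    nv <- colSums(Vr)
    bsum <- colSums((E[roi_idx, , drop = FALSE] - ref_elev[roi_idx]) * Vr)
    breathing_raw[from:to] <- ifelse(nv > 0, bsum / pmax(nv, 1), NA_real_)
    roi_empty[from:to] <- nv == 0

    # boundary pair with the previous chunk
    if (!is.null(prev)) {
      dE <- abs(E[, 1] - prev$E)
      vp <- V[, 1] & prev$V
      st <- pair_stats(dE, vp)
      leg_val[from - 1L] <- st[1]
      frame_change[from - 1L] <- st[2]
      body_frac[from - 1L] <- st[3]
    }
    if (nt > 1) {
      D <- abs(E[, -1, drop = FALSE] - E[, -nt, drop = FALSE])
      VP <- V[, -1, drop = FALSE] & V[, -nt, drop = FALSE]
      idx <- from:(to - 1L)
      leg_val[idx] <- masked_col_means(D, VP, leg_idx)
      frame_change[idx] <- colSums(D * VP) / pmax(colSums(VP), 1)
      body_frac[idx] <- colSums((D[body_idx, , drop = FALSE] > opts$wb_pixel_change_mm) &
                                  VP[body_idx, , drop = FALSE]) /
        pmax(colSums(VP[body_idx, , drop = FALSE]), 1)
      if (nt == cs) { # complete epoch
        feat_rows[[length(feat_rows) + 1]] <-
          epoch_features_from_pairs(D, VP, cells, opts$raster)
        feat_epochs <- c(feat_epochs, i)
      }
    }

    # online whole-body tracking for the resegmentation policy: clusters of
    # moved pairs (gaps < 0.5 s bridged, as in the offline event assembly)
    # spanning at least the minimum movement duration mark the body as
    # possibly shifted; segmentation is then re-run -- immediately on the rest
    # of this chunk when enough clean frames remain, otherwise at the next
    # chunk boundary
    hp <- as.integer(!is.null(prev))
    p0 <- from - hp # global pair index of the first pair in this chunk
    fr <- body_frac[p0:(to - 1L)]
    clean_frame <- NA_integer_ # first in-chunk frame after the last ended movement
    for (k in seq_along(fr)) {
      p <- p0 + k - 1L
      if (fr[k] > opts$wb_area_fraction) {
        if (!wb_in) {
          wb_in <- TRUE
          wb_start <- p
        }
        wb_last <- p
        wb_gap <- 0L
      } else if (wb_in) {
        wb_gap <- wb_gap + 1L
        if (wb_gap >= gap_max) {
          if (wb_last - wb_start + 1L >= wb_thresh_len) {
            pending_reseg <- TRUE
            clean_frame <- wb_last + 2L - from + 1L # frame after the last moved pair
          }
          wb_in <- FALSE
          wb_gap <- 0L
        }
      }
    }
    if (pending_reseg && opts$resegment && !is.na(clean_frame) &&
        clean_frame >= 1L && nt - clean_frame + 1L >= max(50L, cs %/% 3L)) {
      fc <- clean_frame
      update_seg(E[, fc:nt, drop = FALSE], V[, fc:nt, drop = FALSE], i)
      pending_reseg <- FALSE
      cols <- fc:nt
      Vr <- V[roi_idx, cols, drop = FALSE]
      nv <- colSums(Vr)
      bsum <- colSums((E[roi_idx, cols, drop = FALSE] - ref_elev[roi_idx]) * Vr)
      breathing_raw[from + cols - 1L] <- ifelse(nv > 0, bsum / pmax(nv, 1), NA_real_)
      roi_empty[from + cols - 1L] <- nv == 0
      if (fc <= nt - 1L) {
        Ds <- abs(E[, (fc + 1L):nt, drop = FALSE] - E[, fc:(nt - 1L), drop = FALSE])
        VPs <- V[, (fc + 1L):nt, drop = FALSE] & V[, fc:(nt - 1L), drop = FALSE]
        pidx <- (from + fc - 1L):(to - 1L)
        leg_val[pidx] <- masked_col_means(Ds, VPs, leg_idx)
        body_frac[pidx] <- colSums((Ds[body_idx, , drop = FALSE] > opts$wb_pixel_change_mm) &
                                     VPs[body_idx, , drop = FALSE]) /
          pmax(colSums(VPs[body_idx, , drop = FALSE]), 1)
      }
    }

    prev <- list(E = E[, nt], V = V[, nt])
  }
  if (length(feat_rows) < nch) {
    message("dropped ", nch - length(feat_rows), " partial trailing epoch(s) from features")
  }

  whole_body <- assemble_movement_events(
    body_frac, fs, opts$wb_area_fraction, opts$wb_min_duration_s, t0 = lights_off
  )
  flag <- flag_frames(n_f, fs, whole_body, opts$wb_flag_margin_s, t0 = lights_off)

  time <- lights_off + (seq_len(n_f) - 1) / fs
  br <- detrend_breathing(breathing_raw, fs, opts$highpass_hz, opts$smooth_s)
  features <- if (length(feat_rows)) {
    dplyr::bind_cols(
      tibble::tibble(epoch_index = feat_epochs),
      tibble::as_tibble(do.call(rbind, feat_rows))
    )
  } else tibble::tibble(epoch_index = integer())

  structure(
    list(
      breathing = tibble::tibble(time = time, value = br, flagged = flag),
      breathing_raw = breathing_raw,
      leg = tibble::tibble(time = time[-n_f], value = leg_val),
      frame_change = frame_change,
      body_change_frac = body_frac,
      whole_body = whole_body,
      features = features,
      segmentation = seg_log[[1]]$segmentation,
      segmentation_log = seg_log,
      plane = plane, sample_rate = fs, lights_off = lights_off,
      roi_invalid_frac = mean(roi_empty)
    ),
    class = "night_signals"
  )
}

# spans where the moved-area fraction stays above the threshold long enough;
# spans separated by less than 0.5 s are merged
assemble_movement_events <- function(frac, fs, area_fraction, min_duration_s, t0 = 0) {
  r <- runs_of(frac > area_fraction)
  if (nrow(r) > 1) {
    gap <- r$start[-1] - r$end[-nrow(r)] - 1L
    keep_sep <- gap >= 0.5 * fs
    grp <- cumsum(c(TRUE, keep_sep))
    r <- dplyr::summarise(dplyr::group_by(tibble::tibble(grp = grp, s = r$start, e = r$end), grp),
                          start = min(.data$s), end = max(.data$e), .groups = "drop")[, c("start", "end")]
  }
  sp <- runs_to_spans(r, fs, t0)
  sp[sp$duration >= min_duration_s, , drop = FALSE]
}

flag_frames <- function(n_frames, fs, events, margin_s, t0 = 0) {
  flag <- logical(n_frames)
  t <- t0 + (seq_len(n_frames) - 1) / fs
  for (i in seq_len(nrow(events))) {
    flag <- flag | (t >= events$onset[i] - margin_s &
                      t <= events$onset[i] + events$duration[i] + margin_s)
  }
  flag
}

# Centered moving average with truncated windows at the edges (O(n) cumsum).
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  h <- k %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Remove linear trend and slow drift (subtract a centered moving average one
# high-pass period wide), then band-limit with a short moving average: the
# breathing band ends well below 1 Hz while sensor noise is white. NA gaps
# (fully invalid ROI) are interpolated first.
detrend_breathing <- function(raw, fs, highpass_hz, smooth_s = 0.5) {
  x <- raw
  if (anyNA(x)) {
    x <- zoo::na.approx(x, na.rm = FALSE)
    x <- zoo::na.locf(x, na.rm = FALSE)
    x <- zoo::na.locf(x, fromLast = TRUE, na.rm = FALSE)
    x[is.na(x)] <- 0
  }
  x <- x - moving_average(x, round(fs / highpass_hz))
  k <- round(smooth_s * fs)
  if (k > 1) x <- moving_average(x, k)
  x
}

# running extremes over a centered window (vectorised over window offsets;
# edge windows are truncated)
run_max <- function(x, k) {
  h <- max(0L, (as.integer(k) - 1L) %/% 2L)
  n <- length(x)
  out <- x
  for (o in seq_len(h)) {
    out <- pmax(out,
                c(x[-seq_len(o)], rep(-Inf, o)),
                c(rep(-Inf, o), x[seq_len(n - o)]))
  }
  out
}

run_min <- function(x, k) -run_max(-x, k)
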