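# Depth preprocessing: point clouds, bed-plane estimation, rectification to
# elevation above the bed, invalid-pixel filling, and body segmentation.
#
# Pixel coordinates follow the row-major, origin top-left, 0-based convention
# of depth sensors: pixel (row v, col u) back-projects along
# ray r(u,v) = ((u - cx)/fx, (v - cy)/fy, 1), with (u, v) 0-based.

#' Back-project a depth frame to a 3-D point cloud
#'
#' Pinhole back-projection `x = (u - cx) z / fx`, `y = (v - cy) z / fy` of all
#' valid pixels (depth 0 is the sensor's invalid code and is excluded).
#'
#' @param frame Numeric matrix of depth values in mm (0 = invalid).
#' @param intrinsics List with `fx`, `fy`, `cx`, `cy` (pixels, 0-based).
#' @return Tibble with columns `x`, `y`, `z` (mm) and the source pixel
#'   (`row`, `col`, 1-based). If every pixel is invalid an empty tibble is
#'   returned with a warning.
#' @export
depth_to_point_cloud <- function(frame, intrinsics) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  valid <- which(frame > 0)
  if (length(valid) == 0) {
    warn("all pixels invalid; empty point cloud")
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          row = integer(), col = integer()))
  }
  rows <- nrow(frame)
  v <- ((valid - 1L) %% rows)              # 0-based row
  u <- ((valid - 1L) %/% rows)             # 0-based col
  z <- frame[valid]
  tibble::tibble(
    x = (u - intrinsics$cx) * z / intrinsics$fx,
    y = (v - intrinsics$cy) * z / intrinsics$fy,
    z = z,
    row = as.integer(v + 1L), col = as.integer(u + 1L)
  )
}

#' Estimate the bed plane of a recording
#'
#' Fits the dominant planar background of the scene. A least-squares plane
#' `z = a + b x + c y` is fitted to pooled point clouds from sampled frames,
#' then refitted on the lowest-elevation 30% of points (the bed, farthest
#' from the camera) with one reweighting pass that drops outliers beyond 2.5
#' robust standard deviations. Robust to a body occupying part of the frame
#' without full RANSAC machinery.
#'
#' @param video A [depth_video] or lazily rendered source.
#' @param sample_frames Frame indices to pool; default up to 12 frames evenly
#'   spread over the recording.
#' @param max_points Subsample cap for the pooled cloud.
#' @return A `bed_plane`: list with unit `normal` (pointing from the bed
#'   toward the camera side), scalar `d` (plane is `n . p = d`), and
#'   `residual_rms` (mm).
#' @export
estimate_bed_plane <- function(video, sample_frames = NULL, max_points = 30000) {
  if (is.null(sample_frames)) {
    sample_frames <- unique(round(seq(1, video$n_frames, length.out = min(12, video$n_frames))))
  }
  K <- video$intrinsics
  pts <- dplyr::bind_rows(lapply(get_video_frames(video, sample_frames), function(f) {
    depth_to_point_cloud(f, K)
  }))
  if (nrow(pts) < 100) abort("too few valid points to fit a bed plane")
  if (nrow(pts) > max_points) {
    keep <- round(seq(1, nrow(pts), length.out = max_points))
    pts <- pts[keep, , drop = FALSE]
  }
  fit_plane <- function(p) {
    f <- lm(z ~ x + y, data = p)
    coef(f)
  }
  cf <- fit_plane(pts)
  if (anyNA(cf)) abort("degenerate geometry: rank-deficient plane fit")
  # signed elevation toward the camera for current fit
  elev <- function(p, cf) {
    nn <- sqrt(cf[2]^2 + cf[3]^2 + 1)
    (cf[1] + cf[2] * p$x + cf[3] * p$y - p$z) / nn
  }
  e <- elev(pts, cf)
  bed <- pts[e <= quantile(e, 0.30), , drop = FALSE]
  cf <- fit_plane(bed)
  e2 <- elev(bed, cf)
  s <- mad(e2)
  if (s > 0) {
    bed <- bed[abs(e2 - median(e2)) <= 2.5 * s, , drop = FALSE]
    cf <- fit_plane(bed)
  }
  nn <- sqrt(cf[2]^2 + cf[3]^2 + 1)
  normal <- c(-cf[2], -cf[3], 1) / nn
  d <- cf[1] / nn
  res <- elev(bed, cf)
  structure(
    list(normal = unname(normal), d = unname(d),
         residual_rms = sqrt(mean(res^2))),
    class = "bed_plane"
  )
}

#' @export
print.bed_plane <- function(x, ...) {
  cat("<bed_plane> normal (", paste(signif(x$normal, 4), collapse = ", "),
      "), d = ", round(x$d, 1), " mm, residual RMS ",
      signif(x$residual_rms, 3), " mm\n", sep = "")
  invisible(x)
}

# Per-pixel geometric factor g(u,v) = n . r(u,v): depth z at pixel (u,v) has
# elevation d - z g(u,v) above the plane. Vectorised over the whole frame.
plane_g_factor <- function(plane, dim, intrinsics) {
  rows <- dim[1]; cols <- dim[2]
  v0 <- matrix(seq_len(rows) - 1, rows, cols)
  u0 <- matrix(rep(seq_len(cols) - 1, each = rows), rows, cols)
  plane$normal[1] * (u0 - intrinsics$cx) / intrinsics$fx +
    plane$normal[2] * (v0 - intrinsics$cy) / intrinsics$fy +
    plane$normal[3]
}

#' Rectify a depth frame to elevation above the bed plane
#'
#' Removes the camera-to-bed perspective by converting each valid pixel's
#' depth to its signed orthogonal distance above the estimated bed plane
#' (positive toward the camera). Invalid pixels propagate as `NA`.
#'
#' @param frame Depth matrix (mm, 0 = invalid).
#' @param plane A `bed_plane` from [estimate_bed_plane()].
#' @param intrinsics Pinhole intrinsics (see [depth_to_point_cloud()]).
#' @return Elevation matrix in mm, `NA` where invalid.
#' @export
rectify_frame <- function(frame, plane, intrinsics) {
  g <- plane_g_factor(plane, dim(frame), intrinsics)
  e <- plane$d - frame * g
  e[frame <= 0] <- NA_real_
  e
}

#' Fill invalid pixels and smooth an elevation frame
#'
#' Invalid (`NA`) pixels are filled from their connected valid neighbourhood
#' (iterative flood-fill inpainting: each pass replaces invalid pixels that
#' touch valid ones by the mean of their valid neighbours); valid values are
#' unchanged by the fill. The frame is then smoothed with a `kernel x kernel`
#' spatial moving-average filter (replicated borders). Frames with more than
#' 50% invalid pixels are flagged low quality but still processed.
#'
#' @param frame Elevation matrix with `NA` marking invalid pixels.
#' @param kernel Odd moving-average width in pixels; `1` disables smoothing.
#' @return The processed matrix, with attribute `low_quality` set when more
#'   than half the pixels were invalid.
#' @export
fill_and_smooth <- function(frame, kernel = 3) {
  stopifnot(is.matrix(frame))
  low_quality <- mean(is.na(frame)) > 0.5
  if (anyNA(frame)) {
    if (all(is.na(frame))) abort("frame has no valid pixels to fill from")
    nb <- matrix(1, 3, 3)
    while (anyNA(frame)) {
      valid <- !is.na(frame)
      x0 <- frame
      x0[!valid] <- 0
      s <- EBImage::filter2(x0, nb, boundary = "replicate")
      n <- EBImage::filter2(valid * 1, nb, boundary = "replicate")
      fillable <- !valid & n > 1e-9
      if (!any(fillable)) break
      frame[fillable] <- s[fillable] / n[fillable]
    }
  }
  kernel <- as.integer(kernel)
  if (kernel > 1) {
    if (kernel %% 2L == 0L) abort("`kernel` must be odd")
    br <- matrix(1 / kernel^2, kernel, kernel)
    frame <- EBImage::filter2(frame, br, boundary = "replicate")
  }
  attr(frame, "low_quality") <- low_quality
  frame
}

#' Segment the body into thorax and lower-body regions
#'
#' Multi-step segmentation of a rectified, filled elevation frame: pixels more
#' than `threshold` mm above the bed form candidate body pixels; the largest
#' connected component is the body; its principal axis is the head-to-toe
#' line (the broader-mass end is taken head-ward); the thorax and lower-body
#' masks are the body pixels whose normalised axis coordinate falls in
#' `torso_span` and `leg_span`; and the thoracic region of interest is the
#' largest disk centred at the thorax centroid that fits inside the thorax
#' mask. The breathing signal is read from that disk.
#'
#' @param frame Rectified, filled elevation matrix (mm above bed).
#' @param threshold Body elevation threshold, mm.
#' @param torso_span,leg_span Fractional intervals along the head-to-toe axis.
#' @param head_end `"auto"` (broader end is the head), or `"first"`/`"last"`
#'   to force the axis orientation.
#' @return A `body_segmentation`: logical `body_mask`, `thorax_mask`,
#'   `lower_body_mask`, `roi_mask`; `body_axis` (head/foot endpoints, pixel
#'   coords); `thorax_roi` (`center`, `radius` in px).
#' @export
segment_body <- function(frame, threshold = 30, torso_span = c(0.25, 0.55),
                         leg_span = c(0.60, 1.00), head_end = "auto") {
  stopifnot(is.matrix(frame))
  mask <- !is.na(frame) & frame > threshold
  if (!any(mask)) abort("no body detected")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  body <- lab == which.max(sizes)
  idx <- which(body)
  rc <- cbind(row = (idx - 1L) %% nrow(frame) + 1L,
              col = (idx - 1L) %/% nrow(frame) + 1L)
  if (nrow(rc) < 20) abort("no body detected")

  pc <- prcomp(rc, center = TRUE, scale. = FALSE)
  dir <- pc$rotation[, 1]
  ctr <- colMeans(rc)
  proj <- as.numeric((rc[, 1] - ctr[1]) * dir[1] + (rc[, 2] - ctr[2]) * dir[2])
  s <- (proj - min(proj)) / (max(proj) - min(proj))
  flip <- switch(head_end,
    auto = sum(s < 0.25) < sum(s > 0.75), # head quarter carries more mass
    first = FALSE,
    last = TRUE,
    abort("`head_end` must be 'auto', 'first' or 'last'")
  )
  if (flip) {
    s <- 1 - s
    dir <- -dir
    proj <- -proj
  }
  head_pt <- ctr + dir * min(proj)
  foot_pt <- ctr + dir * max(proj)

  in_span <- function(span) {
    m <- matrix(FALSE, nrow(frame), ncol(frame))
    m[idx[s >= span[1] & s <= span[2]]] <- TRUE
    m
  }
  thorax <- in_span(torso_span)
  lower <- in_span(leg_span)
  if (!any(thorax)) abort("no body detected in the torso span")

  tix <- which(thorax)
  t_ctr <- c(mean((tix - 1L) %% nrow(frame) + 1L),
             mean((tix - 1L) %/% nrow(frame) + 1L))
  dm <- EBImage::distmap(thorax)
  radius <- max(1, dm[round(t_ctr[1]), round(t_ctr[2])] - 0.5)
  rr <- matrix(seq_len(nrow(frame)), nrow(frame), ncol(frame))
  cc <- matrix(rep(seq_len(ncol(frame)), each = nrow(frame)), nrow(frame), ncol(frame))
  roi <- (rr - t_ctr[1])^2 + (cc - t_ctr[2])^2 <= radius^2

  structure(
    list(
      body_mask = body, thorax_mask = thorax, lower_body_mask = lower,
      roi_mask = roi,
      body_axis = list(head = unname(head_pt), foot = unname(foot_pt)),
      thorax_roi = list(center = unname(t_ctr), radius = unname(radius))
    ),
    class = "body_segmentation"
  )
}

#' @export
print.body_segmentation <- function(x, ...) {
  cat("<body_segmentation> body ", sum(x$body_mask), " px, thorax ",
      sum(x$thorax_mask), " px, lower body ", sum(x$lower_body_mask),
      " px, ROI disk r = ", round(x$thorax_roi$radius, 1), " px\n", sep = "")
  invisible(x)
}

#' Export segmentation landmarks as JSON
#'
#' Writes the head-to-toe axis endpoints and the thoracic disk (center,
#' radius) for inspection alongside a run report.
#'
#' @param seg A `body_segmentation`.
#' @param path Output path.
#' @export
write_segmentation_json <- function(seg, path) {
  jsonlite::write_json(
    list(
      body_axis = lapply(seg$body_axis, round, 2),
      thorax_roi = list(center = round(seg$thorax_roi$center, 2),
                        radius = round(seg$thorax_roi$radius, 2)),
      body_px = sum(seg$body_mask)
    ),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

# Fetch one frame (rows x cols matrix) from a depth_video or source.
get_video_frame <- function(x, i) {
  if (inherits(x, "depth_video")) return(x$frames[, , i])
  ci <- as.integer(ceiling(i / x$chunk_size))
  ch <- source_chunk(x, ci)
  j <- i - (ci - 1L) * x$chunk_size
  matrix(ch[, j], x$dim[1], x$dim[2])
}

# Fetch several frames, rendering each underlying chunk only once.
get_video_frames <- function(x, idx) {
  if (inherits(x, "depth_video")) {
    return(lapply(idx, function(i) x$frames[, , i]))
  }
  ci <- as.integer(ceiling(idx / x$chunk_size))
  out <- vector("list", length(idx))
  for (cc in unique(ci)) {
    ch <- source_chunk(x, cc)
    for (k in which(ci == cc)) {
      j <- idx[k] - (cc - 1L) * x$chunk_size
      out[[k]] <- matrix(ch[, j], x$dim[1], x$dim[2])
    }
  }
  out
}
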