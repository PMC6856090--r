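# Synthetic depth-video renderer.
#
# The body is a smooth blanket-like elevation map above a tilted bed plane
# (the camera mostly sees the blanket, not limbs). Scene geometry is defined
# in elevation space (mm above the plane) and converted to camera depth via
# the pinhole identity: for pixel ray r(u,v) and plane {n.p = d}, a point at
# elevation e above the plane along the ray has depth
#   z = (d - e) / (n . r(u,v)),
# so elevation <-> depth is elementwise per pixel, with g(u,v) = n . r(u,v)
# precomputed once.

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Ramp 0->1 over [a, a+w] and 1->0 over [b-w, b].
ramp_in_out <- function(x, a, b, w) {
  smoothstep((x - a) / w) * smoothstep((b - x) / w)
}

# Static per-pixel geometry of the scene, all as npx vectors (column-major
# over a rows x cols matrix).
scene_geometry <- function(config) {
  rows <- config$image_size[1]; cols <- config$image_size[2]
  K <- scene_intrinsics(config)
  v <- matrix(seq_len(rows), rows, cols)        # row index
  u <- matrix(rep(seq_len(cols), each = rows), rows, cols) # col index

  theta <- config$bed_tilt * pi / 180
  g <- sin(theta) * ((v - 1) - K$cy) / K$fy + cos(theta)
  d <- config$bed_plane_depth * cos(theta)

  head <- config$body_axis$head; foot <- config$body_axis$foot
  ax <- c(foot[1] - head[1], foot[2] - head[2])
  L <- sqrt(sum(ax^2))
  axn <- ax / L
  dv <- v - head[1]; du <- u - head[2]
  s <- (dv * axn[1] + du * axn[2]) / L          # 0 at head, 1 at toe
  w <- -dv * axn[2] + du * axn[1]               # signed perpendicular px

  # half-width and height profiles along the axis (head -> toe); the torso end
  # carries more mass than the feet, which disambiguates head direction.
  s_ctl <- c(-0.05, 0.02, 0.10, 0.16, 0.30, 0.55, 0.65, 0.90, 1.00, 1.05)
  hw_ctl <- c(0.055, 0.075, 0.085, 0.165, 0.175, 0.165, 0.125, 0.100, 0.085, 0.055) * L
  h_ctl <- c(0.55, 0.70, 0.70, 1.00, 1.00, 0.95, 0.80, 0.75, 0.70, 0.55)
  hw <- approx(s_ctl, hw_ctl, xout = pmin(pmax(s, -0.05), 1.05), rule = 2)$y
  hprof <- approx(s_ctl, h_ctl, xout = pmin(pmax(s, -0.05), 1.05), rule = 2)$y

  inside <- s > -0.04 & s < 1.04 & abs(w) < hw
  cross <- ifelse(inside, sqrt(pmax(0, 1 - (w / hw)^2)), 0)
  ends <- ramp_in_out(s, -0.04, 1.04, 0.06)
  e_body <- config$body_height * hprof * cross * ends

  # blanket folds: smooth quasi-periodic texture, tapered at the body edge so
  # translation of the body changes most interior pixels by tens of mm
  fold_taper <- pmin(e_body / 40, 1)
  folds <- config$fold_amplitude *
    sin(2 * pi * (0.9 * v + 2.2 * w) / 11 + 0.7) * fold_taper

  # breathing support: thorax section of the body, flat at 1 over the core
  b_s <- ramp_in_out(s, config$torso_span[1], config$torso_span[2], 0.05)
  b_w <- smoothstep((1 - abs(w) / hw) / 0.15)
  breath_sup <- b_s * b_w * (e_body > 0)

  # leg supports: lateral halves of the leg span
  l_s <- ramp_in_out(s, config$leg_span[1], config$leg_span[2], 0.06)
  limb_w <- function(side) {
    wn <- side * w / hw # positive over the limb
    exp(-((wn - 0.5) / 0.55)^2) * (wn > 0.02) * (wn < 1)
  }
  leg_left <- l_s * limb_w(-1) * (e_body > 0)
  leg_right <- l_s * limb_w(+1) * (e_body > 0)

  list(
    rows = rows, cols = cols, npx = rows * cols,
    g = as.numeric(g), d = d, intrinsics = K,
    e_static = matrix(e_body + folds, rows, cols),
    breath_sup = matrix(breath_sup, rows, cols),
    leg_left = matrix(leg_left, rows, cols),
    leg_right = matrix(leg_right, rows, cols),
    body_taper = matrix(fold_taper, rows, cols)
  )
}

# Shift a rows x cols field sideways (column direction) by a fractional
# number of pixels, replicating the border.
shift_cols <- function(m, off) {
  if (off == 0) return(m)
  cols <- ncol(m)
  x <- seq_len(cols) - off
  lo <- pmin(pmax(floor(x), 1), cols)
  hi <- pmin(pmax(lo + 1, 1), cols)
  f <- pmin(pmax(x - floor(x), 0), 1)
  m[, lo, drop = FALSE] * rep(1 - f, each = nrow(m)) +
    m[, hi, drop = FALSE] * rep(f, each = nrow(m))
}

# Time courses driven by the schedule ------------------------------------------

# residual breathing-amplitude fraction at each time
amplitude_fraction_at <- function(t, respiratory) {
  af <- rep(1, length(t))
  for (i in seq_len(nrow(respiratory))) {
    on <- respiratory$onset[i]; off <- on + respiratory$duration[i]
    af[t >= on & t < off] <- respiratory$amplitude_fraction[i]
  }
  af
}

# Leg displacement (mm) per limb side: fast rise and fall (15% of the event
# duration each) around a sustained plateau carrying a small 1.5-Hz tremor --
# the jerk-then-hold morphology of periodic limb movements seen through a
# blanket.
leg_displacement_at <- function(t, leg, side) {
  out <- rep(0, length(t))
  rows <- leg[leg$limb %in% c(side, "both"), , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    on <- rows$onset[i]; du <- rows$duration[i]
    sel <- t >= on & t < on + du
    tau <- (t[sel] - on) / du
    rf <- smoothstep(tau / 0.15) * smoothstep((1 - tau) / 0.15)
    trem <- 0.8 + 0.2 * sin(2 * pi * 2.2 * (t[sel] - on))
    out[sel] <- out[sel] + rows$displacement[i] * rf * trem
  }
  out
}

# lateral body offset (px) and vertical wiggle (mm) from whole-body movements
whole_body_motion_at <- function(t, whole_body) {
  off <- rep(0, length(t))
  wig <- rep(0, length(t))
  if (nrow(whole_body) == 0) return(list(offset = off, wiggle = wig))
  cum <- cumsum(whole_body$shift_px)
  prev <- c(0, head(cum, -1))
  for (i in seq_len(nrow(whole_body))) {
    on <- whole_body$onset[i]; du <- whole_body$duration[i]
    off <- off + (cum[i] - prev[i]) * smoothstep((t - on) / du)
    sel <- t >= on & t < on + du
    wig[sel] <- wig[sel] +
      whole_body$wiggle_mm[i] * sin(2 * pi * 2.5 * (t[sel] - on)) *
      sin(pi * pmin(pmax((t[sel] - on) / du, 0), 1))
  }
  list(offset = off, wiggle = wig)
}

# Render one chunk of frames as an npx x nt depth matrix (mm, 0 = invalid).
render_chunk_impl <- function(geom, config, schedule, frame_idx, chunk_seed) {
  t <- (frame_idx - 1) / config$frame_rate
  nt <- length(t)
  npx <- geom$npx
  f_hz <- config$breathing_rate / 60
  breath <- (config$breathing_amplitude / 2) *
    amplitude_fraction_at(t, schedule$respiratory) * sin(2 * pi * f_hz * t)
  dl <- leg_displacement_at(t, schedule$leg_movements, "left")
  dr <- leg_displacement_at(t, schedule$leg_movements, "right")
  wb <- whole_body_motion_at(t, schedule$whole_body)

  off <- wb$offset
  moving <- wb$wiggle != 0 |
    c(FALSE, diff(off) != 0) | c(diff(off) != 0, FALSE)
  if (!any(moving) && all(off == off[1])) {
    # fast path: static geometry for the whole chunk
    e0 <- as.numeric(shift_cols(geom$e_static, off[1]))
    bs <- as.numeric(shift_cols(geom$breath_sup, off[1]))
    E <- tcrossprod(bs, breath)
    if (any(dl != 0)) E <- E + tcrossprod(as.numeric(shift_cols(geom$leg_left, off[1])), dl)
    if (any(dr != 0)) E <- E + tcrossprod(as.numeric(shift_cols(geom$leg_right, off[1])), dr)
    E <- E + e0
  } else {
    E <- matrix(0, npx, nt)
    # static stretches (constant offset, no wiggle) rendered blockwise
    grp <- cumsum(c(TRUE, diff(off) != 0 | diff(moving) != 0))
    for (run in split(seq_len(nt)[!moving], grp[!moving])) {
      o <- off[run[1]]
      blk <- tcrossprod(as.numeric(shift_cols(geom$breath_sup, o)), breath[run])
      if (any(dl[run] != 0)) {
        blk <- blk + tcrossprod(as.numeric(shift_cols(geom$leg_left, o)), dl[run])
      }
      if (any(dr[run] != 0)) {
        blk <- blk + tcrossprod(as.numeric(shift_cols(geom$leg_right, o)), dr[run])
      }
      E[, run] <- blk + as.numeric(shift_cols(geom$e_static, o))
    }
    for (j in seq_len(nt)[moving]) {
      o <- off[j]
      col <- shift_cols(geom$e_static, o) + shift_cols(geom$breath_sup, o) * breath[j]
      if (dl[j] != 0) col <- col + shift_cols(geom$leg_left, o) * dl[j]
      if (dr[j] != 0) col <- col + shift_cols(geom$leg_right, o) * dr[j]
      if (wb$wiggle[j] != 0) col <- col + shift_cols(geom$body_taper, o) * wb$wiggle[j]
      E[, j] <- col
    }
  }

  depth <- (geom$d - E) / geom$g
  withr::with_seed(chunk_seed, {
    if (config$noise_sd > 0) {
      depth <- depth + rnorm(npx * nt, 0, config$noise_sd)
    }
    depth <- round(depth)
    if (config$invalid_pixel_rate > 0) {
      n_inv <- rbinom(1, npx * nt, config$invalid_pixel_rate)
      if (n_inv > 0) depth[sample.int(npx * nt, n_inv)] <- 0
    }
  })
  depth[depth < 0] <- 0
  depth
}

#' Lazily rendered depth-video source for a synthetic night
#'
#' Builds a chunked, deterministic frame source from a scene and a schedule
#' without materialising the whole night in memory. Chunks are 30 s of frames
#' (one scoring epoch); each chunk's sensor noise is drawn from a seed derived
#' once from the night seed, so any access order yields bit-identical frames.
#'
#' @param config A [scene_config()].
#' @param schedule An [event_schedule] from [generate_event_schedule()].
#' @return A `depth_video_source`.
#' @export
render_night <- function(config, schedule) {
  stopifnot(inherits(config, "scene_config"), inherits(schedule, "event_schedule"))
  geom <- scene_geometry(config)
  n_frames <- round(config$duration * config$frame_rate)
  chunk_size <- as.integer(round(30 * config$frame_rate))
  n_chunks <- as.integer(ceiling(n_frames / chunk_size))
  seeds <- derive_seeds(config$seed + 2L, n_chunks)
  structure(
    list(
      n_frames = n_frames, frame_rate = config$frame_rate,
      dim = config$image_size, intrinsics = geom$intrinsics,
      chunk_size = chunk_size, n_chunks = n_chunks,
      config = config, schedule = schedule, geom = geom, chunk_seeds = seeds
    ),
    class = "depth_video_source"
  )
}

#' @export
print.depth_video_source <- function(x, ...) {
  cat("<depth_video_source> ", x$n_frames, " frames ", x$dim[1], "x", x$dim[2],
      " @ ", x$frame_rate, " fps (", x$n_chunks, " chunks)\n", sep = "")
  invisible(x)
}

# npx x nt depth matrix for chunk i of a source or in-memory video
source_chunk <- function(x, i) {
  from <- (i - 1L) * x$chunk_size + 1L
  to <- min(i * x$chunk_size, x$n_frames)
  if (inherits(x, "depth_video_source")) {
    render_chunk_impl(x$geom, x$config, x$schedule, from:to, x$chunk_seeds[i])
  } else {
    f <- x$frames[, , from:to, drop = FALSE]
    dim(f) <- c(x$dim[1] * x$dim[2], to - from + 1L)
    f
  }
}

n_source_chunks <- function(x) {
  as.integer(ceiling(x$n_frames / x$chunk_size))
}

#' Render a synthetic night as an in-memory depth video
#'
#' Materialises [render_night()] into a [depth_video] object (frames as a
#' `rows x cols x T` array of depth in mm, 0 marking invalid pixels). Use the
#' lazy source for long nights; a full 8-h night at full rate does not fit in
#' memory.
#'
#' @inheritParams render_night
#' @return A [depth_video].
#' @export
render_depth_video <- function(config, schedule) {
  src <- render_night(config, schedule)
  npx <- prod(src$dim)
  if (npx * src$n_frames > 2e8) {
    abort("night too large to materialise; use render_night() and chunked analysis")
  }
  frames <- array(0, c(src$dim[1], src$dim[2], src$n_frames))
  for (i in seq_len(src$n_chunks)) {
    from <- (i - 1L) * src$chunk_size + 1L
    to <- min(i * src$chunk_size, src$n_frames)
    ch <- source_chunk(src, i)
    dim(ch) <- c(src$dim[1], src$dim[2], to - from + 1L)
    frames[, , from:to] <- ch
  }
  depth_video(frames, frame_rate = src$frame_rate, intrinsics = src$intrinsics)
}
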