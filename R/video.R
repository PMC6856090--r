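# Depth-video container: in-memory object and HDF5 file format.

#' Depth video object
#'
#' A time-ordered stack of depth frames with timestamps and pinhole
#' calibration. Depth is in millimetres; 0 is the sensor's invalid-pixel code.
#' Timestamps must be strictly increasing; gaps larger than 1.5 frame periods
#' are flagged (never silently resampled).
#'
#' @param frames Numeric array `rows x cols x T`, depth in mm, `0` = invalid.
#' @param frame_rate Frames per second.
#' @param timestamps Optional vector of length `T`, seconds from recording
#'   start; defaults to a regular grid at `frame_rate`.
#' @param intrinsics List with `fx`, `fy`, `cx`, `cy` in pixels.
#' @return A `depth_video` object with fields `frames`, `timestamps`,
#'   `frame_rate`, `intrinsics`, `dim`, `n_frames`, and a logical `gaps` flag
#'   vector marking irregular inter-frame intervals.
#' @export
depth_video <- function(frames, frame_rate, timestamps = NULL, intrinsics = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  n <- dim(frames)[3]
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / frame_rate
  if (length(timestamps) != n) abort("length(timestamps) must equal the number of frames")
  if (any(diff(timestamps) <= 0)) abort("timestamps must be strictly increasing")
  if (any(frames < 0)) abort("depth values must be >= 0")
  if (is.null(intrinsics)) {
    intrinsics <- list(fx = 60, fy = 60,
                       cx = (dim(frames)[2] + 1) / 2, cy = (dim(frames)[1] + 1) / 2)
  }
  gaps <- c(FALSE, abs(diff(timestamps) - 1 / frame_rate) > 0.5 / frame_rate)
  if (any(gaps)) warn(paste0(sum(gaps), " irregular inter-frame gaps flagged"))
  structure(
    list(
      frames = frames, timestamps = as.numeric(timestamps),
      frame_rate = frame_rate, intrinsics = intrinsics,
      dim = dim(frames)[1:2], n_frames = n,
      chunk_size = as.integer(round(30 * frame_rate)), gaps = gaps
    ),
    class = "depth_video"
  )
}

#' @export
print.depth_video <- function(x, ...) {
  cat("<depth_video> ", x$n_frames, " frames ", x$dim[1], "x", x$dim[2],
      " @ ", x$frame_rate, " fps, ", round(max(x$timestamps), 1), " s\n", sep = "")
  invisible(x)
}

#' Read and write the HDF5 depth container
#'
#' The container holds dataset `frames` (`rows x cols x T`, unsigned 16-bit
#' depth in mm with 0 = invalid), dataset `timestamps` (seconds), and root
#' attributes `frame_rate` and `intrinsics` (fx, fy, cx, cy). Round-trips are
#' lossless. Nights recorded in multiple parts can be read together with
#' [read_depth_video_parts()].
#'
#' @param video A [depth_video].
#' @param path File path.
#' @return `write_depth_video()` returns `path` invisibly; `read_depth_video()`
#'   returns a [depth_video].
#' @export
write_depth_video <- function(video, path) {
  stopifnot(inherits(video, "depth_video"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(
    path, "frames", dims = dim(video$frames), storage.mode = "integer",
    chunk = c(video$dim, min(video$n_frames, 300)), level = 4
  )
  rhdf5::h5write(array(as.integer(round(video$frames)), dim(video$frames)),
                 path, "frames")
  rhdf5::h5write(video$timestamps, path, "timestamps")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(video$frame_rate, fid, "frame_rate")
  rhdf5::h5writeAttribute(
    c(video$intrinsics$fx, video$intrinsics$fy, video$intrinsics$cx, video$intrinsics$cy),
    fid, "intrinsics"
  )
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_depth_video
#' @export
read_depth_video <- function(path) {
  if (!file.exists(path)) abort(paste0("depth container not found: ", path))
  contents <- rhdf5::h5ls(path)$name
  for (need in c("frames", "timestamps")) {
    if (!need %in% contents) abort(paste0("malformed container: missing dataset '", need, "'"))
  }
  at <- rhdf5::h5readAttributes(path, "/")
  for (need in c("frame_rate", "intrinsics")) {
    if (is.null(at[[need]])) abort(paste0("malformed container: missing attribute '", need, "'"))
  }
  frames <- rhdf5::h5read(path, "frames")
  storage.mode(frames) <- "double"
  ts <- as.numeric(rhdf5::h5read(path, "timestamps"))
  k <- as.numeric(at$intrinsics)
  depth_video(
    frames, frame_rate = as.numeric(at$frame_rate), timestamps = ts,
    intrinsics = list(fx = k[1], fy = k[2], cx = k[3], cy = k[4])
  )
}

#' Read a night stored as multiple container parts
#'
#' Long recordings may be stored in consecutive parts (e.g. 2-h sections).
#' Parts are concatenated on their timestamps; overlapping or out-of-order
#' parts and mismatched geometry are refused, so events spanning a part
#' boundary are detected on the concatenated signal.
#'
#' @param paths Character vector of container paths, in recording order.
#' @return A [depth_video] covering all parts.
#' @export
read_depth_video_parts <- function(paths) {
  parts <- lapply(paths, read_depth_video)
  if (length(parts) == 1) return(parts[[1]])
  first <- parts[[1]]
  for (p in parts[-1]) {
    if (!identical(p$dim, first$dim) || p$frame_rate != first$frame_rate) {
      abort("container parts disagree on geometry or frame rate")
    }
  }
  ts <- unlist(lapply(parts, function(p) p$timestamps))
  if (any(diff(ts) <= 0)) abort("container parts overlap or are out of order")
  frames <- array(0, c(first$dim, sum(vapply(parts, function(p) p$n_frames, 1L))))
  at <- 1L
  for (p in parts) {
    frames[, , at:(at + p$n_frames - 1L)] <- p$frames
    at <- at + p$n_frames
  }
  suppressWarnings(
    depth_video(frames, frame_rate = first$frame_rate, timestamps = ts,
                intrinsics = first$intrinsics)
  )
}
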