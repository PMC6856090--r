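# Breathing-signal extraction, envelope computation, respiratory-event
# detection by sustained envelope drops, and the per-hour indices.

#' Extract the thoracic breathing signal
#'
#' Mean elevation inside the thoracic disk per frame, with linear trend and
#' slow drift removed by a high-pass (subtraction of a centered moving average
#' one cutoff-period wide; default cutoff 0.05 Hz, well below the breathing
#' band). Frames inside whole-body movements are flagged; frames whose ROI is
#' fully invalid are interpolated and counted toward a quality warning.
#'
#' @param x A [depth_video] or `depth_video_source`.
#' @param segmentation A [segment_body()] result; computed from the first 30 s
#'   when `NULL`.
#' @param plane Optional [estimate_bed_plane()] result.
#' @param highpass_hz Detrending cutoff, Hz.
#' @param smooth_s Band-limiting moving-average width, s.
#' @param movement_events Optional tibble (`onset`, `duration`) of whole-body
#'   movements used to flag frames.
#' @param flag_margin_s Flagging margin around movement events, s.
#' @return A `breathing_signal`: tibble with `time` (s), `value` (mm,
#'   detrended) and `flagged`; attributes `sample_rate` and
#'   `roi_invalid_frac`.
#' @export
extract_breathing_signal <- function(x, segmentation = NULL, plane = NULL,
                                     highpass_hz = 0.05, smooth_s = 0.5,
                                     movement_events = NULL,
                                     flag_margin_s = 2) {
  fs <- x$frame_rate
  if (is.null(plane)) plane <- estimate_bed_plane(x)
  g <- as.numeric(plane_g_factor(plane, x$dim, x$intrinsics))
  if (is.null(segmentation)) {
    M <- source_chunk(x, 1L)
    V <- M > 0
    E <- plane$d - M * g
    E[!V] <- 0
    ref <- chunk_reference_frame(E, V, x$dim, 3)
    segmentation <- segment_body(ref)
  }
  roi_idx <- which(segmentation$roi_mask)
  if (length(roi_idx) == 0) abort("empty thoracic ROI")
  n_f <- x$n_frames
  # per-pixel reference (first-epoch median) so invalid-pixel dropouts do not
  # shift the ROI mean
  M1 <- source_chunk(x, 1L)
  V1 <- M1 > 0
  E1 <- plane$d - M1 * g
  E1[!V1] <- 0
  ref <- as.numeric(chunk_reference_frame(E1, V1, x$dim, 1))[roi_idx]
  raw <- numeric(n_f)
  empty <- logical(n_f)
  for (i in seq_len(n_source_chunks(x))) {
    from <- (i - 1L) * x$chunk_size + 1L
    to <- min(i * x$chunk_size, n_f)
    M <- source_chunk(x, i)[roi_idx, , drop = FALSE]
    V <- M > 0
    E <- plane$d - M * g[roi_idx]
    E[!V] <- 0
    nv <- colSums(V)
    raw[from:to] <- ifelse(nv > 0, colSums((E - ref) * V) / pmax(nv, 1), NA_real_)
    empty[from:to] <- nv == 0
  }
  if (mean(empty) > 0.10) {
    warn("thoracic ROI fully invalid in more than 10% of frames; signal quality is poor")
  }
  value <- detrend_breathing(raw, fs, highpass_hz, smooth_s)
  time <- (seq_len(n_f) - 1) / fs
  flagged <- if (is.null(movement_events)) {
    logical(n_f)
  } else {
    flag_frames(n_f, fs, movement_events, flag_margin_s)
  }
  new_breathing_signal(time, value, flagged, fs, mean(empty))
}

new_breathing_signal <- function(time, value, flagged, fs, roi_invalid_frac = 0) {
  out <- tibble::tibble(time = time, value = value, flagged = flagged)
  attr(out, "sample_rate") <- fs
  attr(out, "roi_invalid_frac") <- roi_invalid_frac
  class(out) <- c("breathing_signal", class(out))
  out
}

signal_fs <- function(signal, sample_rate = NULL) {
  fs <- sample_rate %||% attr(signal, "sample_rate")
  if (is.null(fs)) abort("provide `sample_rate` for plain numeric signals")
  fs
}

signal_values <- function(signal) {
  if (is.data.frame(signal)) signal$value else as.numeric(signal)
}

#' Breathing-amplitude envelope
#'
#' Per-sample amplitude of the oscillatory breathing signal: half the
#' peak-to-peak range of the signal in a centered window. Windowed
#' peak-to-peak is robust to non-sinusoidal blanket motion; the window should
#' cover at least one breathing period.
#'
#' @param signal A `breathing_signal` tibble or numeric vector.
#' @param window_s Window length, s (default 5).
#' @param sample_rate Samples per second (taken from the signal if absent).
#' @return Numeric envelope, same length as the input, nonnegative.
#' @export
compute_envelope <- function(signal, window_s = 5, sample_rate = NULL) {
  fs <- signal_fs(signal, sample_rate)
  x <- signal_values(signal)
  k <- round(window_s * fs)
  if (k < 2) abort("envelope window must span at least 2 samples")
  (run_max(x, k) - run_min(x, k)) / 2
}

#' Dominant breathing period of a signal
#'
#' Spectral peak of the detrended signal inside the adult breathing band
#' (0.08-0.8 Hz), used to derive the event merge gap (two breaths).
#'
#' @inheritParams compute_envelope
#' @return Period in seconds, or `NA` if no in-band peak exists.
#' @export
estimate_breathing_period <- function(signal, sample_rate = NULL) {
  fs <- signal_fs(signal, sample_rate)
  x <- signal_values(signal)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 32) return(NA_real_)
  sp <- Mod(fft(x - mean(x)))[seq_len(n %/% 2)]^2
  freq <- (seq_len(n %/% 2) - 1) * fs / n
  band <- freq >= 0.08 & freq <= 0.8
  if (!any(band)) return(NA_real_)
  1 / freq[band][which.max(sp[band])]
}

#' Detect respiratory events as sustained envelope drops
#'
#' The local baseline is a rolling median of the envelope (default 100 s),
#' with whole-body-movement frames excluded; an event is a maximal span where
#' the envelope falls below `drop_fraction` of that baseline for at least
#' `min_duration_s` (default 10 s, the standard minimum respiratory-event
#' duration) and at most `max_duration_s`. Movement-flagged frames are never
#' counted as event samples. Events separated by less than two recovered
#' breaths are merged. Apneas and hypopneas are deliberately not
#' subclassified: a depth camera sees only effort amplitude, so the residual
#' amplitude fraction is reported per event instead.
#'
#' @param envelope Numeric envelope from [compute_envelope()].
#' @param sample_rate Samples per second.
#' @param drop_fraction Envelope threshold relative to the local baseline.
#' @param min_duration_s,max_duration_s Event duration bounds, s.
#' @param baseline_window_s Rolling-median window, s.
#' @param movement_flag Optional logical per-sample movement flag.
#' @param merge_gap_s Gap below which adjacent events merge; default two
#'   breathing periods (`2 * breathing_period_s`, or 8 s if unknown).
#' @param breathing_period_s Breathing period estimate, s.
#' @param envelope_window_s Window used when computing the envelope; the
#'   movement flag is dilated by half of it and envelope edges are not used
#'   as event evidence.
#' @param t0 Time of the first sample, s.
#' @return Tibble with `onset`, `duration`, `min_amplitude_fraction`.
#' @export
detect_respiratory_events <- function(envelope, sample_rate,
                                      drop_fraction = 0.5,
                                      min_duration_s = 10,
                                      max_duration_s = 120,
                                      baseline_window_s = 100,
                                      movement_flag = NULL,
                                      merge_gap_s = NULL,
                                      breathing_period_s = NULL,
                                      envelope_window_s = 5,
                                      t0 = 0) {
  check_number(drop_fraction, "drop_fraction", min = 0, max = 1, strict_min = TRUE)
  if (drop_fraction >= 1) abort("`drop_fraction` must be < 1")
  env <- as.numeric(envelope)
  if (all(env <= 1e-9)) abort("unscorable signal: envelope is all zero (no breathing detected)")
  fs <- sample_rate
  if (is.null(merge_gap_s)) {
    merge_gap_s <- if (is.null(breathing_period_s) || is.na(breathing_period_s)) 8
    else 2 * breathing_period_s
  }
  # envelope spikes around movements spread half an envelope window beyond the
  # flagged frames; dilate the flag accordingly before it gates the baseline
  # and the event candidates
  flag <- movement_flag
  if (!is.null(flag) && any(flag) && envelope_window_s > 0) {
    h <- as.integer(ceiling(envelope_window_s / 2 * fs)) + 1L
    flag <- run_max(as.numeric(flag), 2L * h + 1L) > 0
  }
  base_in <- env
  if (!is.null(flag)) base_in[flag] <- NA_real_
  baseline <- rolling_median_na(base_in, round(baseline_window_s * fs))

  below <- env < drop_fraction * baseline
  if (!is.null(flag)) below[flag] <- FALSE
  # envelope values in the first/last half window are computed on truncated
  # windows and are not trusted as event evidence
  edge <- as.integer(ceiling(envelope_window_s / 2 * fs))
  if (edge > 0 && length(below) > 2 * edge) {
    below[seq_len(edge)] <- FALSE
    below[(length(below) - edge + 1L):length(below)] <- FALSE
  }
  r <- runs_of(below)
  if (nrow(r) > 1) {
    gap <- (r$start[-1] - r$end[-nrow(r)] - 1L) / fs
    grp <- cumsum(c(TRUE, gap >= merge_gap_s))
    r <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(grp = grp, s = r$start, e = r$end), grp),
      start = min(.data$s), end = max(.data$e), .groups = "drop"
    )[, c("start", "end")]
  }
  if (nrow(r) == 0) {
    return(tibble::tibble(onset = numeric(), duration = numeric(),
                          min_amplitude_fraction = numeric()))
  }
  sp <- runs_to_spans(r, fs, t0)
  frac <- vapply(seq_len(nrow(r)), function(i) {
    ii <- r$start[i]:r$end[i]
    min(env[ii] / pmax(baseline[ii], 1e-12))
  }, numeric(1))
  keep <- sp$duration >= min_duration_s & sp$duration <= max_duration_s
  tibble::tibble(onset = sp$onset[keep], duration = sp$duration[keep],
                 min_amplitude_fraction = frac[keep])
}

#' Respiratory event indices (KREI and KREI_sleep)
#'
#' The camera respiratory-event index counts all detected events (apneas and
#' hypopneas together) per hour from lights-off to lights-on; the sleep
#' variant divides by hours of sleep instead and needs a hypnogram.
#'
#' @param events Tibble with `onset` (s).
#' @param lights_off,lights_on Window bounds, s.
#' @param hypnogram Optional tibble (`epoch_index`, `label`) on the 30-s grid
#'   anchored at `lights_off`.
#' @return One-row tibble: `krei`, `krei_sleep` (`NA` with a flag when no
#'   hypnogram or zero sleep time), `n_events`, `window_h`, `tst_h`.
#' @export
compute_respiratory_indices <- function(events, lights_off, lights_on,
                                        hypnogram = NULL) {
  if (lights_on <= lights_off) abort("lights_on must be after lights_off")
  window_h <- (lights_on - lights_off) / 3600
  inside <- events$onset >= lights_off & events$onset < lights_on
  n <- sum(inside)
  krei <- n / window_h
  krei_sleep <- NA_real_
  tst_h <- NA_real_
  if (!is.null(hypnogram)) {
    tst_h <- sum(hypnogram$label == "sleep") * 30 / 3600
    if (tst_h > 0) {
      ep <- epoch_of(events$onset[inside], lights_off)
      lab <- hypnogram$label[pmin(pmax(ep, 1L), nrow(hypnogram))]
      krei_sleep <- sum(lab == "sleep") / tst_h
    }
  }
  tibble::tibble(krei = krei, krei_sleep = krei_sleep, n_events = n,
                 window_h = window_h, tst_h = tst_h)
}
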