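# Leg-motion signal, AASM-style leg-movement and PLM scoring, whole-body
# movement detection, and the per-hour PLM indices.

#' Detect whole-body movements
#'
#' Spans where a substantial fraction of body pixels change by more than
#' `pixel_change_mm` between consecutive frames for at least
#' `min_duration_s`. Whole-body movements are used as an exclusion mask for
#' respiratory and leg-movement scoring: position shifts collapse or inflate
#' signal amplitudes for a few seconds.
#'
#' @param x A [depth_video] or `depth_video_source`.
#' @param segmentation A [segment_body()] result.
#' @param plane Optional [estimate_bed_plane()] result.
#' @param pixel_change_mm Per-pixel change counting as moved, mm.
#' @param area_fraction Fraction of body pixels that must move.
#' @param min_duration_s Minimum event duration, s.
#' @return Tibble with `onset`, `duration` (s).
#' @export
detect_whole_body_movements <- function(x, segmentation, plane = NULL,
                                        pixel_change_mm = 10,
                                        area_fraction = 0.3,
                                        min_duration_s = 1) {
  series <- body_pair_series(x, segmentation, plane, pixel_change_mm)
  assemble_movement_events(series$body_frac, x$frame_rate,
                           area_fraction = area_fraction,
                           min_duration_s = min_duration_s)
}

#' Extract the leg-motion signal
#'
#' Mean absolute frame-to-frame elevation change over the lower-body mask
#' (mm per frame), one sample per frame pair. The lower-body mask is the body
#' region below the head-to-toe axis span occupied by the legs.
#'
#' @inheritParams detect_whole_body_movements
#' @return A `leg_signal` tibble: `time` (s, start of each frame pair) and
#'   `value` (mm/frame), with attribute `sample_rate`.
#' @export
extract_leg_signal <- function(x, segmentation, plane = NULL) {
  if (sum(segmentation$lower_body_mask) == 0) abort("empty lower-body mask")
  series <- body_pair_series(x, segmentation, plane)
  out <- tibble::tibble(
    time = (seq_len(x$n_frames - 1L) - 1) / x$frame_rate,
    value = series$leg
  )
  attr(out, "sample_rate") <- x$frame_rate
  class(out) <- c("leg_signal", class(out))
  out
}

# shared chunked pass for the two OPs above
body_pair_series <- function(x, segmentation, plane = NULL, pixel_change_mm = 10) {
  if (is.null(plane)) plane <- estimate_bed_plane(x)
  g <- as.numeric(plane_g_factor(plane, x$dim, x$intrinsics))
  leg_idx <- which(segmentation$lower_body_mask)
  body_idx <- which(segmentation$body_mask)
  n_f <- x$n_frames
  leg <- numeric(max(n_f - 1L, 0))
  frac <- numeric(max(n_f - 1L, 0))
  prev <- NULL
  for (i in seq_len(n_source_chunks(x))) {
    from <- (i - 1L) * x$chunk_size + 1L
    to <- min(i * x$chunk_size, n_f)
    M <- source_chunk(x, i)
    V <- M > 0
    E <- plane$d - M * g
    E[!V] <- 0
    nt <- ncol(E)
    if (!is.null(prev)) {
      dE <- abs(E[, 1] - prev$E)
      vp <- V[, 1] & prev$V
      leg[from - 1L] <- if (length(leg_idx)) {
        sum(dE[leg_idx] * vp[leg_idx]) / max(sum(vp[leg_idx]), 1)
      } else 0
      frac[from - 1L] <- sum((dE[body_idx] > pixel_change_mm) & vp[body_idx]) /
        max(sum(vp[body_idx]), 1)
    }
    if (nt > 1) {
      D <- abs(E[, -1, drop = FALSE] - E[, -nt, drop = FALSE])
      VP <- V[, -1, drop = FALSE] & V[, -nt, drop = FALSE]
      idx <- from:(to - 1L)
      leg[idx] <- masked_col_means(D, VP, leg_idx)
      frac[idx] <- colSums((D[body_idx, , drop = FALSE] > pixel_change_mm) &
                             VP[body_idx, , drop = FALSE]) /
        pmax(colSums(VP[body_idx, , drop = FALSE]), 1)
    }
    prev <- list(E = E[, nt], V = V[, nt])
  }
  list(leg = leg, body_frac = frac)
}

#' Detect leg-movement candidates
#'
#' Dual-threshold burst detection on the leg-motion signal, the camera analog
#' of the AASM EMG rule (a movement starts with an excursion 8 uV above
#' resting and ends when activity stays below 2 uV above resting): a candidate
#' is a maximal span above the low (offset) threshold that contains at least
#' one sample above the high (onset) threshold. Spans closer than
#' `merge_gap_s` merge into one movement; only spans lasting 0.5-10 s -- the
#' scorable window -- are kept. Thresholds default to the resting baseline
#' (median of the signal) plus `k_mad` / `k_mad_end` robust standard
#' deviations.
#'
#' @param signal A `leg_signal` tibble or numeric vector (mm/frame).
#' @param sample_rate Samples per second (taken from the signal if absent).
#' @param threshold Absolute onset threshold, mm/frame; computed from the
#'   signal when `NULL`.
#' @param threshold_low Absolute offset threshold; defaults to `threshold`
#'   when that is given explicitly, else to the `k_mad_end` rule.
#' @param k_mad,k_mad_end Robust multipliers for the onset and offset
#'   thresholds when not given explicitly.
#' @param merge_gap_s Merge gap, s.
#' @param duration_range Scorable duration window, s.
#' @return Tibble with `onset`, `duration`, `peak_magnitude`.
#' @export
detect_leg_movement_candidates <- function(signal, sample_rate = NULL,
                                           threshold = NULL,
                                           threshold_low = NULL,
                                           k_mad = 8, k_mad_end = 2,
                                           merge_gap_s = 0.5,
                                           duration_range = c(0.5, 10)) {
  fs <- signal_fs(signal, sample_rate)
  x <- signal_values(signal)
  if (is.null(threshold)) {
    med <- median(x, na.rm = TRUE)
    s <- mad(x, na.rm = TRUE)
    threshold <- max(med + k_mad * s, 1e-9)
    if (is.null(threshold_low)) threshold_low <- max(med + k_mad_end * s, 1e-9)
  }
  if (is.null(threshold_low)) threshold_low <- threshold
  check_number(threshold, "threshold", min = 0, strict_min = TRUE)
  check_number(threshold_low, "threshold_low", min = 0, strict_min = TRUE,
               max = threshold)
  r <- runs_of(x > threshold_low)
  if (nrow(r) > 0) {
    hit <- vapply(seq_len(nrow(r)), function(i) {
      any(x[r$start[i]:r$end[i]] > threshold)
    }, logical(1))
    r <- r[hit, , drop = FALSE]
  }
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
                          peak_magnitude = numeric()))
  }
  sp <- runs_to_spans(r, fs)
  peak <- vapply(seq_len(nrow(r)), function(i) max(x[r$start[i]:r$end[i]]), numeric(1))
  keep <- sp$duration >= duration_range[1] & sp$duration <= duration_range[2]
  tibble::tibble(onset = sp$onset[keep], duration = sp$duration[keep],
                 peak_magnitude = peak[keep])
}

#' Filter leg-movement candidates near other events
#'
#' Removes candidates overlapping a whole-body movement (padded by
#' `wb_margin_s`) and candidates whose onset lies inside a respiratory event
#' or within `resp_margin_s` of its start or end -- the AASM exclusion of leg
#' movements that are part of a respiratory arousal.
#'
#' @param candidates Tibble from [detect_leg_movement_candidates()].
#' @param whole_body,respiratory Event tibbles with `onset`, `duration`.
#' @param wb_margin_s,resp_margin_s Margins, s.
#' @return Filtered candidate tibble.
#' @export
filter_leg_movements <- function(candidates, whole_body = NULL,
                                 respiratory = NULL,
                                 wb_margin_s = 2, resp_margin_s = 0.5) {
  keep <- rep(TRUE, nrow(candidates))
  if (!is.null(whole_body) && nrow(whole_body) > 0) {
    for (i in seq_len(nrow(whole_body))) {
      a <- whole_body$onset[i] - wb_margin_s
      b <- whole_body$onset[i] + whole_body$duration[i] + wb_margin_s
      keep <- keep & !(candidates$onset < b & candidates$onset + candidates$duration > a)
    }
  }
  if (!is.null(respiratory) && nrow(respiratory) > 0) {
    for (i in seq_len(nrow(respiratory))) {
      s <- respiratory$onset[i]
      e <- s + respiratory$duration[i]
      near <- (candidates$onset >= s - resp_margin_s & candidates$onset <= e + resp_margin_s)
      keep <- keep & !near
    }
  }
  candidates[keep, , drop = FALSE]
}

#' Group leg movements into periodic sequences
#'
#' A PLM sequence is a consecutive run of at least four leg movements whose
#' onset-to-onset intervals all lie in [5, 90] s (inclusive). An interval
#' longer than 90 s ends the run; an interval shorter than 5 s breaks the run
#' and excludes both movements involved from any sequence. Runs are maximal
#' and each movement belongs to at most one sequence.
#'
#' @param movements Tibble with `onset`, `duration`, time-ordered and
#'   non-overlapping.
#' @param min_interval_s,max_interval_s Periodicity bounds, s.
#' @param min_run Minimum movements per sequence.
#' @return The input with an added integer `sequence_id` (`NA` outside
#'   sequences).
#' @export
group_plm <- function(movements, min_interval_s = 5, max_interval_s = 90,
                      min_run = 4) {
  n <- nrow(movements)
  out <- dplyr::mutate(movements, sequence_id = NA_integer_)
  if (n == 0) return(out)
  if (is.unsorted(movements$onset)) abort("movements must be time-ordered")
  if (n > 1) {
    ends <- movements$onset + movements$duration
    if (any(movements$onset[-1] < ends[-n])) abort("movements must not overlap")
  }
  if (n < min_run) return(out)

  iv <- diff(movements$onset)
  short <- iv < min_interval_s
  eligible <- rep(TRUE, n)
  eligible[which(short)] <- FALSE
  eligible[which(short) + 1L] <- FALSE
  edge_ok <- iv >= min_interval_s & iv <= max_interval_s

  seq_id <- 0L
  i <- 1L
  while (i <= n) {
    if (!eligible[i]) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && edge_ok[j] && eligible[j + 1L]) j <- j + 1L
    if (j - i + 1L >= min_run) {
      seq_id <- seq_id + 1L
      out$sequence_id[i:j] <- seq_id
    }
    i <- j + 1L
  }
  out
}

#' Periodic limb movement indices (KPLMI and KPLMI_sleep)
#'
#' Counts leg movements belonging to PLM sequences per hour of the
#' lights-off window; the sleep variant restricts to movements whose onset
#' epoch is scored sleep and divides by hours of sleep.
#'
#' @param grouped Output of [group_plm()].
#' @param lights_off,lights_on Window bounds, s.
#' @param hypnogram Optional tibble (`epoch_index`, `label`).
#' @return One-row tibble: `kplmi`, `kplmi_sleep`, `n_plm`, `n_sequences`,
#'   `window_h`, `tst_h`.
#' @export
compute_plm_indices <- function(grouped, lights_off, lights_on, hypnogram = NULL) {
  if (lights_on <= lights_off) abort("lights_on must be after lights_off")
  window_h <- (lights_on - lights_off) / 3600
  plm <- grouped[!is.na(grouped$sequence_id) &
                   grouped$onset >= lights_off & grouped$onset < lights_on, , drop = FALSE]
  kplmi <- nrow(plm) / window_h
  kplmi_sleep <- NA_real_
  tst_h <- NA_real_
  if (!is.null(hypnogram)) {
    tst_h <- sum(hypnogram$label == "sleep") * 30 / 3600
    if (tst_h > 0) {
      ep <- epoch_of(plm$onset, lights_off)
      lab <- hypnogram$label[pmin(pmax(ep, 1L), nrow(hypnogram))]
      kplmi_sleep <- sum(lab == "sleep") / tst_h
    }
  }
  tibble::tibble(kplmi = kplmi, kplmi_sleep = kplmi_sleep,
                 n_plm = nrow(plm),
                 n_sequences = length(unique(stats::na.omit(grouped$sequence_id))),
                 window_h = window_h, tst_h = tst_h)
}
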