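# Night-level orchestration: simulate a night, analyze a recording into
# events and indices, and produce a reproducible run report.

#' Simulate a synthetic night
#'
#' Draws the ground-truth schedule and builds the lazily rendered depth-video
#' source for one night under a [run_config()].
#'
#' @param config A [run_config()].
#' @param seed Optional night seed overriding `config$seed`.
#' @return List with `scene` ([scene_config()]), `schedule`
#'   ([generate_event_schedule()]) and `video` (lazy source).
#' @export
simulate_night <- function(config = run_config(), seed = NULL) {
  scene <- scene_from_config(config, seed)
  schedule <- generate_event_schedule(scene, plan_from_config(config))
  list(scene = scene, schedule = schedule, video = render_night(scene, schedule))
}

#' Analyze a night recording
#'
#' The full pipeline on a depth video: bed-plane estimation, rectification,
#' segmentation, breathing and leg signals, whole-body movements, respiratory
#' events by envelope drop, AASM-style leg-movement and PLM scoring, epoch
#' motion features, and the per-hour indices (KREI/KPLMI with sleep variants
#' when a hypnogram is supplied).
#'
#' @param x A [depth_video] or `depth_video_source`.
#' @param config A [run_config()].
#' @param hypnogram Optional reference hypnogram tibble (`epoch_index`,
#'   `label`) for the `_sleep` index variants.
#' @param lights_off,lights_on Scoring window, s; defaults to the whole
#'   recording.
#' @return A `night_analysis` object; see [tidy.night_analysis()] and
#'   [glance.night_analysis()].
#' @export
analyze_night <- function(x, config = run_config(), hypnogram = NULL,
                          lights_off = 0, lights_on = NULL) {
  t_start <- proc.time()[["elapsed"]]
  fs <- x$frame_rate
  if (is.null(lights_on)) lights_on <- lights_off + x$n_frames / fs
  sig <- extract_night_signals(x, opts = options_from_config(config),
                               lights_off = lights_off)

  rsp <- config$respiration
  env <- compute_envelope(sig$breathing$value, window_s = rsp$envelope_window_s,
                          sample_rate = fs)
  period <- estimate_breathing_period(sig$breathing$value, sample_rate = fs)
  resp_events <- detect_respiratory_events(
    env, fs,
    drop_fraction = rsp$drop_fraction, min_duration_s = rsp$min_duration_s,
    max_duration_s = rsp$max_duration_s,
    baseline_window_s = rsp$baseline_window_s,
    movement_flag = sig$breathing$flagged,
    breathing_period_s = period,
    envelope_window_s = rsp$envelope_window_s, t0 = lights_off
  )
  resp_idx <- compute_respiratory_indices(resp_events, lights_off, lights_on, hypnogram)

  lmb <- config$limb
  leg_cand <- detect_leg_movement_candidates(
    sig$leg$value, sample_rate = fs, k_mad = lmb$k_mad,
    k_mad_end = lmb$k_mad_end, merge_gap_s = lmb$merge_gap_s
  )
  leg_kept <- filter_leg_movements(
    leg_cand, whole_body = sig$whole_body, respiratory = resp_events,
    wb_margin_s = lmb$wb_margin_s, resp_margin_s = lmb$resp_margin_s
  )
  leg_grouped <- group_plm(leg_kept)
  plm_idx <- compute_plm_indices(leg_grouped, lights_off, lights_on, hypnogram)

  elapsed <- proc.time()[["elapsed"]] - t_start
  report <- list(
    package_version = as.character(utils::packageVersion("somnocam")),
    config_hash = config_hash(config),
    window = list(lights_off = lights_off, lights_on = lights_on),
    indices = list(
      krei = resp_idx$krei, krei_sleep = resp_idx$krei_sleep,
      kplmi = plm_idx$kplmi, kplmi_sleep = plm_idx$kplmi_sleep
    ),
    counts = list(
      respiratory_events = nrow(resp_events),
      leg_movement_candidates = nrow(leg_cand),
      leg_movements = nrow(leg_kept),
      plm_movements = plm_idx$n_plm,
      plm_sequences = plm_idx$n_sequences,
      whole_body_movements = nrow(sig$whole_body)
    ),
    quality = list(
      roi_invalid_frac = sig$roi_invalid_frac,
      plane_residual_rms = sig$plane$residual_rms,
      breathing_period_s = period
    ),
    timings = list(elapsed_s = round(elapsed, 2))
  )

  structure(
    list(
      respiratory_events = resp_events,
      leg_movements = leg_grouped,
      whole_body = sig$whole_body,
      respiratory_indices = resp_idx,
      plm_indices = plm_idx,
      features = sig$features,
      signals = sig,
      envelope = env,
      config = config,
      report = report
    ),
    class = "night_analysis"
  )
}

#' @export
print.night_analysis <- function(x, ...) {
  r <- x$report
  cat("<night_analysis> ", round(r$window$lights_on - r$window$lights_off), " s: ",
      r$counts$respiratory_events, " respiratory events (KREI ",
      round(r$indices$krei, 2), "/h), ", r$counts$plm_movements,
      " PLM movements (KPLMI ", round(r$indices$kplmi, 2), "/h), ",
      r$counts$whole_body_movements, " whole-body movements\n", sep = "")
  invisible(x)
}

#' Events of an analyzed night
#'
#' All detected events in the interchange schema (`onset_s`, `duration_s`,
#' `kind`, `subtype`, `magnitude`).
#'
#' @param x A `night_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.night_analysis <- function(x, ...) {
  lm <- x$leg_movements
  dplyr::bind_rows(
    tibble::tibble(
      onset_s = x$respiratory_events$onset,
      duration_s = x$respiratory_events$duration,
      kind = "respiratory", subtype = NA_character_,
      magnitude = x$respiratory_events$min_amplitude_fraction
    ),
    tibble::tibble(
      onset_s = lm$onset, duration_s = lm$duration,
      kind = "leg_movement",
      subtype = as.character(ifelse(is.na(lm$sequence_id), "isolated",
                                    paste0("plm_seq_", lm$sequence_id))),
      magnitude = lm$peak_magnitude
    ),
    tibble::tibble(
      onset_s = x$whole_body$onset, duration_s = x$whole_body$duration,
      kind = "whole_body", subtype = NA_character_, magnitude = NA_real_
    )
  ) |> dplyr::arrange(.data$onset_s)
}

#' Index summary of an analyzed night
#'
#' @param x A `night_analysis`.
#' @param ... Unused.
#' @return One-row tibble with KREI, KREI_sleep, KPLMI, KPLMI_sleep and the
#'   event counts.
#' @export
glance.night_analysis <- function(x, ...) {
  dplyr::bind_cols(
    x$respiratory_indices[, c("krei", "krei_sleep")],
    x$plm_indices[, c("kplmi", "kplmi_sleep", "n_plm", "n_sequences")],
    tibble::tibble(
      n_respiratory = nrow(x$respiratory_events),
      n_whole_body = nrow(x$whole_body),
      window_h = x$respiratory_indices$window_h,
      tst_h = x$respiratory_indices$tst_h
    )
  )
}

#' Write a run report as JSON
#'
#' The report is regenerated identically from the same inputs and seed;
#' timings are excluded by default so reports can be compared byte for byte.
#'
#' @param x A `night_analysis` (or its `$report`).
#' @param path Output path.
#' @param include_timings Keep the timing block.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(x, path, include_timings = FALSE) {
  rep <- if (inherits(x, "night_analysis")) x$report else x
  if (!include_timings) rep$timings <- NULL
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
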