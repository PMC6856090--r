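#' Scene configuration for synthetic nights
#'
#' Describes the static geometry and sensor model of a simulated bedroom
#' scene: a tilted bed plane viewed by a depth camera, with a body rendered as
#' a smooth blanket-like elevation map above the plane. Thoracic breathing is
#' a quasi-sinusoidal depth oscillation; events modulate it (see
#' [generate_event_schedule()] and [render_depth_video()]).
#'
#' @param frame_rate Frames per second (default 30, the native sensor rate).
#' @param duration Recording length in seconds.
#' @param image_size Integer `c(rows, cols)` of each depth frame.
#' @param bed_plane_depth Distance from camera to bed plane at the image
#'   center, mm.
#' @param bed_tilt Camera-to-bed perspective angle in degrees (rotation about
#'   the image row axis).
#' @param body_axis Head-to-toe line in pixel coordinates, a list with
#'   `head = c(row, col)` and `foot = c(row, col)`; `NULL` places a vertical
#'   axis in the image center spanning most of the frame.
#' @param torso_span,leg_span Fractional intervals along the body axis
#'   (head = 0, toe = 1) occupied by the thorax and the legs. Must be disjoint
#'   sub-intervals of `[0, 1]`.
#' @param breathing_amplitude Peak-to-peak thoracic depth oscillation, mm.
#'   Through a blanket a few millimetres is realistic; the default of 8 mm is
#'   at the upper end of plausible.
#' @param breathing_rate Breaths per minute.
#' @param noise_sd Additive Gaussian sensor noise, mm.
#' @param invalid_pixel_rate Fraction of pixels per frame reported as depth 0
#'   (the sensor's invalid code).
#' @param body_height Peak elevation of the body above the bed plane, mm.
#' @param fold_amplitude Amplitude of smooth blanket-fold texture, mm. Folds
#'   make whole-body translations visible as large per-pixel depth changes.
#' @param focal_px Pinhole focal length in pixels (fx = fy).
#' @param seed Integer seed; all randomness of a night flows from it.
#'
#' @return A `scene_config` list, validated.
#' @export
scene_config <- function(frame_rate = 30,
                         duration = 8 * 3600,
                         image_size = c(64L, 48L),
                         bed_plane_depth = 2200,
                         bed_tilt = 8,
                         body_axis = NULL,
                         torso_span = c(0.25, 0.55),
                         leg_span = c(0.60, 1.00),
                         breathing_amplitude = 8,
                         breathing_rate = 14,
                         noise_sd = 1,
                         invalid_pixel_rate = 0.01,
                         body_height = 150,
                         fold_amplitude = 18,
                         focal_px = 60,
                         seed = 1L) {
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  if (length(image_size) != 2L || any(image_size < 8)) {
    abort("`image_size` must be c(rows, cols) with both >= 8")
  }
  image_size <- as.integer(image_size)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(invalid_pixel_rate, "invalid_pixel_rate", min = 0, max = 1 - 1e-9)
  check_number(breathing_amplitude, "breathing_amplitude", min = 0)
  check_number(breathing_rate, "breathing_rate", min = 0, strict_min = TRUE)
  check_span <- function(sp, name) {
    if (length(sp) != 2 || sp[1] < 0 || sp[2] > 1 || sp[1] >= sp[2]) {
      abort(paste0("`", name, "` must be an increasing sub-interval of [0, 1]"))
    }
  }
  check_span(torso_span, "torso_span")
  check_span(leg_span, "leg_span")
  if (max(torso_span[1], leg_span[1]) < min(torso_span[2], leg_span[2])) {
    abort("`torso_span` and `leg_span` must be disjoint")
  }
  if (is.null(body_axis)) {
    mid <- (image_size[2] + 1) / 2
    body_axis <- list(
      head = c(row = round(0.08 * image_size[1]), col = mid),
      foot = c(row = round(0.92 * image_size[1]), col = mid)
    )
  }
  for (ep in body_axis) {
    if (any(ep[1] < 1 | ep[1] > image_size[1] | ep[2] < 1 | ep[2] > image_size[2])) {
      abort("`image_size` too small to contain `body_axis`")
    }
  }
  structure(
    list(
      frame_rate = frame_rate, duration = duration, image_size = image_size,
      bed_plane_depth = bed_plane_depth, bed_tilt = bed_tilt,
      body_axis = body_axis, torso_span = torso_span, leg_span = leg_span,
      breathing_amplitude = breathing_amplitude, breathing_rate = breathing_rate,
      noise_sd = noise_sd, invalid_pixel_rate = invalid_pixel_rate,
      body_height = body_height, fold_amplitude = fold_amplitude,
      focal_px = focal_px, seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

#' @export
print.scene_config <- function(x, ...) {
  cat(
    "<scene_config> ", x$image_size[1], "x", x$image_size[2], " px @ ",
    x$frame_rate, " fps, ", round(x$duration / 3600, 2), " h, tilt ",
    x$bed_tilt, " deg, noise ", x$noise_sd, " mm, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Pinhole intrinsics of a scene
#'
#' @param config A [scene_config()].
#' @return List with `fx`, `fy`, `cx`, `cy` (pixels; principal point in the
#'   0-based pixel convention used throughout).
#' @export
scene_intrinsics <- function(config) {
  list(
    fx = config$focal_px, fy = config$focal_px,
    cx = (config$image_size[2] - 1) / 2,
    cy = (config$image_size[1] - 1) / 2
  )
}

#' Event-rate plan for a synthetic night
#'
#' Parameters from which [generate_event_schedule()] draws a night's ground
#' truth. Rates are expressed per hour of the lights-off window.
#'
#' @param respiratory_rate Target respiratory events per hour (the scheduled
#'   count is `round(rate * hours)`).
#' @param resp_type_mix Named numeric probabilities over event types
#'   `obstructive`, `central`, `mixed`, `hypopnea`; normalised internally.
#' @param resp_duration_range Event duration range, s.
#' @param hypopnea_amplitude_range Residual-amplitude fraction range for
#'   hypopneas. Kept inside the scorable part of the hypopnea definition (a
#'   drop of at least 50% of baseline effort) so that every scheduled event is
#'   in principle detectable by the default event criterion.
#' @param obstructive_amplitude_range Residual effort fraction for obstructive
#'   (and mixed) apneas: low but nonzero, the paradoxical residual effort.
#' @param plm_trains Number of periodic-limb-movement trains.
#' @param plm_movements_range Movements per train (min 4 for a scorable PLM
#'   sequence).
#' @param plm_interval_range Onset-to-onset interval range within a train, s
#'   (AASM: 5-90 s).
#' @param leg_movement_duration_range Single leg-movement duration range, s
#'   (AASM scorable window 0.5-10 s).
#' @param leg_displacement Peak leg displacement, mm.
#' @param isolated_leg_movements Count of isolated (non-periodic) leg
#'   movements to scatter through sleep.
#' @param whole_body_rate Whole-body position shifts per hour.
#' @param sleep_latency_min Minutes of wake at lights-off before sleep onset.
#' @param calm_wake_fraction Fraction of the sleep-latency wake that is "calm"
#'   (lying still, no scheduled movement) - the documented hard case for
#'   motion-based sleep/wake classification.
#' @param awakenings Number of brief nocturnal awakenings (active wake).
#' @param awakening_min Duration of each awakening, minutes.
#' @param fidget_interval_s Mean spacing of movement bursts within active wake.
#'
#' @return An `event_plan` list.
#' @export
event_plan <- function(respiratory_rate = 0,
                       resp_type_mix = c(obstructive = 0.45, central = 0.20,
                                         mixed = 0.05, hypopnea = 0.30),
                       resp_duration_range = c(15, 35),
                       hypopnea_amplitude_range = c(0.30, 0.40),
                       obstructive_amplitude_range = c(0.02, 0.08),
                       plm_trains = 0,
                       plm_movements_range = c(4, 8),
                       plm_interval_range = c(10, 40),
                       leg_movement_duration_range = c(1, 3),
                       leg_displacement = 25,
                       isolated_leg_movements = 0,
                       whole_body_rate = 0.5,
                       sleep_latency_min = 10,
                       calm_wake_fraction = 0.5,
                       awakenings = 1,
                       awakening_min = 2,
                       fidget_interval_s = 20) {
  check_number(respiratory_rate, "respiratory_rate", min = 0)
  check_number(plm_trains, "plm_trains", min = 0)
  check_number(whole_body_rate, "whole_body_rate", min = 0)
  check_number(calm_wake_fraction, "calm_wake_fraction", min = 0, max = 1)
  if (plm_movements_range[1] < 4) abort("a PLM train needs at least 4 movements")
  if (plm_interval_range[1] < 5 || plm_interval_range[2] > 90) {
    abort("`plm_interval_range` must lie inside [5, 90] s")
  }
  if (leg_movement_duration_range[1] < 0.5 || leg_movement_duration_range[2] > 10) {
    abort("`leg_movement_duration_range` must lie inside [0.5, 10] s for scorable movements")
  }
  mix <- resp_type_mix / sum(resp_type_mix)
  structure(
    list(
      respiratory_rate = respiratory_rate, resp_type_mix = mix,
      resp_duration_range = resp_duration_range,
      hypopnea_amplitude_range = hypopnea_amplitude_range,
      obstructive_amplitude_range = obstructive_amplitude_range,
      plm_trains = plm_trains, plm_movements_range = plm_movements_range,
      plm_interval_range = plm_interval_range,
      leg_movement_duration_range = leg_movement_duration_range,
      leg_displacement = leg_displacement,
      isolated_leg_movements = isolated_leg_movements,
      whole_body_rate = whole_body_rate,
      sleep_latency_min = sleep_latency_min,
      calm_wake_fraction = calm_wake_fraction,
      awakenings = awakenings, awakening_min = awakening_min,
      fidget_interval_s = fidget_interval_s
    ),
    class = "event_plan"
  )
}
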