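# Run configuration: nested parameter blocks with defaults for every module,
# YAML round-trip, strict unknown-key rejection, and a content hash so run
# reports can prove which effective parameters produced them.

default_run_config <- function() {
  list(
    seed = 1L,
    scene = list(
      frame_rate = 30, duration = 8 * 3600, image_size = c(64L, 48L),
      bed_plane_depth = 2200, bed_tilt = 8,
      torso_span = c(0.25, 0.55), leg_span = c(0.60, 1.00),
      breathing_amplitude = 8, breathing_rate = 14,
      noise_sd = 1, invalid_pixel_rate = 0.01,
      body_height = 150, fold_amplitude = 18, focal_px = 60
    ),
    plan = list(
      respiratory_rate = 0, plm_trains = 0, isolated_leg_movements = 0,
      whole_body_rate = 0.5, sleep_latency_min = 10, calm_wake_fraction = 0.5,
      awakenings = 1, awakening_min = 2, fidget_interval_s = 20,
      leg_displacement = 25
    ),
    preprocess = list(
      seg_threshold = 30, fill_kernel = 3, head_end = "auto"
    ),
    respiration = list(
      drop_fraction = 0.5, min_duration_s = 10, max_duration_s = 120,
      baseline_window_s = 100, envelope_window_s = 5, highpass_hz = 0.05,
      smooth_s = 0.5
    ),
    limb = list(
      k_mad = 8, k_mad_end = 2, merge_gap_s = 0.5,
      wb_pixel_change_mm = 10, wb_area_fraction = 0.3, wb_min_duration_s = 1,
      wb_flag_margin_s = 2, wb_margin_s = 2, resp_margin_s = 0.5
    ),
    sleep_wake = list(
      rounds = 50, tree_depth = 4, undersample_ratio = 1, raster = c(4L, 4L)
    ),
    agreement = list(
      resp_tolerance_s = 3, leg_tolerance_s = 1, cutoff_rule = "youden"
    )
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(base)) abort(paste0("unknown config key: ", full))
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]])) abort(paste0("config key ", full, " must be a block"))
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Build a run configuration
#'
#' All pipeline parameters in one nested list, each with a default so an
#' empty configuration is runnable. Unknown keys are rejected to catch typos.
#'
#' @param ... Named overrides, e.g. `scene = list(duration = 3600)`,
#'   `seed = 7`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- merge_config(default_run_config(), list(...))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] blocks.
#' @return A `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  structure(merge_config(default_run_config(), y), class = "run_config")
}

#' Hash of the effective configuration
#'
#' Changes iff any effective parameter changes; stored in run reports.
#'
#' @param config A `run_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(lapply(unclass(config), function(b) {
    if (is.list(b)) lapply(b, as.vector) else as.vector(b)
  }))
}

# scene_config / event_plan from config blocks
scene_from_config <- function(config, seed = NULL) {
  sc <- config$scene
  scene_config(
    frame_rate = sc$frame_rate, duration = sc$duration,
    image_size = sc$image_size, bed_plane_depth = sc$bed_plane_depth,
    bed_tilt = sc$bed_tilt, torso_span = sc$torso_span, leg_span = sc$leg_span,
    breathing_amplitude = sc$breathing_amplitude,
    breathing_rate = sc$breathing_rate, noise_sd = sc$noise_sd,
    invalid_pixel_rate = sc$invalid_pixel_rate, body_height = sc$body_height,
    fold_amplitude = sc$fold_amplitude, focal_px = sc$focal_px,
    seed = seed %||% config$seed
  )
}

plan_from_config <- function(config) {
  do.call(event_plan, config$plan)
}

options_from_config <- function(config) {
  signal_options(
    seg_threshold = config$preprocess$seg_threshold,
    torso_span = config$scene$torso_span,
    leg_span = config$scene$leg_span,
    head_end = config$preprocess$head_end,
    fill_kernel = config$preprocess$fill_kernel,
    wb_pixel_change_mm = config$limb$wb_pixel_change_mm,
    wb_area_fraction = config$limb$wb_area_fraction,
    wb_min_duration_s = config$limb$wb_min_duration_s,
    wb_flag_margin_s = config$limb$wb_flag_margin_s,
    raster = config$sleep_wake$raster,
    highpass_hz = config$respiration$highpass_hz,
    smooth_s = config$respiration$smooth_s
  )
}
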