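# Ground-truth schedule generation for synthetic nights.

# --- span (interval) arithmetic on tibbles with columns start, end ------------

spans_new <- function(start = numeric(), end = numeric()) {
  tibble::tibble(start = start, end = end)
}

spans_union <- function(sp) {
  if (nrow(sp) == 0) return(sp)
  sp <- dplyr::arrange(sp, .data$start)
  out_s <- sp$start[1]
  out_e <- sp$end[1]
  for (i in seq_len(nrow(sp))[-1]) {
    if (sp$start[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], sp$end[i])
    } else {
      out_s <- c(out_s, sp$start[i])
      out_e <- c(out_e, sp$end[i])
    }
  }
  spans_new(out_s, out_e)
}

spans_subtract <- function(base, remove) {
  remove <- spans_union(remove)
  if (nrow(remove) == 0) return(base)
  out <- spans_new()
  for (i in seq_len(nrow(base))) {
    s <- base$start[i]; e <- base$end[i]
    cur <- s
    rel <- remove[remove$end > s & remove$start < e, , drop = FALSE]
    for (j in seq_len(nrow(rel))) {
      if (rel$start[j] > cur) out <- dplyr::bind_rows(out, spans_new(cur, rel$start[j]))
      cur <- max(cur, rel$end[j])
    }
    if (cur < e) out <- dplyr::bind_rows(out, spans_new(cur, e))
  }
  out
}

spans_pad <- function(sp, pad) {
  if (nrow(sp) == 0) return(sp)
  spans_new(sp$start - pad, sp$end + pad)
}

# Place `n` non-overlapping spans of the given durations inside `free`
# (already excluding occupied regions), keeping `gap` seconds between placed
# spans. Random but reproducible under the caller's RNG state. Errors when the
# requested event mass cannot be packed.
place_spans <- function(n, durations, free, gap = 0, what = "events") {
  placed <- spans_new()
  if (n == 0) return(placed)
  for (i in seq_len(n)) {
    avail <- spans_subtract(free, spans_pad(placed, gap))
    d <- durations[i]
    avail <- avail[avail$end - avail$start >= d, , drop = FALSE]
    if (nrow(avail) == 0) {
      abort(paste0("infeasible packing: cannot place ", what,
                   " (requested event mass exceeds the available time)"))
    }
    slack <- avail$end - avail$start - d
    seg <- sample.int(nrow(avail), 1, prob = slack + 1e-9)
    onset <- avail$start[seg] + runif(1) * slack[seg]
    placed <- dplyr::bind_rows(placed, spans_new(onset, onset + d))
  }
  dplyr::arrange(placed, .data$start)
}

# --- schedule generation ------------------------------------------------------

#' Generate a ground-truth event schedule for a synthetic night
#'
#' Draws respiratory events, leg movements (isolated and in periodic trains),
#' whole-body position shifts, and a per-30-s-epoch sleep/wake hypnogram from
#' an [event_plan()], reproducibly from the scene seed. The hypnogram includes
#' "calm wake" spans -- wake with no scheduled movement -- so the motion-based
#' sleep/wake classifier's hard case is represented in the ground truth.
#'
#' Scheduled event counts are exact (`round(rate * hours)`), respiratory
#' events never overlap each other or whole-body movements, and PLM trains
#' obey the AASM periodicity definition: at least 4 movements with
#' onset-to-onset intervals inside [5, 90] s.
#'
#' @param config A [scene_config()].
#' @param plan An [event_plan()].
#' @return An `event_schedule`: list with tibbles `respiratory`
#'   (onset, duration, type, amplitude_fraction), `leg_movements`
#'   (onset, duration, limb, displacement, train_id), `whole_body`
#'   (onset, duration, shift_px, wiggle_mm), `hypnogram`
#'   (epoch_index, label, calm), plus `lights_off`, `lights_on`, `seed`.
#' @export
generate_event_schedule <- function(config, plan = event_plan()) {
  stopifnot(inherits(config, "scene_config"), inherits(plan, "event_plan"))
  withr::with_seed(config$seed + 1L, generate_event_schedule_impl(config, plan))
}

generate_event_schedule_impl <- function(config, plan) {
  lights_off <- 0
  lights_on <- config$duration
  hours <- (lights_on - lights_off) / 3600
  n_ep <- as.integer(ceiling((lights_on - lights_off) / 30))

  # -- hypnogram: sleep latency (active then calm) + brief awakenings ---------
  lat_ep <- min(n_ep %/% 2L, round(plan$sleep_latency_min * 2))
  calm_ep <- round(lat_ep * plan$calm_wake_fraction)
  active_lat_ep <- lat_ep - calm_ep
  label <- rep("sleep", n_ep)
  calm <- rep(FALSE, n_ep)
  if (lat_ep > 0) {
    label[seq_len(lat_ep)] <- "wake"
    if (calm_ep > 0) calm[(active_lat_ep + 1):lat_ep] <- TRUE
  }
  wk_len_ep <- max(1L, round(plan$awakening_min * 2))
  n_awake <- plan$awakenings
  guard <- 5L
  if (n_awake > 0 && n_ep > lat_ep + 2 * guard + wk_len_ep) {
    cand <- seq.int(lat_ep + guard + 1L, n_ep - guard - wk_len_ep)
    starts <- integer(0)
    for (k in seq_len(n_awake)) {
      ok <- cand[vapply(cand, function(s) {
        all(abs(s - starts) > wk_len_ep + 4L)
      }, logical(1))]
      if (length(ok) == 0) break
      s <- ok[sample.int(length(ok), 1)]
      starts <- c(starts, s)
      label[s:(s + wk_len_ep - 1L)] <- "wake"
    }
  }
  hypnogram <- tibble::tibble(epoch_index = seq_len(n_ep), label = label, calm = calm)

  ep_start <- lights_off + (hypnogram$epoch_index - 1) * 30
  wake_active <- hypnogram$label == "wake" & !hypnogram$calm
  wake_spans_active <- spans_union(spans_new(ep_start[wake_active], ep_start[wake_active] + 30))
  sleep_spans <- spans_union(spans_new(ep_start[label == "sleep"], ep_start[label == "sleep"] + 30))
  edge_s <- min(60, 0.05 * (lights_on - lights_off))
  edge <- spans_new(c(lights_off, lights_on - edge_s), c(lights_off + edge_s, lights_on))

  # -- whole-body position shifts (persisting) --------------------------------
  n_wb <- round(plan$whole_body_rate * hours)
  wb_free <- spans_subtract(
    spans_subtract(spans_new(lights_off, lights_on), edge),
    spans_new(ep_start[hypnogram$calm], ep_start[hypnogram$calm] + 30)
  )
  wb_dur <- runif(n_wb, 2, 4)
  wb <- place_spans(n_wb, wb_dur, wb_free, gap = 120, what = "whole-body movements")
  shift_sign <- rep_len(c(1, -1), nrow(wb)) # alternate so the body stays in frame
  whole_body <- tibble::tibble(
    onset = wb$start, duration = wb$end - wb$start,
    shift_px = shift_sign * runif(nrow(wb), 2, 4),
    wiggle_mm = runif(nrow(wb), 25, 40)
  )

  # -- fidget bursts during active wake (transient, no net shift) -------------
  if (nrow(wake_spans_active) > 0) {
    for (i in seq_len(nrow(wake_spans_active))) {
      s <- wake_spans_active$start[i]; e <- wake_spans_active$end[i]
      n_f <- max(1L, floor((e - s) / plan$fidget_interval_s))
      on <- sort(s + 1 + runif(n_f) * (e - s - 5))
      whole_body <- dplyr::bind_rows(whole_body, tibble::tibble(
        onset = on, duration = runif(n_f, 1.5, 3),
        shift_px = 0, wiggle_mm = runif(n_f, 28, 45)
      ))
    }
  }
  whole_body <- dplyr::arrange(whole_body, .data$onset)
  wb_spans <- spans_new(whole_body$onset, whole_body$onset + whole_body$duration)

  # -- respiratory events ------------------------------------------------------
  n_resp <- round(plan$respiratory_rate * hours)
  respiratory <- tibble::tibble(
    onset = numeric(), duration = numeric(),
    type = character(), amplitude_fraction = numeric()
  )
  if (n_resp > 0) {
    durs <- runif(n_resp, plan$resp_duration_range[1], plan$resp_duration_range[2])
    free <- spans_subtract(sleep_spans, spans_pad(wb_spans, 15))
    free <- spans_subtract(free, edge)
    total_free <- sum(free$end - free$start)
    if (sum(durs) + 25 * n_resp > 0.9 * total_free) {
      abort("infeasible packing: requested respiratory event mass exceeds the night")
    }
    sp <- place_spans(n_resp, durs, free, gap = 25, what = "respiratory events")
    types <- sample(names(plan$resp_type_mix), n_resp, replace = TRUE,
                    prob = plan$resp_type_mix)
    af <- vapply(types, function(tp) {
      switch(tp,
        central = 0,
        obstructive = runif(1, plan$obstructive_amplitude_range[1],
                            plan$obstructive_amplitude_range[2]),
        mixed = runif(1, 0, plan$obstructive_amplitude_range[2]),
        hypopnea = runif(1, plan$hypopnea_amplitude_range[1],
                         plan$hypopnea_amplitude_range[2])
      )
    }, numeric(1))
    respiratory <- tibble::tibble(
      onset = sp$start, duration = sp$end - sp$start,
      type = types, amplitude_fraction = unname(af)
    )
  }
  resp_spans <- spans_new(respiratory$onset, respiratory$onset + respiratory$duration)

  # -- leg movements: PLM trains plus isolated movements ----------------------
  leg <- tibble::tibble(
    onset = numeric(), duration = numeric(), limb = character(),
    displacement = numeric(), train_id = integer()
  )
  leg_free <- spans_subtract(sleep_spans, spans_pad(wb_spans, 10))
  leg_free <- spans_subtract(leg_free, spans_pad(resp_spans, 5))
  leg_free <- spans_subtract(leg_free, edge)
  if (plan$plm_trains > 0) {
    for (tr in seq_len(plan$plm_trains)) {
      m_choices <- seq(plan$plm_movements_range[1], plan$plm_movements_range[2])
      m <- m_choices[sample.int(length(m_choices), 1)]
      ivals <- runif(m - 1, plan$plm_interval_range[1], plan$plm_interval_range[2])
      durs <- runif(m, plan$leg_movement_duration_range[1],
                    plan$leg_movement_duration_range[2])
      span_len <- sum(ivals) + durs[m]
      # the whole train must fit inside one contiguous free stretch
      tr_span <- place_spans(1, span_len, leg_free, gap = 120, what = "PLM trains")
      onsets <- tr_span$start[1] + c(0, cumsum(ivals))
      leg <- dplyr::bind_rows(leg, tibble::tibble(
        onset = onsets, duration = durs,
        limb = sample(c("left", "right", "both"), m, replace = TRUE,
                      prob = c(0.4, 0.4, 0.2)),
        displacement = plan$leg_displacement * runif(m, 0.9, 1.1),
        train_id = tr
      ))
      leg_free <- spans_subtract(leg_free,
                                 spans_pad(spans_new(tr_span$start, tr_span$end), 120))
    }
  }
  if (plan$isolated_leg_movements > 0) {
    durs <- runif(plan$isolated_leg_movements,
                  plan$leg_movement_duration_range[1],
                  plan$leg_movement_duration_range[2])
    sp <- place_spans(plan$isolated_leg_movements, durs, leg_free,
                      gap = 95, what = "isolated leg movements")
    leg <- dplyr::bind_rows(leg, tibble::tibble(
      onset = sp$start, duration = sp$end - sp$start,
      limb = sample(c("left", "right"), nrow(sp), replace = TRUE),
      displacement = plan$leg_displacement * runif(nrow(sp), 0.9, 1.1),
      train_id = NA_integer_
    ))
  }
  leg <- dplyr::arrange(leg, .data$onset)

  structure(
    list(
      respiratory = dplyr::arrange(respiratory, .data$onset),
      leg_movements = leg,
      whole_body = whole_body,
      hypnogram = hypnogram,
      lights_off = lights_off, lights_on = lights_on,
      seed = config$seed
    ),
    class = "event_schedule"
  )
}

#' @export
print.event_schedule <- function(x, ...) {
  cat("<event_schedule> ", nrow(x$respiratory), " respiratory, ",
      nrow(x$leg_movements), " leg, ", nrow(x$whole_body),
      " whole-body events; ", nrow(x$hypnogram), " epochs (",
      sum(x$hypnogram$label == "wake"), " wake)\n", sep = "")
  invisible(x)
}

#' Flatten a schedule to the interchange event table
#'
#' One row per ground-truth event with the columns used by the CSV
#' annotation format: `onset_s`, `duration_s`, `kind`, `subtype`, `magnitude`.
#'
#' @param x An `event_schedule`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.event_schedule <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      onset_s = x$respiratory$onset, duration_s = x$respiratory$duration,
      kind = "respiratory", subtype = x$respiratory$type,
      magnitude = x$respiratory$amplitude_fraction
    ),
    tibble::tibble(
      onset_s = x$leg_movements$onset, duration_s = x$leg_movements$duration,
      kind = "leg_movement", subtype = x$leg_movements$limb,
      magnitude = x$leg_movements$displacement
    ),
    tibble::tibble(
      onset_s = x$whole_body$onset, duration_s = x$whole_body$duration,
      kind = "whole_body", subtype = ifelse(x$whole_body$shift_px != 0, "shift", "fidget"),
      magnitude = x$whole_body$wiggle_mm
    )
  ) |> dplyr::arrange(.data$onset_s)
}
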