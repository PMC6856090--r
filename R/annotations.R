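# CSV interchange for reference annotations (events and hypnograms).

RESP_TYPES <- c("obstructive", "central", "mixed", "hypopnea")
STAGE_MAP <- c(
  W = "wake", wake = "wake", N1 = "sleep", N2 = "sleep", N3 = "sleep",
  R = "sleep", REM = "sleep", sleep = "sleep"
)

#' Write and read event annotation CSVs
#'
#' The event table has one row per event with columns `onset_s`,
#' `duration_s`, `kind` (`respiratory`, `leg_movement`, `whole_body`),
#' `subtype` (respiratory type or limb), and `magnitude`. Times are seconds
#' from recording start.
#'
#' @param events A tibble in the schema above (e.g. from [tidy.event_schedule()]).
#' @param path File path.
#' @return `write_events_csv()` returns `path` invisibly; `read_events_csv()`
#'   a validated, time-ordered tibble.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(ev) == 0) {
    warn("empty event file")
    return(tibble::tibble(onset_s = numeric(), duration_s = numeric(),
                          kind = character(), subtype = character(),
                          magnitude = numeric()))
  }
  need <- c("onset_s", "duration_s", "kind")
  if (!all(need %in% names(ev))) {
    abort(paste0("event file must have columns ", paste(need, collapse = ", ")))
  }
  if (any(ev$duration_s <= 0)) abort("event durations must be positive")
  bad <- setdiff(unique(ev$kind), c("respiratory", "leg_movement", "whole_body"))
  if (length(bad)) abort(paste0("unknown event kind: ", paste(bad, collapse = ", ")))
  resp <- ev[ev$kind == "respiratory", , drop = FALSE]
  if ("subtype" %in% names(ev)) {
    # NA subtype is legitimate: camera-detected events carry no apnea/hypopnea label
    badt <- setdiff(resp$subtype[!is.na(resp$subtype)], RESP_TYPES)
    if (length(badt)) abort(paste0("unknown respiratory type: ", paste(badt, collapse = ", ")))
  }
  resp <- dplyr::arrange(resp, .data$onset_s)
  if (nrow(resp) > 1 &&
      any(resp$onset_s[-1] < (resp$onset_s + resp$duration_s)[-nrow(resp)])) {
    abort("respiratory events must not overlap")
  }
  dplyr::arrange(ev, .data$onset_s)
}

#' Write and read hypnogram CSVs
#'
#' One row per 30-s epoch with columns `epoch_index` (1-based) and `label`.
#' On reading, five-stage PSG labels (`W`, `N1`, `N2`, `N3`, `R`) are
#' collapsed to binary `wake`/`sleep`.
#'
#' @param hypnogram Tibble with `epoch_index` and `label`.
#' @param path File path.
#' @return `read_hypnogram_csv()` returns a tibble with binary labels.
#' @export
write_hypnogram_csv <- function(hypnogram, path) {
  readr::write_csv(hypnogram[, intersect(c("epoch_index", "label"), names(hypnogram))], path)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  hy <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(hy) == 0) {
    warn("empty hypnogram file")
    return(tibble::tibble(epoch_index = integer(), label = character()))
  }
  if (!all(c("epoch_index", "label") %in% names(hy))) {
    abort("hypnogram file must have columns epoch_index, label")
  }
  lab <- STAGE_MAP[as.character(hy$label)]
  if (anyNA(lab)) {
    abort(paste0("unknown stage label: ",
                 paste(unique(hy$label[is.na(lab)]), collapse = ", ")))
  }
  tibble::tibble(epoch_index = as.integer(hy$epoch_index), label = unname(lab))
}
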