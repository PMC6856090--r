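# Internal helpers shared across modules.

# Maximal TRUE runs of a logical vector as (start, end) sample indices.
runs_of <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# Convert sample-index runs to onset/duration in seconds. `t0` is the time of
# sample 1; samples are 1/fs apart. A run covering samples [s, e] spans
# [t0 + (s-1)/fs, t0 + e/fs).
runs_to_spans <- function(runs, fs, t0 = 0) {
  tibble::tibble(
    onset = t0 + (runs$start - 1) / fs,
    duration = (runs$end - runs$start + 1) / fs
  )
}

# Epoch index (1-based) of a time point on a 30-s grid anchored at lights_off.
epoch_of <- function(time_s, lights_off, epoch_s = 30) {
  as.integer(floor((time_s - lights_off) / epoch_s)) + 1L
}

# Derive a vector of per-chunk RNG seeds from one night seed, reproducibly and
# independently of when or how chunks are rendered.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n, replace = FALSE))
}

# Centered rolling median that tolerates NA gaps (gaps are linearly
# interpolated first; leading/trailing NAs take the nearest value).
rolling_median_na <- function(x, k) {
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(x) %% 2L == 0L) length(x) - 1L else length(x))
  if (anyNA(x)) {
    x <- zoo::na.approx(x, na.rm = FALSE)
    x <- zoo::na.locf(x, na.rm = FALSE)
    x <- zoo::na.locf(x, fromLast = TRUE, na.rm = FALSE)
    if (anyNA(x)) abort("signal contains no usable samples")
  }
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# Masked column means: mean of `x[idx, ]` over rows where `valid` is TRUE.
# Returns NaN for columns with no valid rows.
masked_col_means <- function(x, valid, idx = NULL) {
  if (!is.null(idx)) {
    x <- x[idx, , drop = FALSE]
    valid <- valid[idx, , drop = FALSE]
  }
  colSums(x * valid) / colSums(valid)
}

first_true <- function(x) which(x)[1]

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is_scalar_number(x)) abort(paste0("`", name, "` must be a single finite number"))
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    abort(paste0("`", name, "` must be in ", if (strict_min) "(" else "[", min, ", ", max, "]"))
  }
  invisible(x)
}
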