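# Device-agreement statistics: Pearson correlation with significance,
# Bland-Altman limits of agreement, ROC analysis with operating-point
# selection, and event-level matching between detected and reference events.

#' Pearson correlation with significance
#'
#' Product-moment correlation with the two-sided p-value from the t transform
#' on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, nonzero variance.
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) abort("x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` between two measurements of the same quantity:
#' mean difference (bias), SD of differences, limits of agreement
#' (mean +/- 1.96 SD) and a two-sided one-sample t test of the differences
#' against zero (`p_systematic`). Constant differences (zero SD) collapse the
#' limits onto the mean and are flagged `degenerate`; identical inputs are
#' reported as no disagreement (`p_systematic = 1`).
#'
#' @param a,b Equal-length paired numeric vectors, n >= 2.
#' @return A `bland_altman` object (list with the statistics and the per-pair
#'   `(mean, difference)` points); see [tidy.bland_altman()] /
#'   [glance.bland_altman()].
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) abort("a and b differ in length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) abort("need at least 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  degenerate <- s == 0
  p <- if (degenerate) {
    if (m == 0) 1 else NA_real_
  } else {
    t.test(d, mu = 0, alternative = "two.sided")$p.value
  }
  structure(
    list(
      mean_difference = m, sd_difference = s,
      loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
      p_systematic = p, degenerate = degenerate, n = length(d),
      points = tibble::tibble(mean = (a + b) / 2, difference = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> mean difference ", signif(x$mean_difference, 4),
      " [", signif(x$loa_lower, 4), ", ", signif(x$loa_upper, 4),
      "], p = ", signif(x$p_systematic, 3),
      if (x$degenerate) " (degenerate: constant differences)", "\n", sep = "")
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) x$points

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    mean_difference = x$mean_difference, sd_difference = x$sd_difference,
    loa_lower = x$loa_lower, loa_upper = x$loa_upper,
    p_systematic = x$p_systematic, degenerate = x$degenerate, n = x$n
  )
}

#' ROC analysis with operating-point selection
#'
#' Sweeps all midpoints between sorted unique scores (plus sentinels beyond
#' the extremes), computes sensitivity/specificity at each threshold
#' (positive = score above threshold), integrates the curve by the trapezoid
#' rule -- which equals the Mann-Whitney rank statistic, ties counted half --
#' and selects an operating cutoff, by default maximising Youden's J
#' (sensitivity + specificity - 1). The alternative rule picks the lowest
#' cutoff whose sensitivity still reaches `target_sensitivity`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 vector, or factor/character with
#'   `positive` naming the positive class.
#' @param cutoff_rule `"youden"` or `"target_sensitivity"`.
#' @param target_sensitivity Used by the second rule.
#' @param positive Positive class label when `labels` is not logical/numeric.
#' @return A `roc_analysis` object: `points` tibble (`cutoff`, `sensitivity`,
#'   `specificity`), `auc`, `chosen_cutoff`, `sensitivity`, `specificity`.
#' @export
roc_analysis <- function(scores, labels, cutoff_rule = c("youden", "target_sensitivity"),
                         target_sensitivity = 0.9, positive = NULL) {
  cutoff_rule <- match.arg(cutoff_rule)
  if (is.logical(labels)) {
    y <- labels
  } else if (is.numeric(labels)) {
    y <- labels > 0
  } else {
    lv <- unique(as.character(labels))
    if (is.null(positive)) {
      if (length(lv) != 2) abort("labels must have exactly two classes")
      positive <- sort(lv)[2]
    }
    y <- as.character(labels) == positive
  }
  if (length(scores) != length(y)) abort("scores and labels differ in length")
  ok <- is.finite(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")

  u <- sort(unique(scores))
  cuts <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(cuts, function(cc) sum(scores > cc & y) / n1, numeric(1))
  spec <- vapply(cuts, function(cc) sum(scores <= cc & !y) / n0, numeric(1))
  points <- tibble::tibble(cutoff = cuts, sensitivity = sens, specificity = spec)

  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)

  pick <- switch(cutoff_rule,
    youden = which.max(sens + spec - 1),
    target_sensitivity = {
      cand <- which(sens >= target_sensitivity)
      if (length(cand) == 0) which.max(sens) else cand[which.max(cuts[cand])]
    }
  )
  structure(
    list(points = points, auc = auc, chosen_cutoff = cuts[pick],
         sensitivity = sens[pick], specificity = spec[pick],
         cutoff_rule = cutoff_rule, n_positive = n1, n_negative = n0),
    class = "roc_analysis"
  )
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat("<roc_analysis> AUC ", round(x$auc, 3), "; cutoff ",
      signif(x$chosen_cutoff, 4), " (", x$cutoff_rule, "): sensitivity ",
      round(x$sensitivity, 3), ", specificity ", round(x$specificity, 3),
      "\n", sep = "")
  invisible(x)
}

#' @rdname roc_analysis
#' @param x A `roc_analysis` object.
#' @param ... Unused.
#' @export
tidy.roc_analysis <- function(x, ...) x$points

#' @rdname roc_analysis
#' @export
glance.roc_analysis <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, chosen_cutoff = x$chosen_cutoff,
    sensitivity = x$sensitivity, specificity = x$specificity,
    cutoff_rule = x$cutoff_rule,
    n_positive = x$n_positive, n_negative = x$n_negative
  )
}

#' Match detected events against reference events
#'
#' Greedy one-to-one matching by onset proximity: candidate pairs within
#' `tolerance_s` are accepted in order of increasing onset distance, each
#' event matching at most once. Detection rate is matched / |reference|;
#' false discovery rate is unmatched detected / |detected|.
#'
#' @param detected,reference Event tibbles with `onset` (s), time-ordered.
#' @param tolerance_s Onset tolerance, s (3 s suits respiratory events, 1 s
#'   leg movements).
#' @return List with `detection_rate`, `false_discovery_rate`, `n_matched`,
#'   and a `pairs` tibble (`detected_idx`, `reference_idx`, `onset_diff`).
#' @export
match_events <- function(detected, reference, tolerance_s = 3) {
  nd <- nrow(detected); nr <- nrow(reference)
  pairs <- tibble::tibble(detected_idx = integer(), reference_idx = integer(),
                          onset_diff = numeric())
  if (nd > 0 && nr > 0) {
    cand <- expand.grid(d = seq_len(nd), r = seq_len(nr))
    cand$diff <- abs(detected$onset[cand$d] - reference$onset[cand$r])
    cand <- cand[cand$diff <= tolerance_s, , drop = FALSE]
    cand <- cand[order(cand$diff), , drop = FALSE]
    used_d <- logical(nd); used_r <- logical(nr)
    for (i in seq_len(nrow(cand))) {
      di <- cand$d[i]; ri <- cand$r[i]
      if (!used_d[di] && !used_r[ri]) {
        used_d[di] <- TRUE; used_r[ri] <- TRUE
        pairs <- dplyr::bind_rows(pairs, tibble::tibble(
          detected_idx = di, reference_idx = ri, onset_diff = cand$diff[i]
        ))
      }
    }
  }
  list(
    detection_rate = if (nr > 0) nrow(pairs) / nr else NA_real_,
    false_discovery_rate = if (nd > 0) (nd - nrow(pairs)) / nd else NA_real_,
    n_matched = nrow(pairs),
    pairs = pairs
  )
}
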