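# Agreement statistics: correlation, Bland-Altman, ROC, event matching.

test_that("pearson_with_p matches hand computation and handles exact linearity", {
  res <- pearson_with_p(1:10, 2 * (1:10) + 1)
  expect_equal(res$r, 1.0)

  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  # hand computation: centered cross-products 8, sum of squares 10 and 10
  r_hand <- 8 / sqrt(10 * 10)
  t_hand <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 3)
  res <- pearson_with_p(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)

  expect_error(pearson_with_p(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_with_p(rep(1, 5), 1:5), "zero variance")
})

test_that("pearson_with_p is invariant to affine transforms up to sign", {
  withr::with_seed(5, {
    x <- rnorm(20); y <- rnorm(20) + 0.5 * x
  })
  r0 <- pearson_with_p(x, y)$r
  expect_equal(pearson_with_p(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_with_p(x, -2 * y + 1)$r, -r0, tolerance = 1e-12)
})

test_that("bland_altman matches hand-computed values", {
  a <- c(2, 4, 6, 8)
  b <- c(1, 2, 3, 4) # d = 1, 2, 3, 4
  res <- glance(bland_altman(a, b))
  sd_hand <- sqrt(sum((c(1, 2, 3, 4) - 2.5)^2) / 3)
  t_hand <- 2.5 / (sd_hand / 2)
  expect_equal(res$mean_difference, 2.5, tolerance = 1e-12)
  expect_equal(res$sd_difference, sd_hand, tolerance = 1e-12)
  expect_equal(res$loa_lower, 2.5 - 1.96 * sd_hand, tolerance = 1e-12)
  expect_equal(res$loa_upper, 2.5 + 1.96 * sd_hand, tolerance = 1e-12)
  expect_equal(res$p_systematic, 2 * stats::pt(-abs(t_hand), df = 3), tolerance = 1e-12)
})

test_that("bland_altman handles degenerate cases and is antisymmetric", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mean_difference, 0)
  expect_equal(ident$p_systematic, 1)
  expect_true(ident$degenerate)

  const <- bland_altman(c(6, 7, 8), c(1, 2, 3))
  expect_true(const$degenerate)
  expect_equal(const$loa_lower, const$mean_difference)
  expect_equal(const$loa_upper, const$mean_difference)

  withr::with_seed(2, {
    a <- rnorm(15); b <- rnorm(15)
  })
  expect_equal(bland_altman(a, b)$mean_difference,
               -bland_altman(b, a)$mean_difference, tolerance = 1e-12)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("ROC AUC equals the brute-force Mann-Whitney statistic", {
  u_oracle <- function(scores, y) {
    s1 <- scores[y]; s0 <- scores[!y]
    tot <- 0
    for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(s1) * length(s0))
  }
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(10:40, 1)
      y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      scores <- round(rnorm(n, mean = y), sample(0:2, 1)) # ties likely
      roc <- roc_analysis(scores, y)
      expect_equal(roc$auc, u_oracle(scores, y), tolerance = 1e-10)
    }
  })
})

test_that("ROC handles separation, chance-level scores, and bad input", {
  sep <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1.0)
  expect_equal(sep$sensitivity, 1.0)
  expect_equal(sep$specificity, 1.0)

  withr::with_seed(3, {
    scores <- rnorm(200)
    y <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  })
  expect_lt(abs(roc_analysis(scores, y)$auc - 0.5), 0.1)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both classes")
})

test_that("ROC AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(7, {
    scores <- rnorm(60)
    y <- scores + rnorm(60) > 0
  })
  a0 <- roc_analysis(scores, y)$auc
  expect_equal(roc_analysis(exp(scores), y)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_analysis(5 * scores - 2, y)$auc, a0, tolerance = 1e-12)
})

test_that("ROC agrees with an independent package implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    scores <- rnorm(80)
    y <- scores + rnorm(80, sd = 1.5) > 0
  })
  ours <- roc_analysis(scores, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("match_events handles identity, empty input and jittered copies", {
  ev <- tibble::tibble(onset = c(10, 50, 90), duration = rep(5, 3))
  ident <- match_events(ev, ev, tolerance_s = 3)
  expect_equal(ident$detection_rate, 1.0)
  expect_equal(ident$false_discovery_rate, 0.0)

  none <- match_events(ev[0, ], ev, tolerance_s = 3)
  expect_equal(none$detection_rate, 0.0)
})

test_that("greedy matching equals maximum bipartite matching on jittered events", {
  skip_if_not_installed("igraph")
  withr::with_seed(21, {
    for (case in 1:50) {
      n <- sample(5:25, 1)
      # reference events separated by more than twice the tolerance, so the
      # jittered copy admits a perfect matching
      ref <- tibble::tibble(onset = cumsum(runif(n, 2.5, 60)), duration = 10)
      jitter <- runif(n, -0.9, 0.9)
      det <- tibble::tibble(onset = sort(ref$onset + jitter), duration = 10)
      m <- match_events(det, ref, tolerance_s = 1)
      # maximum matching oracle on the tolerance graph
      g <- igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices(paste0("d", seq_len(n)), type = TRUE) +
        igraph::vertices(paste0("r", seq_len(n)), type = FALSE)
      edges <- c()
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(det$onset[i] - ref$onset[j]) <= 1) edges <- c(edges, paste0("d", i), paste0("r", j))
      }
      g <- igraph::add_edges(g, edges)
      best <- igraph::max_bipartite_match(g)$matching_size
      expect_equal(m$n_matched, best)
      expect_equal(m$detection_rate, 1.0)
    }
  })
})
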