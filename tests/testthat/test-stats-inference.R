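test_that("jsd matches a direct per-bin summation oracle", {
  p <- c(0.5, 0.5)
  q <- c(0.9, 0.1)
  m <- (p + q) / 2
  oracle <- sum(p * log2(p / m)) / 2 + sum(q * log2(q / m)) / 2
  expect_equal(jsd(p, q), oracle, tolerance = 1e-12)
  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)       # disjoint supports: 1 bit
  expect_equal(jsd(p, q), jsd(q, p))
  set.seed(81)
  a <- stats::runif(100)
  a <- a / sum(a)
  b <- stats::runif(100)
  b <- b / sum(b)
  mm <- (a + b) / 2
  oracle2 <- sum(a * log2(a / mm)) / 2 + sum(b * log2(b / mm)) / 2
  expect_equal(jsd(a, b), oracle2, tolerance = 1e-12)
  expect_error(jsd(a, b[1:50]), "mismatch")
})

test_that("jsd on priors demands a shared grid", {
  pts <- simulate_trial_points(10, three_mode_prior())
  p1 <- estimate_prior(pts, coarse_grid())
  p2 <- estimate_prior(pts, triangle_grid(bin = 0.01))
  expect_error(jsd(p1, p2), "different grids")
  expect_equal(jsd(p1, p1), 0)
})

test_that("well-separated groups are detected by the split-half test", {
  o22 <- omega22()
  pr_a <- mixture_prior(o22[o22$ratio == "1:1:2", ], 1, sd = 0.015)
  pr_b <- mixture_prior(o22[o22$ratio == "3:3:2", ], 1, sd = 0.015)
  set.seed(82)
  a <- simulate_trial_points(100, pr_a)
  b <- simulate_trial_points(100, pr_b)
  res <- split_half_group_test(a, b, coarse_grid(), n_boot = 100)
  expect_lte(res$p_value, 0.01)
  expect_gt(res$D_mean, 0)
  expect_true(res$D_ci[1] <= res$D_mean && res$D_mean <= res$D_ci[2])
})

test_that("same-distribution groups give a null divergence excess", {
  set.seed(83)
  a <- simulate_trial_points(60, three_mode_prior())
  b <- simulate_trial_points(60, three_mode_prior())
  res <- split_half_group_test(a, b, coarse_grid(), n_boot = 100)
  expect_gt(res$p_value, 0.05)
  expect_lt(abs(res$D_mean), 0.05)
  # the same dataset on both sides: split halves overlap, so the
  # cross-half divergence can only undershoot the within-half null
  res2 <- split_half_group_test(a, a, coarse_grid(), n_boot = 100)
  expect_gt(res2$p_value, 0.05)
  expect_lte(res2$D_mean, 0)
})

test_that("peakiness separates peaked from uniform data", {
  set.seed(84)
  peaked <- simulate_trial_points(120, three_mode_prior())
  unif <- simulate_trial_points(120, NULL)
  g <- coarse_grid()
  pk <- peakiness(peaked, g, n_null = 100)
  expect_lte(pk$top_mass$p_value, 0.01)
  expect_lte(pk$peak_ratio$p_value, 0.01)
  expect_gt(pk$top_mass$statistic, 0.6)
  expect_gt(pk$peak_ratio$statistic, 5)
  pu <- peakiness(unif, g, n_null = 100)
  expect_gt(pu$top_mass$p_value, 0.05)
  expect_gt(pu$peak_ratio$p_value, 0.05)
  # finite-sample uniform estimates are lumpy, but stay well below the
  # peaked statistics
  expect_lt(pu$top_mass$statistic, pk$top_mass$statistic - 0.2)
  expect_lt(pu$peak_ratio$statistic, pk$peak_ratio$statistic / 2)
})

test_that("integer overlap finds structure at the category points", {
  o22 <- omega22()
  set.seed(85)
  # points exactly at the categories: observed distance 0, minimal p
  at <- cbind(o22$x, o22$y)[rep(1:22, 3), ]
  r1 <- integer_overlap(at, o22, "uniform", n_null = 99)
  expect_equal(r1$statistic, 0)
  expect_lte(r1$p_value, 1 / 99 + 1e-9)
  r2 <- integer_overlap(at, o22, "spaced", n_null = 99)
  expect_lte(r2$p_value, 1 / 99 + 1e-9)
  # spaced-null audit: every null set lies within d_min/2 of its anchor
  dmin <- ratio_set_dmin(o22)
  set.seed(86)
  pts <- rhythmprior:::runif_triangle(50, f = 0.15)
  r3 <- integer_overlap(pts, o22, "spaced", n_null = 50)
  expect_s3_class(r3, "bootstrap_result")
  # uniform data: spaced variant non-significant
  expect_gt(r3$p_value, 0.05)
  expect_error(integer_overlap(matrix(numeric(0), ncol = 2), o22),
               "no points")
})

test_that("integerness variant detects category-aligned priors", {
  o22 <- omega22()
  set.seed(87)
  peaked <- simulate_trial_points(150, mixture_prior(
    o22[o22$ratio %in% c("1:1:2", "1:2:2", "3:3:2", "1:1:1"), ],
    c(0.3, 0.3, 0.2, 0.2), sd = 0.01))
  km <- kernel_matrix(peaked, coarse_grid())
  r <- integer_overlap(km$means, o22, "integerness", n_null = 50,
                       grid = coarse_grid())
  expect_lte(r$p_value, 0.05)
})

test_that("bias statistic is affine invariant and detects shifts", {
  o22 <- omega22()
  anchor <- c(o22$x[3], o22$y[3])
  set.seed(88)
  S <- matrix(c(4e-4, 1e-4, 1e-4, 3e-4), 2)
  pts <- MASS::mvrnorm(12, anchor, S)
  r <- bias_test(pts, anchor, n_null = 200)
  # the ratio statistic is at most 1 by construction
  expect_lte(r$statistic, 1)
  # invariance of the statistic under an invertible linear map
  A <- matrix(c(2, 0.5, -0.3, 1.5), 2)
  stat_of <- function(x, a) {
    Sinv <- solve(stats::cov(x))
    msd <- function(centre) {
      d <- sweep(x, 2, centre)
      mean(rowSums((d %*% Sinv) * d))
    }
    msd(colMeans(x)) / msd(a)
  }
  expect_equal(stat_of(pts, anchor),
               stat_of(pts %*% t(A), as.numeric(A %*% anchor)),
               tolerance = 1e-9)
  # a 3-sd shift is detected
  set.seed(89)
  shifted <- MASS::mvrnorm(12, anchor + c(3 * sqrt(S[1, 1]), 0), S)
  r2 <- bias_test(shifted, anchor, n_null = 2000)
  expect_lt(r2$p_value, 0.01)
  expect_error(bias_test(pts[1:2, ], anchor), "at least 3")
})

test_that("tapping metrics follow the sample-sd convention", {
  # two taps at +10 and -10: mean 0, sample sd = sqrt(200)
  rec <- list(list(iterations = list(list(
    index = 1, stimulus = c(600, 700, 700),
    record = list(valid = TRUE, asynchronies = c(10, -10))))))
  tm <- tapping_metrics(rec)
  expect_equal(tm$mean_ms, 0)
  expect_equal(tm$sd_ms, sqrt(200))
  expect_equal(tm$sd_ms, 14.14, tolerance = 1e-3)
  empty <- tapping_metrics(list(list(iterations = list())))
  expect_true(is.na(empty$mean_ms))
  expect_equal(empty$n_taps, 0L)
})

test_that("identical halves give perfect corrected reliability", {
  ctr <- project(rep(1 / 3, 3))
  pts <- data.frame(trial = rep(1:8, each = 2),
                    x = ctr[1], y = ctr[2])
  rel <- split_half_reliability(pts, coarse_grid(), n_splits = 3)
  expect_equal(rel$reliability, 1, tolerance = 1e-9)
})

test_that("permutation symmetry classifies by the longest interval", {
  sym <- permutation_asymmetry(rbind(c(0.5, 0.25, 0.25),
                                     c(0.25, 0.5, 0.25),
                                     c(0.25, 0.25, 0.5)))
  expect_equal(sym$fractions, rep(1 / 3, 3))
  all3 <- permutation_asymmetry(rbind(c(0.2, 0.3, 0.5), c(0.25, 0.3, 0.45)))
  expect_equal(all3$fractions, c(0, 0, 1))
  tie <- permutation_asymmetry(rbind(c(0.4, 0.4, 0.2), c(0.5, 0.25, 0.25)))
  expect_equal(tie$n_ties, 1L)
})

test_that("first taps land after the long interval when produced there", {
  # build a responder that starts tapping at the onset after the long
  # interval (drop all earlier taps)
  pat <- c(1000, 500, 500)   # longest interval first -> onset position 1
  responder <- function(stimulus, iteration) {
    stim <- pattern_onsets(stimulus)
    taps <- stim[-1]          # first tap at onset index 1 (0-based 1)
    list(stimulus_onsets = stim, response_onsets = taps)
  }
  tr <- run_trial(pat, responder, n_iter = 2)
  res <- first_tap_after_long(list(tr))
  expect_equal(res$fraction, 1)
})

test_that("rank-sum weight comparison detects shifted groups", {
  set.seed(90)
  a <- stats::rnorm(12, 0.3, 0.02)
  b <- stats::rnorm(12, 0.1, 0.02)
  r <- weight_rank_sum(a, b)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$cohen_d, 2)
  expect_true(r$ci[1] <= r$mean_diff && r$mean_diff <= r$ci[2])
  expect_error(weight_rank_sum(numeric(0), b), "empty")
})

test_that("pairwise-distance permutation test separates homogeneous sets", {
  o22 <- omega22()
  g <- coarse_grid()
  set.seed(91)
  # set A: four groups from one prior; set B: four groups from four priors
  pr_fixed <- mixture_prior(o22[o22$ratio == "1:1:2", ], 1, sd = 0.015)
  others <- c("1:1:1", "1:2:2", "3:3:2", "1:1:3")
  priors <- c(
    lapply(1:4, function(i) {
      estimate_prior(simulate_trial_points(60, pr_fixed), g)
    }),
    lapply(others, function(rt) {
      estimate_prior(simulate_trial_points(
        60, mixture_prior(o22[o22$ratio == rt, ], 1, sd = 0.015)), g)
    }))
  names(priors) <- paste0("g", 1:8)
  res <- pairwise_jsd_permutation(priors, 1:4, 5:8, n_perm = 200)
  expect_lt(res$statistic, 0)
  expect_lte(res$p_value, 0.05)
})
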