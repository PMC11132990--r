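# Kullback-Leibler divergence in bits over a shared grid; 0 log 0 = 0.
# Masses below 1e-300 are treated as zero so that denormal underflow in
# (p + q)/2 cannot produce a spurious infinite ratio.
kl_bits <- function(p, q) {
  i <- p > 1e-300
  sum(p[i] * log2(p[i] / q[i]))
}

#' Jensen-Shannon divergence between two binned priors
#'
#' JSD(P, Q) = KL(P, M)/2 + KL(Q, M)/2 with M = (P + Q)/2, in bits
#' (log base 2), so 0 <= JSD <= 1; symmetric; 0 log 0 treated as 0.
#'
#' @param p,q `discrete_prior` objects on the same grid, or bare
#'   probability vectors of equal length.
#' @return divergence in bits.
#' @export
jsd <- function(p, q) {
  if (inherits(p, "discrete_prior") && inherits(q, "discrete_prior")) {
    if (!same_grid(p$grid, q$grid)) stop("priors are on different grids")
    p <- p$p
    q <- q$p
  }
  if (length(p) != length(q)) stop("grid mismatch")
  m <- (p + q) / 2
  kl_bits(p, m) / 2 + kl_bits(q, m) / 2
}

new_bootstrap_result <- function(statistic, p_value, null = NULL, ...) {
  structure(c(list(statistic = statistic, p_value = p_value, null = null),
              list(...)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("statistic = %.6g, p = %.4g (n_null = %d)\n",
              x$statistic, x$p_value, length(x$null)))
  invisible(x)
}

#' Split-half bootstrap test for a difference between two groups' priors
#'
#' For each of `n_boot` bootstrap rounds the trials of each group are
#' split in half at random; the across-group divergence between first
#' halves, JSD(P1_half, P2_half), is compared with the two within-group
#' split-half divergences, which quantify the divergence expected from
#' finite sampling alone. The p-value is the larger (least favourable) of
#' the two rank-based p-values, so a significant result means the groups
#' differ by more than either group's internal sampling noise. Also
#' reports the mean and 95% CI of the divergence excess
#' D = [(cross - within1) + (cross - within2)] / 2.
#'
#' @param points_a,points_b repetition-point tables (`trial`, `x`, `y`)
#'   for the two groups.
#' @param grid shared [triangle_grid()].
#' @param n_boot bootstrap rounds.
#' @param gamma_ms,period,gamma_mode kernel options, see [trial_kernel()].
#' @return a `bootstrap_result` with fields `statistic` (mean cross-group
#'   JSD), `p_value`, `p_within` (both one-sided ranks), `D_mean`, `D_ci`.
#' @export
split_half_group_test <- function(points_a, points_b,
                                  grid = triangle_grid(), n_boot = 1000,
                                  gamma_ms = 15, period = 2000,
                                  gamma_mode = "sd") {
  ka <- kernel_matrix(points_a, grid, gamma_ms, period, gamma_mode)
  kb <- kernel_matrix(points_b, grid, gamma_ms, period, gamma_mode)
  na <- nrow(ka$K)
  nb <- nrow(kb$K)
  if (na < 4L || nb < 4L) stop("need at least 4 trials per group")
  half_prior <- function(K, idx) {
    p <- colMeans(K[idx, , drop = FALSE])
    p / sum(p)
  }
  cross <- within_a <- within_b <- numeric(n_boot)
  for (j in seq_len(n_boot)) {
    ia <- sample.int(na)
    ib <- sample.int(nb)
    a1 <- half_prior(ka$K, ia[seq_len(na %/% 2)])
    a2 <- half_prior(ka$K, ia[(na %/% 2 + 1L):na])
    b1 <- half_prior(kb$K, ib[seq_len(nb %/% 2)])
    b2 <- half_prior(kb$K, ib[(nb %/% 2 + 1L):nb])
    cross[j] <- jsd(a1, b1)
    within_a[j] <- jsd(a1, a2)
    within_b[j] <- jsd(b1, b2)
  }
  obs <- mean(cross)
  p_a <- (1 + sum(within_a >= obs)) / (n_boot + 1)
  p_b <- (1 + sum(within_b >= obs)) / (n_boot + 1)
  D <- (cross - within_a + cross - within_b) / 2
  new_bootstrap_result(obs, max(p_a, p_b),
                       null = cbind(within_a = within_a,
                                    within_b = within_b),
                       p_within = c(a = p_a, b = p_b),
                       D_mean = mean(D),
                       D_ci = unname(stats::quantile(D, c(0.025, 0.975))),
                       n_boot = n_boot)
}

# Uniform points on the inner (or full) region in triangle coordinates.
runif_triangle <- function(n, f = 0) {
  project(f + (1 - 3 * f) * runif_simplex(n))
}

# Mean density grid of isotropic kernels centred at uniform points (the
# peakiness null: one regularizer-width kernel per sampled point).
uniform_null_prior <- function(n_points, grid, f, sd) {
  pts <- runif_triangle(n_points, f = f)
  d2 <- outer(pts[, 1], grid$x, "-")^2 + outer(pts[, 2], grid$y, "-")^2
  p <- colMeans(exp(-d2 / (2 * sd^2)))
  p / sum(p)
}

#' Peakiness of an estimated prior
#'
#' Two statistics against a uniform-tapping null: (a) the probability mass
#' captured by the top `top_frac` of inner-region bins, and (b) the peak
#' bin density relative to the uniform density over the inner region.
#' The null redraws the same number of trial points uniformly from the
#' inner region, one regularizer-width kernel per point.
#'
#' @param points repetition-point table (`trial`, `x`, `y`).
#' @param grid a [triangle_grid()].
#' @param n_null null replicates.
#' @param top_frac fraction of inner bins counted as the "top" (0.33).
#' @param gamma_ms,period,gamma_mode kernel options.
#' @return list of two `bootstrap_result`s: `top_mass` and `peak_ratio`.
#' @export
peakiness <- function(points, grid = triangle_grid(), n_null = 1000,
                      top_frac = 0.33, gamma_ms = 15, period = 2000,
                      gamma_mode = "sd") {
  km <- kernel_matrix(points, grid, gamma_ms, period, gamma_mode)
  prior <- prior_from_kernels(km)
  n_trials <- nrow(km$K)
  inner <- grid$inner
  n_top <- max(1L, as.integer(round(top_frac * sum(inner))))
  stat_pair <- function(p) {
    pi_ <- p[inner]
    c(top = sum(sort(pi_, decreasing = TRUE)[seq_len(n_top)]),
      peak = max(pi_) * sum(inner))
  }
  obs <- stat_pair(prior$p)
  g <- gamma_ms / period
  sd_null <- if (gamma_mode == "sd") g else sqrt(g)
  null <- matrix(0, n_null, 2)
  for (j in seq_len(n_null)) {
    null[j, ] <- stat_pair(uniform_null_prior(n_trials, grid,
                                              attr(grid, "f"), sd_null))
  }
  list(top_mass = new_bootstrap_result(
         unname(obs["top"]),
         (1 + sum(null[, 1] >= obs["top"])) / (n_null + 1),
         null = null[, 1], n_trials = n_trials),
       peak_ratio = new_bootstrap_result(
         unname(obs["peak"]),
         (1 + sum(null[, 2] >= obs["peak"])) / (n_null + 1),
         null = null[, 2], n_trials = n_trials))
}

#' Overlap of reproductions with the small-integer-ratio set
#'
#' Three variants. `"uniform"`: the mean minimal distance from each point
#' to the category set, against null category sets drawn uniformly from
#' the full triangle. `"spaced"`: the same statistic, but null sets keep
#' the spacing of the real set (each null category uniform in a disc of
#' radius d_min/2 around its anchor). `"integerness"`: the JSD between the
#' prior and the normalized indicator distribution of the category set,
#' against nulls built by refitting an unconstrained mixture to the points
#' and randomizing its component means.
#'
#' @param points n-by-2 matrix of fifth-iteration trial points.
#' @param rset a `ratio_set`.
#' @param variant one of `"uniform"`, `"spaced"`, `"integerness"`.
#' @param n_null null replicates.
#' @param grid grid for the integerness variant.
#' @param gamma_ms,period kernel regularizer for the integerness prior.
#' @param prior optional `discrete_prior` for the integerness variant
#'   (built from `points` when omitted).
#' @return a `bootstrap_result` (one-sided p: smaller observed statistic
#'   means tighter overlap with the integer ratios).
#' @export
integer_overlap <- function(points, rset = omega22(),
                            variant = c("uniform", "spaced", "integerness"),
                            n_null = 1000, grid = triangle_grid(),
                            gamma_ms = 15, period = 2000, prior = NULL) {
  variant <- match.arg(variant)
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("no points")
  if (variant %in% c("uniform", "spaced")) {
    obs <- mean(min_distance_to_set(points, rset)$distance)
    K <- nrow(rset)
    dmin <- ratio_set_dmin(rset)
    null <- numeric(n_null)
    for (j in seq_len(n_null)) {
      set_xy <- if (variant == "uniform") {
        runif_triangle(K, f = 0)
      } else {
        r <- (dmin / 2) * sqrt(stats::runif(K))
        th <- stats::runif(K, 0, 2 * pi)
        cbind(rset$x + r * cos(th), rset$y + r * sin(th))
      }
      d2 <- outer(points[, 1], set_xy[, 1], "-")^2 +
        outer(points[, 2], set_xy[, 2], "-")^2
      null[j] <- mean(sqrt(apply(d2, 1, min)))
    }
    return(new_bootstrap_result(
      obs, (1 + sum(null <= obs)) / (n_null + 1), null = null,
      variant = variant))
  }
  # integerness: JSD between the prior and the category indicator
  if (is.null(prior)) {
    pts_df <- data.frame(trial = seq_len(nrow(points)),
                         x = points[, 1], y = points[, 2])
    prior <- estimate_prior(pts_df, grid = grid, gamma_ms = gamma_ms,
                            period = period)
  } else {
    grid <- prior$grid
  }
  ind <- numeric(nrow(grid))
  nearest_bin <- vapply(seq_len(nrow(rset)), function(k) {
    which.min((grid$x - rset$x[k])^2 + (grid$y - rset$y[k])^2)
  }, integer(1))
  for (b in nearest_bin) ind[b] <- ind[b] + 1 / nrow(rset)
  obs <- jsd(prior$p, ind)
  gm <- fit_constrained_gmm(points, anchors = rset, constrain = FALSE)
  null <- numeric(n_null)
  f <- attr(grid, "f")
  for (j in seq_len(n_null)) {
    rand_means <- runif_triangle(nrow(rset), f = f)
    q <- numeric(nrow(grid))
    for (k in seq_len(nrow(rset))) {
      q <- q + gm$weights[k] * gauss_on_grid(grid, rand_means[k, ],
                                             gm$covs[, , k])
    }
    null[j] <- jsd(q / sum(q), ind)
  }
  new_bootstrap_result(obs, (1 + sum(null <= obs)) / (n_null + 1),
                       null = null, variant = variant)
}

#' Bias of fitted category means away from the integer ratio
#'
#' Nonparametric analogue of an analysis of variance: the statistic is the
#' ratio of the average squared Mahalanobis distance of the group-level
#' component means from their empirical mean to that from the integer
#' ratio anchor (a ratio well below 1 indicates systematic bias). The null
#' redraws the means from a Gaussian with the empirical covariance centred
#' at the anchor (zero bias).
#'
#' @param points m-by-2 matrix of per-group component means for one
#'   category (triangle coordinates).
#' @param anchor length-2 anchor point.
#' @param n_null null replicates (default 10,000).
#' @return a `bootstrap_result` (one-sided p: smaller ratio = more bias).
#' @export
bias_test <- function(points, anchor, n_null = 10000) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 group means")
  S <- stats::cov(points)
  if (abs(det(S)) < 1e-24) {
    warning("near-singular covariance; regularizing")
    S <- S + diag(1e-12, 2)
  }
  # statistic is computed from a point set alone (Mahalanobis wrt the
  # set's own empirical covariance), so null replicates mirror the data
  stat <- function(x) {
    Sinv <- solve(stats::cov(x) + diag(1e-15, 2))
    msd <- function(centre) {
      d <- sweep(x, 2, centre)
      mean(rowSums((d %*% Sinv) * d))
    }
    msd(colMeans(x)) / msd(anchor)
  }
  obs <- stat(points)
  null <- vapply(seq_len(n_null), function(j) {
    stat(MASS::mvrnorm(nrow(points), mu = anchor, Sigma = S))
  }, numeric(1))
  new_bootstrap_result(obs, (1 + sum(null <= obs)) / (n_null + 1),
                       null = null)
}

#' Tapping asynchrony summary
#'
#' Mean and sample standard deviation of the signed tap-minus-click
#' asynchrony over all matched taps of valid iterations (the sd is the
#' standard tapping-precision measure; the mean is typically negative).
#'
#' @param trials list of `trial_record`s.
#' @return list with `mean_ms`, `sd_ms`, `n_taps`.
#' @export
tapping_metrics <- function(trials) {
  asyn <- unlist(lapply(trials, function(tr) {
    unlist(lapply(tr$iterations, function(it) {
      if (it$record$valid) it$record$asynchronies else numeric(0)
    }))
  }))
  if (length(asyn) == 0L) {
    return(list(mean_ms = NA_real_, sd_ms = NA_real_, n_taps = 0L))
  }
  list(mean_ms = mean(asyn), sd_ms = stats::sd(asyn),
       n_taps = length(asyn))
}

#' Split-half reliability of the estimated prior
#'
#' Pearson correlation between the prior grids estimated from two random
#' halves of the trials, boosted by the Spearman-Brown formula
#' r* = 2r / (1 + r) and averaged over `n_splits` random splits.
#'
#' @param points repetition-point table (`trial`, `x`, `y`).
#' @param grid a [triangle_grid()].
#' @param n_splits random splits to average over.
#' @param gamma_ms,period,gamma_mode kernel options.
#' @return list with `reliability` (corrected, averaged), `r_splits`
#'   (uncorrected per split) and `n_trials`.
#' @export
split_half_reliability <- function(points, grid = triangle_grid(),
                                   n_splits = 20, gamma_ms = 15,
                                   period = 2000, gamma_mode = "sd") {
  km <- kernel_matrix(points, grid, gamma_ms, period, gamma_mode)
  n <- nrow(km$K)
  if (n < 2L) stop("need at least 2 trials")
  r <- numeric(n_splits)
  for (j in seq_len(n_splits)) {
    idx <- sample.int(n)
    h1 <- colMeans(km$K[idx[seq_len(n %/% 2)], , drop = FALSE])
    h2 <- colMeans(km$K[idx[(n %/% 2 + 1L):n], , drop = FALSE])
    r[j] <- stats::cor(h1, h2)
  }
  rstar <- 2 * r / (1 + r)
  list(reliability = mean(rstar), r_splits = r, n_trials = n)
}

#' Cyclic-permutation symmetry of final reproductions
#'
#' Fraction of reproductions whose longest interval is in the first,
#' second or third position; ties are excluded and counted.
#'
#' @param props n-by-3 matrix of reproduction proportion triples.
#' @return list with `fractions` (length 3, sums to 1) and `n_ties`.
#' @export
permutation_asymmetry <- function(props) {
  props <- as.matrix(props)
  stopifnot(ncol(props) == 3L)
  longest <- apply(props, 1, function(v) {
    w <- which(v == max(v))
    if (length(w) > 1L) NA_integer_ else w
  })
  ties <- sum(is.na(longest))
  longest <- longest[!is.na(longest)]
  list(fractions = as.numeric(table(factor(longest, levels = 1:3))) /
         length(longest),
       n_ties = ties)
}

#' Fraction of iterations whose first tap follows the long interval
#'
#' For each valid iteration, checks whether the earliest matched tap falls
#' on the stimulus onset immediately after the longest stimulus interval
#' (listeners tend to treat that onset as the pattern's beginning).
#'
#' @param trials list of `trial_record`s.
#' @return list with `fraction`, `n_iterations`, `n_ties` (iterations
#'   with tied longest intervals, excluded).
#' @export
first_tap_after_long <- function(trials) {
  hits <- 0L
  total <- 0L
  ties <- 0L
  for (tr in trials) {
    for (it in tr$iterations) {
      rec <- it$record
      if (!rec$valid || is.na(rec$first_position)) next
      s <- it$stimulus
      w <- which(s == max(s))
      if (length(w) > 1L) {
        ties <- ties + 1L
        next
      }
      total <- total + 1L
      if (rec$first_position == (w %% 3L)) hits <- hits + 1L
    }
  }
  list(fraction = if (total) hits / total else NA_real_,
       n_iterations = total, n_ties = ties)
}

#' Compare a category weight between two sets of groups
#'
#' One-sided Wilcoxon rank-sum test that the weight is higher in the
#' in-group, with Cohen's d (pooled sample sd), the mean difference and a
#' bootstrap percentile CI for it.
#'
#' @param w_in,w_out numeric vectors of per-group category weights.
#' @param n_boot bootstrap rounds for the CI.
#' @param conf confidence level.
#' @return list with `p_value`, `cohen_d`, `mean_diff`, `ci`.
#' @export
weight_rank_sum <- function(w_in, w_out, n_boot = 1000, conf = 0.95) {
  if (length(w_in) == 0L || length(w_out) == 0L) stop("empty group side")
  p <- stats::wilcox.test(w_in, w_out, alternative = "greater",
                          exact = FALSE)$p.value
  sp <- sqrt(((length(w_in) - 1) * stats::var(w_in) +
                (length(w_out) - 1) * stats::var(w_out)) /
               (length(w_in) + length(w_out) - 2))
  d <- (mean(w_in) - mean(w_out)) / sp
  boots <- vapply(seq_len(n_boot), function(j) {
    mean(sample(w_in, replace = TRUE)) - mean(sample(w_out, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(p_value = p, cohen_d = d, mean_diff = mean(w_in) - mean(w_out),
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))))
}

#' Permutation test on average pairwise prior distances of group sets
#'
#' Tests whether one set of groups (e.g. students) is internally more
#' homogeneous than another: the statistic is the difference between the
#' mean pairwise JSDs within set A and within set B; the null resamples
#' both sets without replacement from the union of group labels.
#'
#' @param priors named list of `discrete_prior`s (one per group).
#' @param set_a,set_b character or integer indices into `priors`.
#' @param n_perm permutation rounds.
#' @return a `bootstrap_result` (one-sided p for set A being more
#'   homogeneous, i.e. the observed difference being low).
#' @export
pairwise_jsd_permutation <- function(priors, set_a, set_b, n_perm = 1000) {
  nm <- names(priors)
  if (is.character(set_a)) set_a <- match(set_a, nm)
  if (is.character(set_b)) set_b <- match(set_b, nm)
  n <- length(priors)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- jsd(priors[[i]], priors[[j]])
    }
  }
  mean_within <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    mean(D[idx, idx][upper.tri(diag(length(idx)))])
  }
  pool <- c(set_a, set_b)
  obs <- mean_within(set_a) - mean_within(set_b)
  null <- vapply(seq_len(n_perm), function(k) {
    perm <- sample(pool)
    mean_within(perm[seq_along(set_a)]) -
      mean_within(perm[-seq_along(set_a)])
  }, numeric(1))
  new_bootstrap_result(obs, (1 + sum(null <= obs)) / (n_perm + 1),
                       null = null, jsd_matrix = D)
}
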