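#' Ground-truth mixture prior specification
#'
#' Builds the prior table used by the synthetic tapper: isotropic Gaussian
#' components (in triangle units) centred at rhythm categories.
#'
#' @param props n-by-3 matrix (or data frame) of component centres as
#'   proportion triples, or a `ratio_set` whose members are used.
#' @param weights component weights (normalized to sum 1).
#' @param sd isotropic component standard deviation(s), triangle units.
#' @return data frame with columns p1, p2, p3, weight, sd.
#' @export
mixture_prior <- function(props, weights, sd = 0.03) {
  if (inherits(props, "ratio_set")) props <- as.matrix(props[, c("p1", "p2", "p3")])
  props <- as.matrix(props)
  stopifnot(ncol(props) == 3L, length(weights) == nrow(props))
  data.frame(p1 = props[, 1], p2 = props[, 2], p3 = props[, 3],
             weight = weights / sum(weights),
             sd = rep_len(sd, nrow(props)))
}

#' Parameters of the synthetic Bayesian tapper
#'
#' A generative observer/motor model with a known ground-truth prior: the
#' observer perceives the stimulus through isotropic Gaussian sensory
#' noise on the triangle, forms the posterior against its prior on the
#' analysis grid, and reproduces the posterior mean (or a posterior
#' sample); the motor stage perturbs the reproduced intervals, shifts
#' every tap by a (negative-mean) asynchrony, and drops taps at random.
#'
#' @param prior `NULL` for a flat prior over the inner region, or a
#'   mixture table from [mixture_prior()].
#' @param sigma_s sensory noise sd, triangle units.
#' @param sigma_m motor noise sd per interval, ms.
#' @param mu_a,sigma_a mean and sd of the tap asynchrony, ms (negative
#'   mean: taps anticipate the click).
#' @param p_miss probability that a produced tap goes undetected.
#' @param posterior `"mean"` (deterministic attractor dynamics; default)
#'   or `"sample"` (posterior sampling).
#' @param bin,f resolution and inner fraction of the posterior grid.
#' @return an `observer_params` object (prior density cached on the grid).
#' @export
observer_params <- function(prior = NULL, sigma_s = 0.15, sigma_m = 15,
                            mu_a = -50, sigma_a = 20, p_miss = 0.05,
                            posterior = c("mean", "sample"),
                            bin = 0.006, f = 0.15) {
  posterior <- match.arg(posterior)
  stopifnot(sigma_s >= 0, sigma_m >= 0, sigma_a >= 0,
            p_miss >= 0, p_miss < 1)
  grid <- triangle_grid(bin = bin, f = f)
  if (is.null(prior)) {
    dens <- as.numeric(grid$inner)
  } else {
    mu <- project(as.matrix(prior[, c("p1", "p2", "p3")]))
    dens <- numeric(nrow(grid))
    for (k in seq_len(nrow(prior))) {
      S <- diag(prior$sd[k]^2, 2)
      dens <- dens + prior$weight[k] * gauss_on_grid(grid, mu[k, ], S)
    }
  }
  dens <- dens / sum(dens)
  structure(list(prior = prior, prior_grid = dens, grid = grid,
                 sigma_s = sigma_s, sigma_m = sigma_m, mu_a = mu_a,
                 sigma_a = sigma_a, p_miss = p_miss, posterior = posterior),
            class = "observer_params")
}

#' Perceive a stimulus through the Bayesian observer
#'
#' Adds isotropic sensory noise to the stimulus point, then returns the
#' posterior mean (or a posterior sample) of location under the observer's
#' prior, computed by quadrature on the analysis grid.
#'
#' @param xy stimulus point, triangle coordinates.
#' @param params an [observer_params()] object.
#' @return length-2 internal estimate, inside the triangle.
#' @export
perceive <- function(xy, params) {
  if (params$sigma_s == 0) return(as.numeric(xy))
  obs <- as.numeric(xy) + stats::rnorm(2, 0, params$sigma_s)
  g <- params$grid
  q <- ((g$x - obs[1])^2 + (g$y - obs[2])^2) / (2 * params$sigma_s^2)
  post <- params$prior_grid * exp(-(q - min(q)))
  s <- sum(post)
  if (s == 0) return(as.numeric(xy))
  post <- post / s
  if (params$posterior == "mean") {
    c(sum(post * g$x), sum(post * g$y))
  } else {
    i <- sample.int(nrow(g), 1L, prob = post)
    jitter <- (stats::runif(2) - 0.5) * attr(g, "bin")
    c(g$x[i], g$y[i]) + jitter
  }
}

#' Produce an onset stream from an internal estimate
#'
#' Builds the 31 stimulus click onsets from the presented pattern and the
#' synthetic taps: within each cycle the tap offsets follow the estimate's
#' intervals perturbed by motor noise (interval sum not renormalized),
#' each tap is shifted by an asynchrony draw, and taps are dropped
#' independently with probability `p_miss`.
#'
#' @param est internal estimate (triangle coordinates).
#' @param stimulus_pattern presented interval pattern, ms.
#' @param params an [observer_params()] object.
#' @param period cycle duration, ms.
#' @param repetitions pattern cycles.
#' @param t0 time of the first click, ms.
#' @return list with `stimulus_onsets` and `response_onsets` (ms).
#' @export
produce_taps <- function(est, stimulus_pattern, params, period = 2000,
                         repetitions = 10, t0 = 0) {
  stim <- pattern_onsets(stimulus_pattern, repetitions, t0 = t0)
  est_int <- unproject(est) * period
  n_taps <- 3L * repetitions + 1L
  motor <- matrix(stats::rnorm(3L * repetitions, 0, params$sigma_m),
                  nrow = repetitions)
  nominal <- numeric(n_taps)
  for (cyc in seq_len(repetitions)) {
    i1 <- est_int[1] + motor[cyc, 1]
    i2 <- est_int[2] + motor[cyc, 2]
    start <- t0 + (cyc - 1L) * period
    nominal[3L * (cyc - 1L) + 1:3] <- start + c(0, i1, i1 + i2)
  }
  nominal[n_taps] <- t0 + repetitions * period
  asyn <- stats::rnorm(n_taps, params$mu_a, params$sigma_a)
  miss <- stats::runif(n_taps) < params$p_miss
  taps <- sort((nominal + asyn)[!miss])
  list(stimulus_onsets = stim, response_onsets = taps)
}

#' Responder closure for the trial engine
#'
#' @param params an [observer_params()] object.
#' @param period cycle duration, ms.
#' @param repetitions pattern cycles per iteration.
#' @return function(stimulus_pattern, iteration) usable by [run_trial()].
#' @export
make_responder <- function(params, period = 2000, repetitions = 10) {
  function(stimulus, iteration) {
    xy <- project(normalize_pattern(stimulus))
    est <- perceive(xy, params)
    produce_taps(est, stimulus, params, period = period,
                 repetitions = repetitions)
  }
}

#' Simulate an iterated-reproduction dataset
#'
#' Samples uniform seeds from the inner region and runs the full protocol
#' (synthetic tapper -> onset preprocessing -> validity bookkeeping) for
#' each trial. Deterministic given the RNG state (use `set.seed()` or the
#' `seed` argument).
#'
#' @param params an [observer_params()] object.
#' @param n_trials number of trials.
#' @param period cycle duration, ms.
#' @param repetitions pattern cycles per iteration.
#' @param seed optional RNG seed.
#' @param ... passed to [run_trial()] (e.g. `n_iter`, `max_invalid`).
#' @return a `rhythm_dataset` (list of `trial_record`s).
#' @export
simulate_dataset <- function(params, n_trials, period = 2000,
                             repetitions = 10, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- attr(params$grid, "f")
  seeds <- sample_seed(n_trials, period = period,
                       min_interval = f * period)
  run_group(seeds, make_responder(params, period, repetitions),
            period = period, repetitions = repetitions, ...)
}

#' Directly simulate trial-level reproduction points
#'
#' Lightweight generator used for calibrating the statistical tests: trial
#' mean points are drawn from a mixture prior (or uniformly from the inner
#' region when `prior` is `NULL`) and each trial gets `reps` repetition
#' points scattered isotropically around its mean. This bypasses the
#' tapping/preprocessing stages, producing the `trial`/`x`/`y` table the
#' estimators consume.
#'
#' @param n_trials number of trials.
#' @param prior `NULL` (uniform over the inner region) or a
#'   [mixture_prior()] table.
#' @param reps repetition points per trial.
#' @param rep_sd within-trial scatter sd, triangle units.
#' @param f inner-region fraction.
#' @return data frame with columns `trial`, `x`, `y`.
#' @export
simulate_trial_points <- function(n_trials, prior = NULL, reps = 10,
                                  rep_sd = 0.01, f = 0.15) {
  if (is.null(prior)) {
    means <- project(f + (1 - 3 * f) * runif_simplex(n_trials))
  } else {
    comp <- sample.int(nrow(prior), n_trials, replace = TRUE,
                       prob = prior$weight)
    mu <- project(as.matrix(prior[, c("p1", "p2", "p3")]))
    means <- mu[comp, , drop = FALSE] +
      matrix(stats::rnorm(2 * n_trials, 0, prior$sd[comp]), ncol = 2)
  }
  data.frame(
    trial = rep(seq_len(n_trials), each = reps),
    x = rep(means[, 1], each = reps) + stats::rnorm(n_trials * reps, 0, rep_sd),
    y = rep(means[, 2], each = reps) + stats::rnorm(n_trials * reps, 0, rep_sd))
}
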