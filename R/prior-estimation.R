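#' Binned grid over the rhythm triangle
#'
#' Square bins of side `bin` (triangle units); bin centres falling inside
#' the full triangle are kept and flagged when inside the inner region.
#'
#' @param bin bin width (default 0.006, i.e. 12 ms of a 2,000 ms cycle;
#'   use 0.003 for display-resolution grids).
#' @param f inner-region minimum interval fraction.
#' @return a `triangle_grid`: data frame with bin centres `x`, `y` and
#'   logical `inner`; `bin` and `f` stored as attributes.
#' @export
triangle_grid <- function(bin = 0.006, f = 0.15) {
  xs <- seq(bin / 2, 1, by = bin)
  ys <- seq(bin / 2, sqrt(3) / 2, by = bin)
  g <- expand.grid(x = xs, y = ys)
  b <- barycentric(as.matrix(g))
  keep <- apply(b >= 0, 1, all)
  g <- g[keep, , drop = FALSE]
  g$inner <- in_inner_triangle(as.matrix(g[, c("x", "y")]), f = f)
  rownames(g) <- NULL
  structure(g, class = c("triangle_grid", "data.frame"), bin = bin, f = f)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(attr(a, "bin"), attr(b, "bin"))) &&
    nrow(a) == nrow(b) &&
    isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$y, b$y))
}

# Regularized per-trial kernel: empirical mean and covariance of the
# repetition points plus the gamma regularizer on the diagonal.
# gamma_mode "sd" adds (gamma_ms/period)^2 (gamma read as an sd);
# "raw" adds gamma_ms/period to the diagonal (the literal Sigma + gamma I).
#' Per-trial Gaussian kernel from fifth-iteration repetitions
#'
#' @param xy matrix of repetition points (triangle coordinates).
#' @param gamma_ms regularizer, ms.
#' @param period cycle duration, ms (converts gamma to triangle units).
#' @param gamma_mode `"sd"` (default) adds gamma squared in triangle units
#'   to the covariance diagonal; `"raw"` adds gamma in triangle units.
#' @return list with `mean` (length 2) and `cov` (2-by-2, positive
#'   definite).
#' @export
trial_kernel <- function(xy, gamma_ms = 15, period = 2000,
                         gamma_mode = c("sd", "raw")) {
  gamma_mode <- match.arg(gamma_mode)
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  if (nrow(xy) == 0L) stop("no repetition points")
  mu <- colMeans(xy)
  S <- if (nrow(xy) > 1L) stats::cov(xy) else matrix(0, 2, 2)
  g <- gamma_ms / period
  reg <- if (gamma_mode == "sd") g^2 else g
  list(mean = as.numeric(mu), cov = S + diag(reg, 2))
}

# Density of N(mu, S) at the grid centres (vector over bins).
gauss_on_grid <- function(grid, mu, S) {
  dx <- grid$x - mu[1]
  dy <- grid$y - mu[2]
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  inv <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2) / det
  q <- inv[1, 1] * dx^2 + 2 * inv[1, 2] * dx * dy + inv[2, 2] * dy^2
  exp(-q / 2) / (2 * pi * sqrt(det))
}

#' Kernel matrix of a dataset on a grid
#'
#' One row per trial: the trial's regularized Gaussian kernel evaluated at
#' every bin centre. Averaging subsets of rows and renormalizing yields
#' the prior of any trial subset, which is what the split-half bootstrap
#' procedures reuse.
#'
#' @param points data frame of repetition points with columns `trial`,
#'   `x`, `y` (several rows per trial).
#' @param grid a [triangle_grid()].
#' @inheritParams trial_kernel
#' @param f trials whose mean point lies outside the inner region (all
#'   proportions > `f`) are excluded before kernel construction.
#' @return list with `K` (n_trials-by-n_bins matrix), `trials` (ids),
#'   `means` (trial mean points) and `grid`.
#' @export
kernel_matrix <- function(points, grid = triangle_grid(),
                          gamma_ms = 15, period = 2000,
                          gamma_mode = c("sd", "raw"),
                          f = attr(grid, "f")) {
  gamma_mode <- match.arg(gamma_mode)
  stopifnot(all(c("trial", "x", "y") %in% names(points)))
  ids <- unique(points$trial)
  mu_all <- t(vapply(ids, function(id) {
    colMeans(as.matrix(points[points$trial == id, c("x", "y")]))
  }, numeric(2)))
  keep <- in_inner_triangle(mu_all, f = f)
  ids <- ids[keep]
  if (length(ids) == 0L) stop("no usable trials inside the inner region")
  K <- matrix(0, nrow = length(ids), ncol = nrow(grid))
  for (i in seq_along(ids)) {
    xy <- as.matrix(points[points$trial == ids[i], c("x", "y")])
    k <- trial_kernel(xy, gamma_ms = gamma_ms, period = period,
                      gamma_mode = gamma_mode)
    K[i, ] <- gauss_on_grid(grid, k$mean, k$cov)
  }
  list(K = K, trials = ids, means = mu_all[keep, , drop = FALSE],
       grid = grid)
}

#' Prior from (a subset of) a kernel matrix
#'
#' @param km result of [kernel_matrix()].
#' @param idx trial rows to average (default all).
#' @return a `discrete_prior`.
#' @export
prior_from_kernels <- function(km, idx = seq_len(nrow(km$K))) {
  p <- if (length(idx) == 1L) km$K[idx, ] else colMeans(km$K[idx, , drop = FALSE])
  new_discrete_prior(p / sum(p), km$grid, n_trials = length(idx))
}

new_discrete_prior <- function(p, grid, n_trials = NA_integer_) {
  structure(list(p = as.numeric(p), grid = grid,
                 bin = attr(grid, "bin"), f = attr(grid, "f"),
                 n_trials = n_trials),
            class = "discrete_prior")
}

#' Kernel density estimate of the rhythm prior
#'
#' Averages one regularized Gaussian kernel per trial (mean and covariance
#' from the fifth-iteration repetitions) over the grid and renormalizes.
#' Trials whose mean reproduction falls outside the inner region are
#' excluded first.
#'
#' @inheritParams kernel_matrix
#' @return a `discrete_prior`: list with probabilities `p` (summing to 1
#'   over the grid), the `grid`, `bin`, `f` and `n_trials`.
#' @export
estimate_prior <- function(points, grid = triangle_grid(),
                           gamma_ms = 15, period = 2000,
                           gamma_mode = c("sd", "raw"),
                           f = attr(grid, "f")) {
  km <- kernel_matrix(points, grid = grid, gamma_ms = gamma_ms,
                      period = period, gamma_mode = gamma_mode, f = f)
  prior_from_kernels(km)
}

#' @export
print.discrete_prior <- function(x, ...) {
  cat(sprintf("discrete prior: %d bins (bin %.4g, f %.3g), %s trials\n",
              length(x$p), x$bin, x$f,
              ifelse(is.na(x$n_trials), "?", x$n_trials)))
  invisible(x)
}

#' Density relative to the uniform distribution over the inner region
#'
#' Pointwise ratio P(x)/U(x), with U uniform over the inner-region bins.
#' Outside the inner region the ratio is `NA` (U is 0 there). Clipping is
#' a display option only; it never alters the prior's probabilities.
#'
#' @param prior a `discrete_prior`.
#' @param clip optional ceiling for the returned ratios.
#' @return numeric vector of ratios, one per grid bin.
#' @export
normalize_vs_uniform <- function(prior, clip = NULL) {
  inner <- prior$grid$inner
  u <- 1 / sum(inner)
  ratio <- rep(NA_real_, length(prior$p))
  ratio[inner] <- prior$p[inner] / u
  if (!is.null(clip)) ratio[!is.na(ratio) & ratio > clip] <- clip
  ratio
}

#' Write / read a discrete prior as TSV
#'
#' A small `# key=value` header (bin, f, n_trials) followed by columns
#' bin_x, bin_y, probability, inner_flag. Round-trips exactly.
#'
#' @param prior a `discrete_prior`.
#' @param path file path.
#' @return `read_prior` returns the `discrete_prior`.
#' @export
write_prior <- function(prior, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin=%.17g", prior$bin),
               sprintf("# f=%.17g", prior$f),
               sprintf("# n_trials=%d", prior$n_trials),
               "bin_x\tbin_y\tprobability\tinner_flag"), con)
  writeLines(sprintf("%.17g\t%.17g\t%.17g\t%d",
                     prior$grid$x, prior$grid$y, prior$p,
                     as.integer(prior$grid$inner)), con)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    as.numeric(sub(sprintf("^# %s=", key), "",
                   grep(sprintf("^# %s=", key), hdr, value = TRUE)))
  }
  body <- utils::read.table(text = lines[!grepl("^# ", lines)],
                            header = TRUE, sep = "\t")
  grid <- data.frame(x = body$bin_x, y = body$bin_y,
                     inner = as.logical(body$inner_flag))
  grid <- structure(grid, class = c("triangle_grid", "data.frame"),
                    bin = get("bin"), f = get("f"))
  new_discrete_prior(body$probability, grid, n_trials = get("n_trials"))
}

#' Fifth-iteration repetition points of a dataset
#'
#' Extracts, for every trial with a valid iteration of the requested
#' index, the per-repetition interval triples (missing taps already
#' imputed) projected to triangle coordinates.
#'
#' @param trials a list of `trial_record`s (e.g. from [run_group()]).
#' @param iteration which iteration to use (default 5, the final one).
#' @param period cycle duration, ms.
#' @return data frame with columns `trial`, `x`, `y` (one row per
#'   repetition).
#' @export
dataset_points <- function(trials, iteration = 5, period = 2000) {
  rows <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    for (it in tr$iterations) {
      if (it$index == iteration && it$record$valid) {
        ri <- it$record$rep_intervals
        ok <- apply(ri > 0, 1, all)
        if (!any(ok)) next
        xy <- project(normalize_pattern(ri[ok, , drop = FALSE]))
        rows[[length(rows) + 1L]] <-
          data.frame(trial = i, x = xy[, 1], y = xy[, 2])
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(trial = integer(0), x = numeric(0), y = numeric(0)))
  }
  do.call(rbind, rows)
}
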