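#' Metric multidimensional scaling of a group distance matrix
#'
#' Stress-majorization (SMACOF/Guttman transform) with classical-scaling
#' initialization; minimizes metric stress-1. Orientation is arbitrary
#' (solutions are defined up to rotation and reflection).
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal
#'   (e.g. pairwise JSDs between group priors).
#' @param dims embedding dimension.
#' @param max_iter,tol majorization iterations and relative stress
#'   tolerance.
#' @return a `group_embedding`: list with `points` (n-by-dims), `stress`
#'   (stress-1), `method`.
#' @export
mds_embedding <- function(D, dims = 2, max_iter = 500, tol = 1e-10) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0) || any(D < 0)) {
    stop("distance matrix must be symmetric, nonnegative, zero diagonal")
  }
  n <- nrow(D)
  X <- stats::cmdscale(D, k = min(dims, n - 1))
  if (ncol(X) < dims) {
    X <- cbind(X, matrix(0, n, dims - ncol(X)))
  }
  dist_config <- function(X) as.matrix(stats::dist(X))
  stress1 <- function(X) {
    d <- dist_config(X)
    up <- upper.tri(d)
    sqrt(sum((D[up] - d[up])^2) / sum(d[up]^2))
  }
  s_old <- stress1(X)
  for (it in seq_len(max_iter)) {
    d <- dist_config(X)
    ratio <- ifelse(d > 0, D / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    s_new <- stress1(X)
    if (abs(s_old - s_new) < tol * (1 + s_old)) break
    s_old <- s_new
  }
  structure(list(points = X, stress = stress1(X), method = "smacof"),
            class = "group_embedding")
}

#' Principal components of a set of gridded priors
#'
#' Treats each prior's probability grid as a feature vector (one feature
#' per bin), centres features and computes the SVD. Component signs are
#' arbitrary.
#'
#' @param priors list of `discrete_prior`s on a common grid.
#' @return list with `projections` (groups-by-components scores),
#'   `components` (bins-by-components loadings), `variance_share`,
#'   `center` (feature means).
#' @export
pca_on_grids <- function(priors) {
  if (length(priors) < 2L) stop("need at least 2 priors")
  g0 <- priors[[1]]$grid
  for (pr in priors) {
    if (!same_grid(pr$grid, g0)) stop("priors are on different grids")
  }
  M <- do.call(rbind, lapply(priors, function(pr) pr$p))
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  list(projections = pc$x, components = pc$rotation,
       variance_share = pc$sdev^2 / sum(pc$sdev^2),
       center = pc$center)
}

# Rank-based inverse normal transform.
rin <- function(v) stats::qnorm((rank(v) - 0.5) / length(v))

#' Correlation of an embedding dimension with category weights
#'
#' Pearson correlation across groups, with a confidence interval and
#' p-value computed on rank-based inverse-normal (RIN) transformed
#' variables via Fisher's z (robust to non-normal weight distributions);
#' the p-value can be Bonferroni-scaled.
#'
#' @param projection numeric vector (one value per group).
#' @param weights numeric vector of class weights (same groups).
#' @param conf confidence level.
#' @param bonferroni multiplicative correction factor for the p-value.
#' @return list with `r` (raw Pearson), `r_rin`, `ci` (RIN-based), and
#'   `p_value`.
#' @export
correlate_dims_with_weights <- function(projection, weights, conf = 0.95,
                                        bonferroni = 1) {
  stopifnot(length(projection) == length(weights))
  if (stats::sd(projection) == 0 || stats::sd(weights) == 0) {
    warning("constant vector; correlation undefined")
    return(list(r = NA_real_, r_rin = NA_real_, ci = c(NA_real_, NA_real_),
                p_value = NA_real_))
  }
  n <- length(projection)
  r <- stats::cor(projection, weights)
  a <- rin(projection)
  b <- rin(weights)
  r2 <- stats::cor(a, b)
  z <- atanh(r2)
  se <- 1 / sqrt(n - 3)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(c(z - zc * se, z + zc * se))
  p <- min(1, stats::cor.test(a, b)$p.value * bonferroni)
  list(r = r, r_rin = r2, ci = ci, p_value = p)
}
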