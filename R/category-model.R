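# Bivariate normal density of points at (mu, S); returns a vector.
dmvnorm2 <- function(xy, mu, S) {
  dx <- xy[, 1] - mu[1]
  dy <- xy[, 2] - mu[2]
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  inv <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2) / det
  q <- inv[1, 1] * dx^2 + 2 * inv[1, 2] * dx * dy + inv[2, 2] * dy^2
  exp(-q / 2) / (2 * pi * sqrt(det))
}

# Project a mean onto the closed ball of radius r around its anchor.
project_mean <- function(mu, anchor, r) {
  d <- sqrt(sum((mu - anchor)^2))
  if (d <= r) mu else anchor + (mu - anchor) * (r / d)
}

# Eigenvalue truncation and aspect clamp of a covariance matrix:
# lambda' = min(lambda, dmin/2), then each eigenvalue is clamped into
# [A * sum, (1 - A) * sum] of the truncated pair; eigenvectors preserved.
clamp_covariance <- function(S, dmin, A = 0.2) {
  e <- eigen(S, symmetric = TRUE)
  lam <- pmin(e$values, dmin / 2)
  tot <- sum(lam)
  lam2 <- pmin(pmax(lam, A * tot), (1 - A) * tot)
  V <- e$vectors
  V %*% diag(lam2, 2) %*% t(V)
}

#' Constrained Gaussian mixture model anchored at rhythm categories
#'
#' Fits a K-component Gaussian mixture by expectation-maximization with
#' one component per integer-ratio category. After every M-step the
#' parameters are projected back into the constraint set that keeps the
#' component-to-category correspondence interpretable: each mean stays
#' within half the minimal inter-category distance (d_min/2) of its
#' anchor, covariance eigenvalues are truncated at d_min/2, and the
#' eigenvalue pair is clamped to an aspect band `[A, 1-A]` of its sum.
#' Components are initialized at the anchors.
#'
#' @param points n-by-2 matrix (or data frame with x, y) of fifth-iteration
#'   trial points in triangle coordinates.
#' @param anchors a `ratio_set` (default [omega22()]).
#' @param A aspect-ratio constant (default 1/5).
#' @param tol convergence threshold on the change in total log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param constrain set `FALSE` for an unconstrained EM from the same
#'   initialization (used for the integerness null).
#' @param init_sd initial isotropic component sd, triangle units
#'   (default d_min/4).
#' @return a `rhythm_gmm`: list with `anchors`, `means` (K-by-2), `covs`
#'   (2-by-2-by-K), `weights`, `d_min`, `A`, `loglik`, `n_iter`,
#'   `converged`.
#' @export
fit_constrained_gmm <- function(points, anchors = omega22(), A = 0.2,
                                tol = 1e-6, max_iter = 1000,
                                constrain = TRUE, init_sd = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("no points to fit")
  K <- nrow(anchors)
  n <- nrow(points)
  anchor_xy <- cbind(anchors$x, anchors$y)
  dmin <- ratio_set_dmin(anchors)
  if (is.null(init_sd)) init_sd <- dmin / 4
  means <- anchor_xy
  covs <- array(rep(diag(init_sd^2, 2), K), dim = c(2, 2, K))
  w <- rep(1 / K, K)
  loglik <- -Inf
  converged <- FALSE
  it <- 0L
  dens <- matrix(0, n, K)
  for (it in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      dens[, k] <- w[k] * dmvnorm2(points, means[k, ], covs[, , k])
    }
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_))
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
    resp <- dens / rowsum_
    nk <- colSums(resp)
    w_new <- nk / n
    for (k in seq_len(K)) {
      if (nk[k] < 1e-12) {
        # degenerate component: re-anchor it
        means[k, ] <- anchor_xy[k, ]
        covs[, , k] <- diag(init_sd^2, 2)
        next
      }
      mu <- colSums(resp[, k] * points) / nk[k]
      dxy <- sweep(points, 2, mu)
      S <- crossprod(dxy * sqrt(resp[, k])) / nk[k]
      S <- S + diag(1e-12, 2)
      if (constrain) {
        mu <- project_mean(mu, anchor_xy[k, ], dmin / 2)
        S <- clamp_covariance(S, dmin, A)
      }
      means[k, ] <- mu
      covs[, , k] <- S
    }
    w <- w_new
  }
  structure(list(anchors = anchors, means = means, covs = covs,
                 weights = w, d_min = dmin, A = A, loglik = loglik,
                 n_iter = it, converged = converged, n = n),
            class = "rhythm_gmm")
}

#' @export
print.rhythm_gmm <- function(x, ...) {
  cat(sprintf("constrained GMM: %d components, n = %d, loglik = %.4f%s\n",
              length(x$weights), x$n, x$loglik,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Mixture density of a fitted model
#'
#' @param model a `rhythm_gmm`.
#' @param xy points (n-by-2 matrix or data frame with x, y).
#' @return density values.
#' @export
gmm_density <- function(model, xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, c("x", "y")])
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  out <- numeric(nrow(xy))
  for (k in seq_along(model$weights)) {
    out <- out + model$weights[k] *
      dmvnorm2(xy, model$means[k, ], model$covs[, , k])
  }
  out
}

#' Cyclic-class weights of a fitted mixture
#'
#' Averages the component weight across the three cyclic permutations of
#' each category; the isochronous 1:1:1 category has a single component
#' whose weight is used as is.
#'
#' @param model a `rhythm_gmm`.
#' @return named numeric vector, one weight per cyclic class.
#' @export
category_weights <- function(model) {
  vapply(split(model$weights, model$anchors$class), mean, numeric(1))
}

#' Variance of the prior explained by the mixture
#'
#' Squared Pearson correlation between the gridded kernel density estimate
#' and the model density evaluated on the same grid.
#'
#' @param model a `rhythm_gmm`.
#' @param prior a `discrete_prior`.
#' @return fraction in [0, 1]; `NA` with a warning when either grid
#'   vector has zero variance.
#' @export
explained_variance <- function(model, prior) {
  q <- gmm_density(model, prior$grid)
  if (stats::sd(q) == 0 || stats::sd(prior$p) == 0) {
    warning("zero-variance density grid; explained variance undefined")
    return(NA_real_)
  }
  stats::cor(q, prior$p)^2
}

#' Predict the perceived category of rhythm-triangle points
#'
#' Selects, at each point, the mixture component with the highest value of
#' the exponent-weighted density U_i(x) in which the component weight is
#' raised to `gamma_cat` (categorical judgements sharpen the prior) after
#' the 1:1:1 weight is boosted by `iso_boost`. Ties go to the component
#' with the nearer mean.
#'
#' @param model a `rhythm_gmm`.
#' @param xy points to classify.
#' @param gamma_cat weight exponent (> 1 favours high-probability
#'   categories).
#' @param iso_boost multiplicative boost of the isochronous 1:1:1 weight.
#' @param boost_first apply the boost before exponentiation (default; set
#'   `FALSE` to boost after).
#' @return integer vector of anchor row indices (use the model's
#'   `anchors` to translate to ratios).
#' @export
predict_category <- function(model, xy, gamma_cat = 7, iso_boost = 3,
                             boost_first = TRUE) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, c("x", "y")])
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  w <- model$weights
  iso <- which(model$anchors$class == "111")
  if (boost_first) {
    w[iso] <- w[iso] * iso_boost
    w <- w^gamma_cat
  } else {
    w <- w^gamma_cat
    w[iso] <- w[iso] * iso_boost
  }
  K <- length(w)
  U <- matrix(0, nrow(xy), K)
  for (k in seq_len(K)) {
    U[, k] <- w[k] * dmvnorm2(xy, model$means[k, ], model$covs[, , k])
  }
  best <- max.col(U, ties.method = "first")
  # break exact ties toward the nearer component mean
  for (i in seq_len(nrow(xy))) {
    tied <- which(U[i, ] == U[i, best[i]])
    if (length(tied) > 1L) {
      d2 <- (model$means[tied, 1] - xy[i, 1])^2 +
        (model$means[tied, 2] - xy[i, 2])^2
      best[i] <- tied[which.min(d2)]
    }
  }
  best
}

#' Mean distance between two category maps
#'
#' Categories are compared as proportion triples; the score is the mean
#' Euclidean distance in the three-dimensional interval-ratio space
#' between the predicted and reference category at each evaluation point.
#'
#' @param predicted,reference n-by-3 matrices of category proportion
#'   triples, aligned by evaluation point.
#' @return mean L2 distance (dimensionless).
#' @export
category_map_distance <- function(predicted, reference) {
  predicted <- as.matrix(predicted)
  reference <- as.matrix(reference)
  stopifnot(ncol(predicted) == 3L, ncol(reference) == 3L,
            nrow(predicted) == nrow(reference))
  if (anyNA(predicted) || anyNA(reference)) {
    stop("missing category assignment at an evaluation point")
  }
  mean(sqrt(rowSums((predicted - reference)^2)))
}

#' Reference category map from labelled categorization judgements
#'
#' Interpolates per-category choice counts over the triangle with an
#' isotropic Gaussian kernel and assigns each evaluation point the
#' category with the largest interpolated weight (the format of classic
#' rhythm categorization experiments: stimulus point, notated category,
#' choice count).
#'
#' @param table data frame with stimulus proportions `s1`, `s2`, `s3`,
#'   chosen-category proportions `c1`, `c2`, `c3` and `count`.
#' @param eval_xy n-by-2 matrix of evaluation points (triangle
#'   coordinates).
#' @param kernel_width isotropic kernel sd, triangle units.
#' @return n-by-3 matrix of modal category proportion triples.
#' @export
build_reference_map <- function(table, eval_xy, kernel_width = 0.03) {
  stopifnot(all(c("s1", "s2", "s3", "c1", "c2", "c3", "count") %in%
                  names(table)))
  if (nrow(table) == 0L) stop("empty categorization table")
  if (is.null(dim(eval_xy))) eval_xy <- matrix(eval_xy, ncol = 2)
  stim_xy <- project(as.matrix(table[, c("s1", "s2", "s3")]))
  key <- paste(table$c1, table$c2, table$c3)
  cats <- !duplicated(key)
  cat_props <- as.matrix(table[cats, c("c1", "c2", "c3")])
  ukey <- key[cats]
  W <- matrix(0, nrow(eval_xy), length(ukey))
  for (j in seq_along(ukey)) {
    rows <- which(key == ukey[j])
    for (r in rows) {
      d2 <- (eval_xy[, 1] - stim_xy[r, 1])^2 +
        (eval_xy[, 2] - stim_xy[r, 2])^2
      W[, j] <- W[, j] + table$count[r] * exp(-d2 / (2 * kernel_width^2))
    }
  }
  cat_props[max.col(W, ties.method = "first"), , drop = FALSE]
}
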