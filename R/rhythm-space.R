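# Vertices of the equilateral rhythm triangle (side length 1).
triangle_vertices <- function() {
  matrix(c(0, 0,
           1, 0,
           0.5, sqrt(3) / 2),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("P1", "P2", "P3"), c("x", "y")))
}

#' Normalize a three-interval pattern to proportions
#'
#' Divides the three inter-onset intervals of a rhythm cycle by their sum,
#' giving the proportion of the cycle occupied by each interval.
#'
#' @param p numeric vector of length 3 (intervals in ms), or an n-by-3
#'   matrix of patterns (one per row).
#' @return a proportion triple summing to 1 (or an n-by-3 matrix of them).
#' @examples
#' normalize_pattern(c(500, 500, 1000))
#' @export
normalize_pattern <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("pattern must have exactly 3 intervals")
    if (any(!is.finite(p)) || any(p <= 0)) {
      stop("invalid pattern: intervals must be positive and finite")
    }
    return(p / sum(p))
  }
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("pattern matrix must have 3 columns")
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("invalid pattern: intervals must be positive and finite")
  }
  p / rowSums(p)
}

#' Project proportion triples onto the rhythm triangle
#'
#' Maps a normalized three-interval rhythm (p1, p2, p3) to the point
#' p1*P1 + p2*P2 + p3*P3 of the equilateral triangle with vertices
#' P1 = (0,0), P2 = (1,0), P3 = (1/2, sqrt(3)/2).
#'
#' @param p proportion triple, or an n-by-3 matrix of triples.
#' @return numeric xy coordinates (length-2 vector or n-by-2 matrix).
#' @export
project <- function(p) {
  v <- triangle_vertices()
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3L)
    return(as.numeric(p %*% v))
  }
  p <- as.matrix(p)
  stopifnot(ncol(p) == 3L)
  out <- p %*% v
  colnames(out) <- c("x", "y")
  out
}

# Barycentric coordinates of xy points with respect to the triangle.
# Returns an n-by-3 matrix; no domain check.
barycentric <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  xy <- as.matrix(xy)
  p3 <- xy[, 2] * 2 / sqrt(3)
  p2 <- xy[, 1] - xy[, 2] / sqrt(3)
  cbind(p1 = 1 - p2 - p3, p2 = p2, p3 = p3)
}

#' Invert the triangle projection
#'
#' Recovers the proportion triple from coordinates in the equilateral
#' triangle. Inverse of [project()] for points inside the triangle.
#'
#' @param xy length-2 coordinate vector or n-by-2 matrix.
#' @param tol points whose barycentric coordinates are below `-tol` are
#'   rejected as outside the triangle.
#' @return proportion triple(s) with tiny negative values snapped to 0.
#' @export
unproject <- function(xy, tol = 1e-9) {
  single <- is.null(dim(xy))
  b <- barycentric(xy)
  if (any(b < -tol)) stop("point outside the rhythm triangle")
  b[b < 0] <- 0
  b <- b / rowSums(b)
  if (single) as.numeric(b) else b
}

#' Vertices of the inner (producible) triangular region
#'
#' The region of rhythms whose smallest interval exceeds the fraction `f`
#' of the cycle; seeds are sampled from it and fifth-iteration points
#' outside it are excluded from the prior.
#'
#' @param f minimum interval as a fraction of the cycle (default 0.15,
#'   i.e. 300 ms of a 2,000 ms cycle).
#' @return 3-by-2 matrix of xy vertices.
#' @export
inner_triangle_vertices <- function(f = 0.15) {
  matrix(c(1.5 * f, sqrt(3) / 2 * f,
           1 - 1.5 * f, sqrt(3) / 2 * f,
           0.5, sqrt(3) / 2 * (1 - 2 * f)),
         nrow = 3, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

#' Test membership in the inner triangular region
#'
#' A point is inside the inner region iff all three recovered interval
#' proportions are strictly greater than `f` (matching the strict seed
#' constraint: all seed intervals > 300 ms at the default tempo).
#'
#' @param xy length-2 vector or n-by-2 matrix of triangle coordinates.
#' @param f minimum interval fraction.
#' @return logical vector.
#' @details Proportions within 1e-12 of `f` count as on the boundary and
#'   are excluded (keeps the strict rule deterministic under floating
#'   point round-off).
#' @export
in_inner_triangle <- function(xy, f = 0.15) {
  b <- barycentric(xy)
  as.logical(apply(b > f + 1e-12, 1, all))
}

rotations3 <- function(v) {
  list(v, c(v[2], v[3], v[1]), c(v[3], v[1], v[2]))
}

gcd3 <- function(v) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  g(g(v[1], v[2]), v[3])
}

# Lexicographically smallest cyclic rotation, used as the class label.
canonical_rotation <- function(v) {
  rots <- do.call(rbind, rotations3(v))
  o <- order(rots[, 1], rots[, 2], rots[, 3])
  rots[o[1], ]
}

#' Enumerate small-integer-ratio rhythm categories
#'
#' All ordered integer triples over 1..`max_int`, deduplicated as exact
#' rational proportions (triples equal after dividing by their gcd are the
#' same rhythm) and filtered so that the smallest proportion is at least
#' `min_fraction`. With the defaults this yields the 22 unique ratios over
#' the integers 1-3 whose intervals all exceed 15% of the cycle.
#'
#' @param max_int largest integer allowed in a ratio.
#' @param min_fraction smallest admissible interval proportion.
#' @return a `ratio_set`: data frame with integer columns `a`, `b`, `c`
#'   (reduced ratio), proportions `p1`, `p2`, `p3`, triangle coordinates
#'   `x`, `y`, a `ratio` label such as "3:3:2" and a cyclic-class label
#'   `class` (digits of the lexicographically smallest rotation).
#' @examples
#' nrow(enumerate_integer_ratios())  # 22
#' @export
enumerate_integer_ratios <- function(max_int = 3, min_fraction = 0.15) {
  stopifnot(max_int >= 1, min_fraction >= 0, min_fraction < 1 / 3)
  g <- as.matrix(expand.grid(a = seq_len(max_int), b = seq_len(max_int),
                             c = seq_len(max_int)))
  red <- t(apply(g, 1, function(v) v / gcd3(v)))
  keep <- !duplicated(red)
  red <- red[keep, , drop = FALSE]
  props <- red / rowSums(red)
  ok <- apply(props, 1, min) >= min_fraction
  red <- red[ok, , drop = FALSE]
  props <- props[ok, , drop = FALSE]
  xy <- project(props)
  cls <- apply(red, 1, function(v) {
    paste(canonical_rotation(v), collapse = "")
  })
  out <- data.frame(a = red[, 1], b = red[, 2], c = red[, 3],
                    p1 = props[, 1], p2 = props[, 2], p3 = props[, 3],
                    x = xy[, 1], y = xy[, 2],
                    ratio = apply(red, 1, paste, collapse = ":"),
                    class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$class, out$ratio), ]
  rownames(out) <- NULL
  class(out) <- c("ratio_set", "data.frame")
  attr(out, "min_fraction") <- min_fraction
  out
}

#' The 22-category set over the integers 1-3
#' @param min_fraction smallest admissible interval proportion.
#' @return a `ratio_set` with 22 members in 8 cyclic classes.
#' @export
omega22 <- function(min_fraction = 0.15) {
  enumerate_integer_ratios(3, min_fraction)
}

#' The 25-category set: omega22 plus the rotations of 7:2:3
#'
#' Extension used for groups whose repertoire features the 7:2:3 timeline
#' rhythm; adds 2:3:7, 7:2:3 and 3:7:2 as a ninth cyclic class.
#'
#' @param min_fraction smallest admissible interval proportion for the base
#'   1-3 set (the 7:2:3 rotations are always included).
#' @return a `ratio_set` with 25 members in 9 cyclic classes.
#' @export
omega25 <- function(min_fraction = 0.15) {
  base <- omega22(min_fraction)
  extra <- do.call(rbind, rotations3(c(7, 2, 3)))
  props <- extra / rowSums(extra)
  xy <- project(props)
  add <- data.frame(a = extra[, 1], b = extra[, 2], c = extra[, 3],
                    p1 = props[, 1], p2 = props[, 2], p3 = props[, 3],
                    x = xy[, 1], y = xy[, 2],
                    ratio = apply(extra, 1, paste, collapse = ":"),
                    class = apply(extra, 1, function(v) {
                      paste(canonical_rotation(v), collapse = "")
                    }),
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(base), add)
  out <- out[order(out$class, out$ratio), ]
  rownames(out) <- NULL
  class(out) <- c("ratio_set", "data.frame")
  attr(out, "min_fraction") <- min_fraction
  out
}

#' Partition a ratio set into cyclic-permutation classes
#'
#' @param rset a `ratio_set`.
#' @return named list of integer row-index vectors, one per class.
#' @export
cyclic_classes <- function(rset) {
  split(seq_len(nrow(rset)), rset$class)
}

#' Minimum pairwise distance within a ratio set
#'
#' Smallest Euclidean distance between distinct members after projection
#' to the triangle; the unit that scales the mixture-model constraints.
#'
#' @param rset a `ratio_set`.
#' @return a single distance (triangle units).
#' @export
ratio_set_dmin <- function(rset) {
  xy <- cbind(rset$x, rset$y)
  min(stats::dist(xy))
}

#' Distance from points to the nearest integer-ratio rhythm
#'
#' @param xy length-2 vector or n-by-2 matrix of triangle coordinates.
#' @param rset a `ratio_set` (or any data frame with `x`, `y` columns).
#' @return data frame with the Euclidean `distance` to, and row index
#'   `nearest` of, the closest member.
#' @export
min_distance_to_set <- function(xy, rset) {
  if (nrow(rset) == 0L) stop("empty ratio set")
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  xy <- as.matrix(xy)
  sx <- rset$x
  sy <- rset$y
  d2 <- outer(xy[, 1], sx, "-")^2 + outer(xy[, 2], sy, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  data.frame(distance = sqrt(d2[cbind(seq_len(nrow(xy)), nearest)]),
             nearest = nearest)
}

# Uniform draws from the unit 2-simplex via sorted-uniform gaps.
runif_simplex <- function(n) {
  u <- matrix(stats::runif(2 * n), ncol = 2)
  lo <- pmin(u[, 1], u[, 2])
  hi <- pmax(u[, 1], u[, 2])
  cbind(lo, hi - lo, 1 - hi)
}

#' Sample seed rhythms uniformly from the inner region
#'
#' Draws interval patterns uniformly over the shrunken simplex of rhythms
#' whose intervals all exceed `min_interval`, by an affine map of a uniform
#' simplex draw (no rejection, so the draw count per seed is fixed and the
#' output is deterministic per RNG state).
#'
#' @param n number of seeds.
#' @param period cycle duration in ms.
#' @param min_interval smallest allowed interval in ms.
#' @return n-by-3 matrix of interval patterns (ms) summing to `period`.
#' @export
sample_seed <- function(n = 1, period = 2000, min_interval = 300) {
  if (3 * min_interval >= period) {
    stop("infeasible constraint: 3 * min_interval must be < period")
  }
  f <- min_interval / period
  q <- runif_simplex(n)
  p <- f + (1 - 3 * f) * q
  unname(p * period)
}
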