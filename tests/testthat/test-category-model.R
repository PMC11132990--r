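test_that("a single tight cluster takes nearly all mixture weight", {
  o22 <- omega22()
  set.seed(71)
  ctr <- project(rep(1 / 3, 3))
  pts <- cbind(ctr[1] + stats::rnorm(150, 0, 0.004),
               ctr[2] + stats::rnorm(150, 0, 0.004))
  gm <- fit_constrained_gmm(pts, o22)
  w111 <- gm$weights[gm$anchors$ratio == "1:1:1"]
  expect_gte(w111, 0.99)
})

test_that("anchor-proportioned clusters recover their weights", {
  an <- separated_anchors()
  set.seed(72)
  n <- c(250, 150, 100)   # 0.5 / 0.3 / 0.2
  pts <- do.call(rbind, lapply(1:3, function(k) {
    MASS::mvrnorm(n[k], c(an$x[k], an$y[k]), diag(1e-4, 2))
  }))
  gm <- fit_constrained_gmm(pts, an)
  expect_equal(gm$weights, c(0.5, 0.3, 0.2), tolerance = 0.05,
               ignore_attr = TRUE)
  # brute-force responsibility oracle on a subset: with tight clusters,
  # each point's responsibility concentrates on its generating component
  sub <- pts[c(1, 260, 420), ]
  dens <- sapply(1:3, function(k) {
    gm$weights[k] * rhythmprior:::dmvnorm2(sub, gm$means[k, ],
                                           gm$covs[, , k])
  })
  expect_equal(max.col(dens), 1:3)
})

test_that("every fit satisfies the constraint contract", {
  # scattered data force the constraints to bind
  set.seed(73)
  pts <- rhythmprior:::runif_triangle(300, f = 0.15)
  o22 <- omega22()
  gm <- fit_constrained_gmm(pts, o22)
  shift <- sqrt(rowSums((gm$means - cbind(o22$x, o22$y))^2))
  expect_true(all(shift <= gm$d_min / 2 + 1e-12))
  for (k in 1:22) {
    lam <- eigen(gm$covs[, , k], symmetric = TRUE)$values
    expect_true(all(lam <= gm$d_min / 2 + 1e-12))
    expect_true(all(lam / sum(lam) >= 0.2 - 1e-9))
    expect_true(all(lam / sum(lam) <= 0.8 + 1e-9))
  }
  expect_equal(sum(gm$weights), 1, tolerance = 1e-9)
})

test_that("constraint projections are idempotent", {
  S <- matrix(c(4e-3, 1e-3, 1e-3, 2e-4), 2)
  dmin <- 0.0433
  once <- rhythmprior:::clamp_covariance(S, dmin, 0.2)
  twice <- rhythmprior:::clamp_covariance(once, dmin, 0.2)
  expect_equal(once, twice, tolerance = 1e-12)
  mu <- c(0.9, 0.1)
  anchor <- c(0.5, 0.3)
  p1 <- rhythmprior:::project_mean(mu, anchor, dmin / 2)
  p2 <- rhythmprior:::project_mean(p1, anchor, dmin / 2)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("EM with inactive constraints matches the unconstrained oracle", {
  suppressMessages(library(mclust))
  an <- separated_anchors()
  set.seed(74)
  pts <- rbind(MASS::mvrnorm(20, c(an$x[1], an$y[1]), diag(25e-6, 2)),
               MASS::mvrnorm(15, c(an$x[2], an$y[2]), diag(25e-6, 2)),
               MASS::mvrnorm(15, c(an$x[3], an$y[3]), diag(25e-6, 2)))
  gm <- fit_constrained_gmm(pts, an, tol = 1e-12, max_iter = 5000)
  mc <- mclust::Mclust(pts, G = 3, modelNames = "VVV", verbose = FALSE,
                       control = mclust::emControl(tol = c(1e-12, 1e-12)))
  expect_lt(abs(gm$loglik - mc$loglik), 1e-6)
  # constraints never bound
  shift <- sqrt(rowSums((gm$means - cbind(an$x, an$y))^2))
  expect_true(all(shift < gm$d_min / 2))
})

test_that("class weights follow the permutation-averaging rule", {
  o22 <- omega22()
  set.seed(75)
  pts <- rhythmprior:::runif_triangle(60, f = 0.15)
  gm <- fit_constrained_gmm(pts, o22)
  # uniform weights: every class averages to the same value
  gm$weights <- rep(1 / 22, 22)
  cw <- category_weights(gm)
  expect_equal(unname(cw), rep(1 / 22, 8), tolerance = 1e-12)
  # all weight on the 3:3:2 component: its class mean is 1/3
  gm$weights <- as.numeric(gm$anchors$ratio == "3:3:2")
  cw2 <- category_weights(gm)
  expect_equal(unname(cw2["233"]), 1 / 3)
  expect_equal(unname(cw2["111"]), 0)
  # invariance to relabelling rotations within a class
  i <- which(gm$anchors$ratio == "3:2:3")
  j <- which(gm$anchors$ratio == "2:3:3")
  w <- rep(1 / 22, 22)
  w[i] <- 0.2
  w[j] <- 0.05
  gm$weights <- w / sum(w)
  a <- category_weights(gm)["233"]
  gm$weights[c(i, j)] <- gm$weights[c(j, i)]
  b <- category_weights(gm)["233"]
  expect_equal(a, b)
})

test_that("weights are covariant under anchor relabelling", {
  an <- separated_anchors()
  set.seed(76)
  pts <- rbind(MASS::mvrnorm(60, c(an$x[1], an$y[1]), diag(1e-4, 2)),
               MASS::mvrnorm(30, c(an$x[2], an$y[2]), diag(1e-4, 2)),
               MASS::mvrnorm(30, c(an$x[3], an$y[3]), diag(1e-4, 2)))
  gm1 <- fit_constrained_gmm(pts, an)
  an2 <- an[c(3, 1, 2), ]
  class(an2) <- c("ratio_set", "data.frame")
  gm2 <- fit_constrained_gmm(pts, an2)
  expect_equal(gm2$weights, gm1$weights[c(3, 1, 2)], tolerance = 1e-6)
})

test_that("explained variance is the squared grid correlation", {
  grid <- coarse_grid()
  set.seed(77)
  pts <- simulate_trial_points(80, three_mode_prior())
  pr <- estimate_prior(pts, grid)
  km <- kernel_matrix(pts, grid)
  gm <- fit_constrained_gmm(km$means)
  ev <- explained_variance(gm, pr)
  expect_gte(ev, 0)
  expect_lte(ev, 1)
  oracle <- stats::cor(gmm_density(gm, grid), pr$p)^2
  expect_equal(ev, oracle)
  # a model equal to the data has explained variance 1 by construction
  expect_gt(ev, 0.5)
  flat <- gm
  flat$covs[] <- rep(diag(10, 2), 22)   # nearly constant density
  expect_warning(ev2 <- explained_variance(flat, rhythmprior:::new_discrete_prior(
    rep(1 / nrow(grid), nrow(grid)), grid)), "zero-variance")
  expect_true(is.na(ev2))
})

test_that("category prediction picks dominant components and sharpens", {
  an <- separated_anchors()
  set.seed(78)
  pts <- rbind(MASS::mvrnorm(100, c(an$x[1], an$y[1]), diag(1e-4, 2)),
               MASS::mvrnorm(50, c(an$x[2], an$y[2]), diag(1e-4, 2)),
               MASS::mvrnorm(50, c(an$x[3], an$y[3]), diag(1e-4, 2)))
  gm <- fit_constrained_gmm(pts, an)
  # at a component mean, that component wins
  expect_equal(predict_category(gm, gm$means[2, ]), 2L)
  # gamma = 1, iso_boost = 1, equal weights and covariances: the decision
  # boundary is the perpendicular bisector between means
  gm_eq <- gm
  gm_eq$weights <- rep(1 / 3, 3)
  gm_eq$covs[] <- rep(diag(1e-4, 2), 3)
  mid <- (gm_eq$means[1, ] + gm_eq$means[2, ]) / 2
  u <- gm_eq$means[2, ] - gm_eq$means[1, ]
  u <- u / sqrt(sum(u^2))
  expect_equal(predict_category(gm_eq, rbind(mid - 0.01 * u), gamma_cat = 1,
                                iso_boost = 1), 1L)
  expect_equal(predict_category(gm_eq, rbind(mid + 0.01 * u), gamma_cat = 1,
                                iso_boost = 1), 2L)
  # increasing gamma never shrinks the highest-weight component's region
  grid <- coarse_grid()
  xy <- as.matrix(grid[grid$inner, c("x", "y")])
  top <- which.max(gm$weights)
  r1 <- predict_category(gm, xy, gamma_cat = 1, iso_boost = 1) == top
  r7 <- predict_category(gm, xy, gamma_cat = 7, iso_boost = 1) == top
  expect_true(all(r7[r1]))
})

test_that("category map distance matches the printed example", {
  expect_equal(category_map_distance(rbind(c(0.5, 0.2, 0.3)),
                                     rbind(c(0.5, 0.25, 0.25))),
               sqrt(0 + 0.05^2 + 0.05^2))
  expect_equal(category_map_distance(rbind(c(0.5, 0.2, 0.3)),
                                     rbind(c(0.5, 0.25, 0.25))),
               0.0707, tolerance = 1e-3)
  m <- rbind(c(0.2, 0.4, 0.4), c(0.5, 0.25, 0.25))
  expect_equal(category_map_distance(m, m), 0)
  a <- rbind(c(0.2, 0.4, 0.4))
  b <- rbind(c(0.25, 0.375, 0.375))
  expect_equal(category_map_distance(a, b), category_map_distance(b, a))
  expect_error(category_map_distance(rbind(c(NA, 0.5, 0.5)), b), "missing")
})

test_that("reference maps interpolate categorization tables", {
  # single category: chosen everywhere
  tab <- data.frame(s1 = 1 / 3, s2 = 1 / 3, s3 = 1 / 3,
                    c1 = 0.25, c2 = 0.25, c3 = 0.5, count = 10)
  xy <- rhythmprior:::runif_triangle(20, f = 0.15)
  map <- build_reference_map(tab, xy)
  expect_true(all(map[, 3] == 0.5))
  expect_error(build_reference_map(tab[0, ], xy), "empty")

  # two categories at separated stimuli: boundary at the midline
  tab2 <- data.frame(s1 = c(0.25, 0.5), s2 = c(0.25, 0.25),
                     s3 = c(0.5, 0.25),
                     c1 = c(0.25, 0.5), c2 = c(0.25, 0.25),
                     c3 = c(0.5, 0.25), count = c(5, 5))
  s_xy <- project(as.matrix(tab2[, c("s1", "s2", "s3")]))
  mid <- colMeans(s_xy)
  u <- (s_xy[2, ] - s_xy[1, ])
  u <- u / sqrt(sum(u^2))
  probe <- rbind(mid - 0.02 * u, mid + 0.02 * u)
  map2 <- build_reference_map(tab2, probe)
  expect_equal(map2[1, ], c(0.25, 0.25, 0.5), ignore_attr = TRUE)
  expect_equal(map2[2, ], c(0.5, 0.25, 0.25), ignore_attr = TRUE)

  # a three-category fixture reproduces its own partition
  an <- separated_anchors()
  cats <- as.matrix(an[, c("p1", "p2", "p3")])
  set.seed(79)
  stims <- rhythmprior:::runif_triangle(120, f = 0.15)
  owner <- max.col(-(outer(stims[, 1], an$x, "-")^2 +
                       outer(stims[, 2], an$y, "-")^2))
  tab3 <- data.frame(s1 = unproject(stims)[, 1],
                     s2 = unproject(stims)[, 2],
                     s3 = unproject(stims)[, 3],
                     c1 = cats[owner, 1], c2 = cats[owner, 2],
                     c3 = cats[owner, 3], count = 1)
  probe3 <- rhythmprior:::runif_triangle(200, f = 0.15)
  map3 <- build_reference_map(tab3, probe3)
  truth <- max.col(-(outer(probe3[, 1], an$x, "-")^2 +
                       outer(probe3[, 2], an$y, "-")^2))
  agree <- rowSums(abs(map3 - cats[truth, ])) < 1e-9
  expect_gte(mean(agree), 0.95)
})
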