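# The RS-MB plane: MB prototype, geometry, rotations, projections, PQ,
# behavior prediction, and the rotation sweep.

test_that("mb prototype weights are the high-minus-low mean difference", {
  xn <- rbind(c(10, 10, 6, 6), c(2, 2, 2, 2))
  xr <- xn
  mem <- c(0.9, 0.8, 0.2, 0.1)
  clf <- mb_weights(xn, xr, mem)
  expect_equal(clf$w, c(4, 0))
  expect_error(mb_weights(xn, xr, rep(0.5, 4)), "identical")
})

test_that("plane geometry matches hand-computed angles and rejects degeneracy", {
  g <- plane_gamma(c(1, 1), c(1, 0))
  expect_equal(g$gamma, 45)
  expect_equal(plane_gamma(c(1, 0), c(0, 2))$gamma, 90)
  # invariant to positive rescaling
  expect_equal(plane_gamma(c(3, 3), c(0.2, 0))$gamma, 45)
  expect_error(plane_gamma(c(0, 0), c(1, 0)), "zero vector")
  expect_error(plane_gamma(c(1, 1), c(2, 2)), "degenerate")
})

test_that("rotated weights satisfy the exact geometric contract", {
  withr::with_seed(13, {
    w_mb <- rnorm(20)
  })
  geom <- plane_gamma(rep(1, 20), w_mb)
  expect_equal(rotated_weights(0, geom), geom$one_hat)
  expect_equal(rotated_weights(geom$gamma, geom), geom$mb_hat)

  # gamma = 60, theta = 90: coefficients (-cot 60, csc 60), orthogonal to RS
  u <- c(1, 0); v <- c(cos(pi / 3), sin(pi / 3))
  g60 <- plane_gamma(u, v)
  w90 <- rotated_weights(90, g60)
  expect_equal(w90, -1 / sqrt(3) * u + 2 / sqrt(3) * v)
  expect_lt(abs(sum(w90 * u)), 1e-12)

  # unit norm, angle to RS axis = theta, and W(theta) . mb_hat = cos(gamma - theta)
  for (th in c(10, 77, 133, 245)) {
    w <- rotated_weights(th, geom)
    expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-12)
    ang <- acos(pmin(1, pmax(-1, sum(w * geom$one_hat)))) * 180 / pi
    expect_equal(ang, min(th %% 360, 360 - th %% 360), tolerance = 1e-8)
    expect_equal(sum(w * geom$mb_hat), cos((geom$gamma - th) * pi / 180),
                 tolerance = 1e-12)
  }
  # the memorability-blind rotation
  expect_lt(abs(sum(rotated_weights(geom$gamma + 90, geom) * geom$mb_hat)), 1e-12)
})

test_that("plane projections recover cloud shape up to view rotation", {
  u <- c(1, 0, 0); v <- c(cos(pi / 4), sin(pi / 4), 0)
  geom <- plane_gamma(u, v)
  withr::with_seed(14, {
    iso <- matrix(rnorm(3 * 10000), 3)
    pr <- project_plane(iso, iso, rep(seq(0.05, 0.95, length.out = 100), 100),
                        geom, rotate_view = 45)
  })
  ell <- pr$ellipses[pr$ellipses$ok, ]
  expect_true(all(abs(ell$major - 1) < 0.12 & abs(ell$minor - 1) < 0.12))
  expect_true(all(ell$major / ell$minor < 1.1))

  # cloud stretched 3:1 along the RS axis (in-plane orthonormal directions)
  withr::with_seed(15, {
    world <- rbind(rnorm(8000, sd = 3), rnorm(8000, sd = 1), rnorm(8000))
    pr2 <- project_plane(world, world, rep(0.5, 8000), geom, rotate_view = 0)
  })
  # single memorability value -> quartiles collapse; use the pooled points
  cv <- stats::cov(cbind(pr2$points$u, pr2$points$v))
  eg <- sort(sqrt(eigen(cv)$values), decreasing = TRUE)
  expect_equal(eg[1] / eg[2], 3, tolerance = 0.15)

  # view rotation changes coordinates, not eigenvalue ratios
  pr3 <- project_plane(world, world, rep(0.5, 8000), geom, rotate_view = 45)
  cv3 <- stats::cov(cbind(pr3$points$u, pr3$points$v))
  eg3 <- sort(sqrt(eigen(cv3)$values), decreasing = TRUE)
  expect_equal(eg3[1] / eg3[2], eg[1] / eg[2], tolerance = 1e-6)
})

test_that("predict_behavior scores a perfect classifier at 100% in every bin", {
  withr::with_seed(16, {
    xn <- matrix(rpois(240, 30) + 30L, 3)
    xr <- matrix(rpois(240, 5), 3)
  })
  clf <- fld_weights(xn, xr)
  pb <- predict_behavior(clf, xn, xr, memorability = runif(80))
  expect_equal(pb$accuracy, rep(1, 8))
  expect_equal(nrow(pb), 8L)
})

test_that("pq scores slope alignment with the reflection rule", {
  mk <- function(slope, cc) tibble::tibble(
    condition = cc, bin_center = c(0.2, 0.4, 0.6, 0.8),
    accuracy = 0.5 + slope * (c(0.2, 0.4, 0.6, 0.8) - 0.5))
  both <- function(s_n, s_r) dplyr::bind_rows(mk(s_n, "novel"), mk(s_r, "repeated"))

  # identical slopes -> 1
  expect_equal(pq(both(0.3, 0.2), both(0.3, 0.2))$pq[3], 1)
  # perpendicular slopes (1 and -1 are 90 degrees apart) -> 0
  expect_equal(pq(both(1, 1), both(-1, -1))$pq[3], 0)
  # 135-degree difference reflects to 45 -> 0.5
  b <- both(tan(70 * pi / 180), tan(70 * pi / 180))
  p <- both(tan(-65 * pi / 180), tan(-65 * pi / 180))
  expect_equal(pq(b, p)$pq[3], 0.5)
  # symmetric in its arguments
  expect_equal(pq(b, p)$pq[3], pq(p, b)$pq[3])
  # exchanging condition labels leaves the mean PQ unchanged
  b2 <- both(0.4, 0.1); p2 <- both(0.15, 0.35)
  swap <- function(d) dplyr::mutate(d, condition = ifelse(condition == "novel",
                                                          "repeated", "novel"))
  expect_equal(pq(b2, p2)$pq[3], pq(swap(b2), swap(p2))$pq[3])

  expect_error(pq(both(1, 1)[1, ], both(1, 1)[1, ]), "2 bins")
})

test_that("rescaling solves the closed-form single-factor least squares with clamping", {
  pred <- tibble::tibble(condition = "repeated", quartile = 1:4,
                         accuracy = c(0.2, 0.3, 0.4, 0.5))
  beh <- pred
  expect_equal(attr(rescale_predictions(pred, beh), "factor"), 1)
  beh2 <- dplyr::mutate(pred, accuracy = accuracy / 2)
  expect_equal(attr(rescale_predictions(pred, beh2), "factor"), 0.5)

  beh3 <- dplyr::mutate(pred, accuracy = accuracy * 3)  # factor 3 -> 150% clamped
  rs <- rescale_predictions(pred, beh3)
  expect_true(all(rs$rescaled_percent <= 100))
  expect_true(any(rs$clamped))
})

test_that("theta sweep reproduces the RS decoder at theta = 0 and reports geometry", {
  fx <- make_pop(n_img = 80, n_units = 50, seed = 70, levels = c(1, 2, 4))
  ch <- simulate_behavior(fx$sequence, fx$images, seed = 70)
  beh <- behavior_by_quartile(ch, fx$images)
  sw <- theta_sweep(fx$pop, beh, theta = seq(0, 350, 10), window = c(100, 500),
                    n_folds = 5, seed = 71)
  cv_rs <- cv_performance(fx$pop, "rs", window = c(100, 500), n_folds = 5,
                          seed = 71)
  pooled <- sum(cv_rs$accuracy * cv_rs$n_test) / sum(cv_rs$n_test)
  expect_equal(sw$accuracy[1], pooled)
  expect_true(attr(sw, "gamma") > 0 && attr(sw, "gamma") < 180)
  expect_true(all(sw$pq >= 0 & sw$pq <= 1))
  expect_true(attr(sw, "best_theta") %in% sw$theta)
})
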