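# Linear memory decoders.

test_that("unit d-prime follows the pooled-SD closed form", {
  nov <- rbind(c(8, 10, 12), c(5, 5, 5))     # unit 1: mean 10 sd 2
  rep_ <- rbind(c(6, 8, 10), c(5, 5, 5))     # unit 1: mean 8 sd 2
  pop <- make_counts_pop(nov, rep_, memorability = c(0.2, 0.5, 0.8))
  expect_message(d <- unit_dprime(pop, c(0, 200)), "zero-variance")
  expect_equal(d$dprime[1], 1)
  expect_equal(d$dprime[2], 0)               # novel == repeated -> 0

  # arbitrary 6-value unit against the formula written out by hand
  nv <- c(4, 7, 6); rp <- c(3, 2, 5)
  pop2 <- make_counts_pop(matrix(nv, 1), matrix(rp, 1), memorability = c(0.2, 0.5, 0.8))
  pooled <- sqrt((var(nv) + var(rp)) / 2)
  expect_equal(unit_dprime(pop2, c(0, 200))$dprime, (mean(nv) - mean(rp)) / pooled)
})

test_that("fld weights equal the diagonal-covariance closed form", {
  xn <- rbind(c(8, 10, 12), c(4, 5, 6))      # means 10, 5; vars 4, 1
  xr <- rbind(c(6, 8, 10), c(4, 5, 6))       # means 8, 5
  clf <- fld_weights(xn, xr)
  expect_equal(clf$w, c(0.5, 0))
  expect_equal(clf$b, 0.5 * (0.5 * (10 + 8) + 0 * (5 + 5)))

  # identical class means -> zero weights
  expect_equal(fld_weights(xn, xn)$w, c(0, 0))

  # invariance to adding a constant to one unit's counts in both classes
  xn2 <- xn; xr2 <- xr
  xn2[1, ] <- xn2[1, ] + 7; xr2[1, ] <- xr2[1, ] + 7
  expect_equal(fld_weights(xn2, xr2)$w, clf$w)

  # d'-weighting identity: w_i * avg variance_i == mean difference
  withr::with_seed(5, {
    xn3 <- matrix(rpois(200, 8), 10)
    xr3 <- matrix(rpois(200, 6), 10)
  })
  clf3 <- fld_weights(xn3, xr3)
  expect_equal(clf3$w * clf3$var_bar, rowMeans(xn3) - rowMeans(xr3))
})

test_that("rs weights reduce decisions to a population-count threshold", {
  withr::with_seed(6, {
    xn <- matrix(rpois(60, 10), 6)
    xr <- matrix(rpois(60, 8), 6)
  })
  clf <- rs_weights(xn, xr)
  expect_equal(clf$w, rep(1, 6))
  x <- xr[, 3]
  expect_equal(decision_values(clf, x), sum(x) - clf$b)
  # permuting units leaves decisions unchanged
  perm <- sample(6)
  clf_p <- rs_weights(xn[perm, ], xr[perm, ])
  expect_equal(decide(clf_p, xn[perm, ]), decide(clf, xn))
})

test_that("decide uses the sign rule with ties going to repeated", {
  clf <- fld_weights(rbind(c(8, 10, 12)), rbind(c(6, 8, 10)))
  expect_equal(decide(clf, matrix(10, 1, 1)), "novel")     # novel training mean
  expect_equal(decide(clf, matrix(9, 1, 1)), "repeated")   # midpoint tie
  expect_error(decide(clf, matrix(1, 2, 1)), "dimension")

  # scale invariance
  clf2 <- clf; clf2$w <- 3.7 * clf$w; clf2$b <- 3.7 * clf$b
  withr::with_seed(7, x <- matrix(rpois(20, 9), 1))
  expect_equal(decide(clf2, x), decide(clf, x))
})

test_that("decide agrees with a diagonal-whitened nearest-class-mean oracle", {
  withr::with_seed(8, {
    xn <- matrix(rpois(300, 12), 15)
    xr <- matrix(rpois(300, 9), 15)
    clf <- fld_weights(xn, xr)
    v <- pmax(clf$var_bar, 1e-6 * mean(clf$var_bar))
    x_test <- matrix(rpois(15 * 20, 10), 15)
    oracle <- apply(x_test, 2, function(x) {
      dn <- sum((x - clf$mu1)^2 / v)
      dr <- sum((x - clf$mu2)^2 / v)
      if (dn < dr) "novel" else "repeated"
    })
    expect_equal(decide(clf, x_test), oracle)
  })
})

test_that("cross-validation scores separable data perfectly and null data at chance", {
  # disjoint count ranges -> 100%
  withr::with_seed(9, {
    xn <- matrix(rpois(200, 30) + 40L, 5)
    xr <- matrix(rpois(200, 5), 5)
  })
  pop <- make_counts_pop(xn, xr, memorability = runif(40))
  cv <- cv_performance(pop, "fld", window = c(0, 200), n_folds = 4, seed = 1)
  expect_equal(mean(cv$accuracy), 1)

  # exchangeable classes -> chance within 3 SE
  withr::with_seed(10, {
    xn0 <- matrix(rpois(2000, 10), 10)
    xr0 <- matrix(rpois(2000, 10), 10)
  })
  pop0 <- make_counts_pop(xn0, xr0, memorability = runif(200))
  cv0 <- cv_performance(pop0, "fld", window = c(0, 200), n_folds = 5, seed = 2)
  se <- sd(cv0$accuracy) / sqrt(5)
  expect_lt(abs(mean(cv0$accuracy) - 0.5), 3 * max(se, 0.02))
})

test_that("2-fold cross-validation matches a hand-rolled oracle on 4 pseudoimages", {
  xn <- rbind(c(10, 12, 11, 13), c(3, 4, 3, 4))
  xr <- rbind(c(7, 8, 9, 8), c(3, 4, 4, 3))
  pop <- make_counts_pop(xn, xr, memorability = c(0.2, 0.4, 0.6, 0.8))
  folds <- make_folds(pop, 2, seed = 3)
  cv <- cv_performance(pop, "fld", window = c(0, 200), n_folds = 2, seed = 3)
  for (f in 1:2) {
    te <- which(folds == f); tr <- which(folds != f)
    clf <- fld_weights(xn[, tr, drop = FALSE], xr[, tr, drop = FALSE])
    acc <- mean(c(decide(clf, xn[, te, drop = FALSE]) == "novel",
                  decide(clf, xr[, te, drop = FALSE]) == "repeated"))
    expect_equal(cv$accuracy[cv$fold == f], acc)
  }
})

test_that("breaking memorability alignment helps the FLD on ITC-like data", {
  diffs <- vapply(1:5, function(s) {
    fx <- make_pop(n_img = 80, n_units = 60, seed = s + 20, levels = c(1, 2, 4))
    aligned <- mean(cv_performance(fx$pop, "fld", c(300, 500), n_folds = 5,
                                   seed = s)$accuracy)
    shuffled <- mean(cv_performance(fx$pop, "fld", c(300, 500), n_folds = 5,
                                    seed = s, shuffle_alignment_flag = TRUE)$accuracy)
    shuffled - aligned
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("decoding timecourse is at chance before stimulus and rises near memory onset", {
  cfg <- itc_config()
  cfg$memory_onset <- par_fixed(150)
  fx <- make_pop(n_img = 100, n_units = 80, cfg = cfg, seed = 30,
                 levels = c(1, 2, 4))
  tc <- decoding_timecourse(fx$pop, "fld", n_folds = 5, seed = 30,
                            shuffle_alignment_flag = TRUE)
  pre <- tc[tc$window_end <= 0, ]
  expect_lt(abs(mean(pre$accuracy) - 0.5), 0.05)
  # first window whose accuracy clears chance by 3 fold-SDs contains ~150 ms
  above <- tc$accuracy - 0.5 > 3 * tc$sd_folds / sqrt(5)
  first_rise <- tc$window_start[which(above & tc$window_start >= 0)[1]]
  expect_lt(abs((first_rise + 75) - 150), 160)   # window center within one window
})

test_that("ranked FLD reproduces full-population CV at zero removal and orders removal harm", {
  fx <- make_pop(n_img = 90, n_units = 60, seed = 40, levels = c(1, 2, 4))
  pop <- shuffle_alignment(fx$pop, seed = 40)
  rf <- ranked_fld(pop, window = c(300, 500),
                   removal_fractions = c(0, 0.5), remove_end = "suppressed",
                   n_folds = 5, seed = 41)
  cv <- cv_performance(pop, "fld", c(300, 500), n_folds = 5, seed = 41)
  expect_equal(rf$accuracy[1], mean(cv$accuracy))

  rf_enh <- ranked_fld(pop, window = c(300, 500),
                       removal_fractions = c(0, 0.5), remove_end = "enhanced",
                       n_folds = 5, seed = 41)
  # removing the most-suppressed half hurts more than removing the
  # (noise-dominated) enhanced half
  expect_lt(rf$accuracy[2], rf_enh$accuracy[2])
  # removing enhanced units does not degrade accuracy beyond fluctuation
  expect_gt(rf_enh$accuracy[2], rf_enh$accuracy[1] - 3 * rf_enh$sd_folds[1])

  expect_error(ranked_fld(pop, removal_fractions = c(0, 1)), "all units")
})
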