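# Generator: images, sequences, units, spike counts, behavior.

test_that("gen_images draws scores from the requested distribution, deterministically", {
  imgs <- gen_images(4, dist_degenerate(0.5), seed = 1)
  expect_equal(imgs$memorability, rep(0.5, 4))
  expect_equal(anyDuplicated(imgs$image_id), 0L)

  big <- gen_images(10000, dist_uniform(0, 1), seed = 7)
  expect_lt(abs(mean(big$memorability) - 0.5), 0.01)

  expect_identical(gen_images(50, seed = 3), gen_images(50, seed = 3))
  expect_false(identical(gen_images(50, seed = 3)$memorability,
                         gen_images(50, seed = 4)$memorability))

  expect_error(gen_images(0), "positive")
  expect_error(dist_uniform(-0.2, 1), "min")
})

test_that("nback_spec gives extreme levels half the core frequency", {
  sp <- nback_spec(c(1, 2, 4, 8, 32, 48, 64, 192), core_count = 30)
  expect_equal(sp$counts, c(15L, 30L, 30L, 30L, 30L, 30L, 30L, 15L))
  expect_error(nback_spec(c(2, 1)), "increasing")
})

test_that("gen_sequence hits on-target n-back counts exactly and keeps pairs consistent", {
  imgs <- gen_images(150, seed = 2)
  sp <- nback_spec(c(1, 2, 4), core_count = 30)  # targets 15/30/15
  seqn <- gen_sequence(imgs, sp, seed = 2)
  on <- seqn[!is.na(seqn$on_target) & seqn$on_target, ]
  expect_equal(as.integer(table(factor(on$n_back, levels = c(1, 2, 4)))),
               c(15L, 30L, 15L))
  # invariants over several seeds: exactly twice, novel first, gap == n_back
  for (s in 1:4) {
    sq <- gen_sequence(imgs, sp, seed = s)
    expect_true(all(table(sq$image_id) == 2))
    by_img <- split(sq, sq$image_id)
    for (p in by_img) {
      p <- p[order(p$trial_index), ]
      expect_equal(p$novelty, c("novel", "repeated"))
      expect_equal(p$n_back[2], p$trial_index[2] - p$trial_index[1])
    }
  }
})

test_that("gen_sequence handles the smallest case and rejects infeasible targets", {
  one <- gen_images(1, seed = 1)
  sq <- gen_sequence(one, nback_spec(1, counts = 1), seed = 1)
  expect_equal(sq$novelty, c("novel", "repeated"))
  expect_equal(sq$n_back[2], 1L)

  expect_error(
    gen_sequence(gen_images(3, seed = 1), nback_spec(c(1, 2), counts = c(3, 3))),
    "infeasible"
  )
})

test_that("gen_units honors region configs and is seed-deterministic", {
  imgs <- gen_images(40, seed = 1)
  hc <- gen_units(hc_config(), 400, imgs, seed = 5)
  expect_lt(abs(mean(hc$memorability_gain)), 0.02)
  itc <- gen_units(itc_config(), 500, imgs, seed = 5)
  expect_gt(mean(itc$memorability_gain), 0)
  expect_gt(mean(1 - itc$suppression_base), 0)
  expect_true(all(vapply(itc$image_rank, function(r) all(sort(r) == 0:39), TRUE)))

  expect_identical(gen_units(itc_config(), 2, imgs, seed = 9),
                   gen_units(itc_config(), 2, imgs, seed = 9))
})

test_that("simulated spike counts match the Poisson rate model", {
  # baseline-only unit: 5 sp/s over a 500 ms trial -> expected 2.5 spikes
  cfg <- region_config(
    name = "baseline-only",
    baseline_rate = par_fixed(5), peak_amplitude = par_fixed(0),
    selectivity = par_fixed(0), memorability_gain = par_fixed(0),
    suppression_base = par_fixed(1), trial_window = c(0, 500)
  )
  imgs <- gen_images(2500, seed = 3)
  seqn <- gen_sequence(imgs, nback_spec(1, counts = 100), seed = 3)
  units <- gen_units(cfg, 1, imgs, seed = 3)
  ses <- simulate_session(units, seqn, imgs, cfg, seed = 3)
  totals <- apply(ses$counts[1, , , drop = FALSE], 2, sum)
  expect_equal(length(totals), 5000L)
  expect_lt(abs(mean(totals) - 2.5) / 2.5, 0.02)
  # Poisson dispersion: variance/mean close to 1
  expect_gt(var(totals) / mean(totals), 0.95)
  expect_lt(var(totals) / mean(totals), 1.05)
  expect_true(all(ses$counts >= 0) && all(ses$counts == round(ses$counts)))
})

test_that("no-modulation limit gives identical novel and repeated expected rates", {
  imgs <- gen_images(10, seed = 1)
  cfg <- region_config(
    name = "flat", baseline_rate = par_fixed(2), peak_amplitude = par_fixed(10),
    selectivity = par_fixed(0.05), memorability_gain = par_fixed(0),
    suppression_base = par_fixed(1)
  )
  units <- gen_units(cfg, 5, imgs, seed = 1)
  ev <- memdecode:::evoked_rates(units, imgs$image_id[3], imgs$memorability[3], 0)
  expect_equal(ev$novel, ev$repeated)
})

test_that("negative computed rates are clipped with a warning", {
  imgs <- gen_images(30, dist_uniform(0.9, 1), seed = 2)
  cfg <- region_config(
    name = "wild", baseline_rate = par_fixed(1), peak_amplitude = par_fixed(10),
    selectivity = par_fixed(0.01), memorability_gain = par_fixed(-10),
    suppression_base = par_fixed(0.9), trial_window = c(0, 100)
  )
  seqn <- gen_sequence(imgs, nback_spec(1, counts = 10), seed = 2)
  units <- gen_units(cfg, 3, imgs, seed = 2)
  expect_warning(simulate_session(units, seqn, imgs, cfg, seed = 2), "clipped")
})

test_that("suppression magnitude is non-decreasing in memorability for both configs (pre-noise)", {
  for (cfg in list(itc_config(), hc_config())) {
    imgs <- tibble::tibble(image_id = "img1", memorability = NA_real_)
    units <- gen_units(cfg, 200, tibble::tibble(image_id = "img1", memorability = 0),
                       seed = 3)
    m_grid <- seq(0.05, 0.95, by = 0.1)
    gap <- vapply(m_grid, function(m) {
      ev <- memdecode:::evoked_rates(units, "img1", m, cfg$suppression_mb_slope)
      mean(ev$novel - ev$repeated)
    }, numeric(1))
    expect_true(all(diff(gap) > -1e-8))
  }
})

test_that("memorability gain makes expected novel population rate track memorability", {
  cfg <- itc_config()
  imgs <- gen_images(50, seed = 4)
  units <- gen_units(cfg, 300, imgs, seed = 4)
  pop_rate <- vapply(seq_len(nrow(imgs)), function(i) {
    mean(memdecode:::evoked_rates(units, imgs$image_id[i], imgs$memorability[i],
                                  cfg$suppression_mb_slope)$novel)
  }, numeric(1))
  expect_gt(cor(imgs$memorability, pop_rate), 0)
})

test_that("simulated behavior follows the configured monotonicities", {
  imgs <- gen_images(2500, seed = 5)
  seqn <- gen_sequence(imgs, nback_spec(c(1, 2, 4), core_count = 500), seed = 5)

  # ceiling: deterministic parameters give 100% correct
  det <- behavior_params(hit_intercept = 50, hit_mb_slope = 0,
                         hit_nback_slope = 0, fa_intercept = -50,
                         fa_mb_slope = 0)
  ch <- simulate_behavior(seqn, imgs, det, seed = 5)
  expect_true(all(ch$correct))

  # null memorability coefficient: hit-rate slope CI covers 0
  null_p <- behavior_params(hit_intercept = 1, hit_mb_slope = 0,
                            hit_nback_slope = 0, fa_mb_slope = 0)
  ch0 <- simulate_behavior(seqn, imgs, null_p, seed = 6)
  rep0 <- ch0[ch0$novelty == "repeated", ]
  m <- imgs$memorability[match(rep0$image_id, imgs$image_id)]
  ci <- confint(lm(as.numeric(rep0$correct) ~ m))[2, ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)

  # positive coefficient: top-quartile hit rate beats bottom quartile
  ch1 <- simulate_behavior(seqn, imgs, behavior_params(), seed = 7)
  rep1 <- ch1[ch1$novelty == "repeated", ]
  m1 <- imgs$memorability[match(rep1$image_id, imgs$image_id)]
  qs <- quantile(m1, c(0.25, 0.75))
  expect_gt(mean(rep1$correct[m1 >= qs[2]]), mean(rep1$correct[m1 <= qs[1]]))

  expect_error(behavior_params(fa_mb_slope = 0.5), "<= 0")
})

test_that("behavior_by_quartile summarizes accuracy on quartile bin centers", {
  imgs <- gen_images(400, seed = 8)
  seqn <- gen_sequence(imgs, nback_spec(c(1, 2), core_count = 80), seed = 8)
  ch <- simulate_behavior(seqn, imgs, seed = 8)
  bq <- behavior_by_quartile(ch, imgs)
  expect_equal(nrow(bq), 8L)
  expect_setequal(unique(bq$condition), c("novel", "repeated"))
  expect_true(all(bq$accuracy >= 0 & bq$accuracy <= 1))
  expect_true(all(diff(sort(unique(bq$bin_center))) > 0))
})
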