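## Synthetic-data generator: seeded images, two-presentation trial sequences,
## heterogeneous tuned units, Poisson spike counts, and behavioral choices.

# ---------------------------------------------------------------------------
# distribution / parameter specs
# ---------------------------------------------------------------------------

#' Memorability score distributions
#'
#' Small distribution specifications used by [gen_images()]. Support must lie
#' inside `[0, 1]` because memorability is defined as a score on that range.
#'
#' @param min,max Bounds of the uniform distribution (inside `[0, 1]`).
#' @param shape1,shape2 Beta shape parameters.
#' @param value Point mass for the degenerate distribution.
#' @return A distribution spec understood by [gen_images()].
#' @export
dist_uniform <- function(min = 0, max = 1) {
  if (min < 0 || max > 1 || max <= min) {
    abort("uniform memorability distribution must have 0 <= min < max <= 1.")
  }
  structure(list(type = "uniform", min = min, max = max), class = "mem_dist")
}

#' @rdname dist_uniform
#' @export
dist_beta <- function(shape1, shape2) {
  if (shape1 <= 0 || shape2 <= 0) abort("beta shapes must be positive.")
  structure(list(type = "beta", shape1 = shape1, shape2 = shape2),
            class = "mem_dist")
}

#' @rdname dist_uniform
#' @export
dist_degenerate <- function(value) {
  if (value < 0 || value > 1) abort("degenerate memorability value must lie in [0, 1].")
  structure(list(type = "degenerate", value = value), class = "mem_dist")
}

sample_mem_dist <- function(dist, n) {
  switch(dist$type,
    uniform    = runif(n, dist$min, dist$max),
    beta       = rbeta(n, dist$shape1, dist$shape2),
    degenerate = rep(dist$value, n),
    abort(sprintf("unknown memorability distribution type '%s'", dist$type))
  )
}

#' Unit-parameter sampling specs
#'
#' Specifications for the per-unit parameter distributions held in a region
#' configuration: a point mass, a normal, or a lognormal parameterized by its
#' median and log-scale spread.
#'
#' @param value Fixed value.
#' @param mean,sd Normal mean and standard deviation.
#' @param median,sdlog Lognormal median (`exp(meanlog)`) and `sdlog`.
#' @return A parameter spec understood by [gen_units()].
#' @export
par_fixed <- function(value) structure(list(type = "fixed", value = value), class = "par_spec")

#' @rdname par_fixed
#' @export
par_normal <- function(mean, sd) {
  structure(list(type = "normal", mean = mean, sd = sd), class = "par_spec")
}

#' @rdname par_fixed
#' @export
par_lognormal <- function(median, sdlog) {
  structure(list(type = "lognormal", meanlog = log(median), sdlog = sdlog),
            class = "par_spec")
}

sample_par <- function(spec, n) {
  switch(spec$type,
    fixed     = rep(spec$value, n),
    normal    = rnorm(n, spec$mean, spec$sd),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    abort(sprintf("unknown parameter spec type '%s'", spec$type))
  )
}

# ---------------------------------------------------------------------------
# region configurations
# ---------------------------------------------------------------------------

#' Region configurations for the synthetic generator
#'
#' A region configuration bundles the distributions from which per-unit
#' parameters are drawn plus the binning of the recorded trial window.
#' `itc_config()` describes an "ITC-like" population whose evoked rate scales
#' with image memorability (positive-mean memorability gain) and whose
#' repetition suppression is modestly supra-proportional. `hc_config()`
#' describes an "HC-like" population with memorability gain centred at zero
#' but repetition suppression that still grows with memorability (via a
#' memorability-dependent suppression base).
#'
#' @param name Label for the configuration.
#' @param baseline_rate,peak_amplitude,selectivity,memorability_gain,
#'   suppression_base,suppression_exponent,response_latency,memory_onset
#'   Parameter specs (see [par_fixed()]) for the corresponding [gen_units()]
#'   fields. Rates are in spikes/s, latencies in ms.
#' @param suppression_mb_slope Scalar: how fast the suppression base shrinks
#'   with memorability (`s_eff = suppression_base - slope * (m - 0.5)`); this
#'   is how an HC-like population shows memorability-dependent suppression
#'   without any vigor modulation.
#' @param bin_width Spike-count bin width in ms.
#' @param trial_window `[t_start, t_end]` in ms relative to stimulus onset.
#' @return A `region_config` list.
#' @export
region_config <- function(name,
                          baseline_rate,
                          peak_amplitude,
                          selectivity,
                          memorability_gain,
                          suppression_base,
                          suppression_exponent = par_fixed(1),
                          suppression_mb_slope = 0,
                          response_latency = par_fixed(100),
                          memory_onset = par_fixed(180),
                          bin_width = 20,
                          trial_window = c(-500, 800)) {
  if (trial_window[2] <= trial_window[1]) abort("trial_window must be increasing.")
  if (bin_width <= 0) abort("bin_width must be positive.")
  structure(
    list(
      name = name,
      baseline_rate = baseline_rate,
      peak_amplitude = peak_amplitude,
      selectivity = selectivity,
      memorability_gain = memorability_gain,
      suppression_base = suppression_base,
      suppression_exponent = suppression_exponent,
      suppression_mb_slope = suppression_mb_slope,
      response_latency = response_latency,
      memory_onset = memory_onset,
      bin_width = bin_width,
      trial_window = trial_window
    ),
    class = "region_config"
  )
}

#' @rdname region_config
#' @export
itc_config <- function() {
  region_config(
    name = "ITC-like",
    baseline_rate = par_lognormal(5, 0.4),
    peak_amplitude = par_lognormal(20, 0.25),
    selectivity = par_lognormal(0.02, 0.3),
    memorability_gain = par_normal(0.8, 0.7),
    suppression_base = par_normal(0.92, 0.03),
    suppression_exponent = par_fixed(1.2),
    suppression_mb_slope = 0.2,
    response_latency = par_fixed(100),
    memory_onset = par_fixed(180)
  )
}

#' @rdname region_config
#' @export
hc_config <- function() {
  region_config(
    name = "HC-like",
    baseline_rate = par_lognormal(2, 0.4),
    peak_amplitude = par_lognormal(8, 0.3),
    selectivity = par_lognormal(0.02, 0.3),
    memorability_gain = par_normal(0, 0.05),
    suppression_base = par_normal(0.95, 0.02),
    suppression_exponent = par_fixed(1),
    suppression_mb_slope = 0.03,
    response_latency = par_fixed(150),
    memory_onset = par_fixed(180)
  )
}

#' @export
print.region_config <- function(x, ...) {
  cat(sprintf("<region_config: %s>\n", x$name))
  cat(sprintf("  bins: %g ms over [%g, %g] ms\n",
              x$bin_width, x$trial_window[1], x$trial_window[2]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# images
# ---------------------------------------------------------------------------

#' Generate a set of images with memorability scores
#'
#' @param n Number of images.
#' @param distribution A [dist_uniform()]-style spec supported on `[0, 1]`.
#' @param seed Optional integer; when supplied the draw is deterministic.
#' @return A tibble with columns `image_id` and `memorability`.
#' @export
gen_images <- function(n, distribution = dist_uniform(), seed = NULL) {
  if (!is_scalar_number(n) || n < 1) abort("`n` must be a positive count.")
  n <- as.integer(n)
  scores <- with_stream(seed, "images", sample_mem_dist(distribution, n))
  tibble::tibble(
    image_id = sprintf("img%05d", seq_len(n)),
    memorability = scores
  )
}

# ---------------------------------------------------------------------------
# trial sequences
# ---------------------------------------------------------------------------

#' n-back target specification
#'
#' Describes the target distribution of gaps between the novel and repeated
#' presentation of an image. The interior levels share a common target count
#' and the two extreme levels receive half that count (e.g. a core count of 30
#' yields 15 one-back trials when 1 is the smallest level).
#'
#' @param levels Strictly increasing positive integer gaps.
#' @param core_count Target count for each interior level.
#' @param counts Optional explicit per-level counts, overriding `core_count`.
#' @return An `nback_spec` list with `levels` and `counts`.
#' @export
nback_spec <- function(levels = c(1, 2, 4, 8, 32, 48, 64, 192),
                       core_count = 30, counts = NULL) {
  if (any(levels <= 0) || any(diff(levels) <= 0)) {
    abort("n-back levels must be strictly increasing positive integers.")
  }
  if (is.null(counts)) {
    counts <- rep(core_count, length(levels))
    if (length(levels) > 1) {
      counts[c(1, length(levels))] <- floor(core_count / 2)
    }
  }
  if (length(counts) != length(levels) || any(counts < 0)) {
    abort("`counts` must be non-negative and match `levels` in length.")
  }
  structure(list(levels = as.integer(levels), counts = as.integer(counts)),
            class = "nback_spec")
}

#' Generate a two-presentation trial sequence
#'
#' Builds a pseudo-random sequence in which every image appears exactly twice,
#' first as novel and later as repeated. The realized gaps for on-target pairs
#' match the [nback_spec()] counts exactly; remaining images are used as
#' fillers whose repeats are flagged `on_target = FALSE` whatever their gap.
#'
#' @param images Tibble from [gen_images()].
#' @param spec An [nback_spec()].
#' @param seed Optional integer seed.
#' @param max_tries Number of randomized placement attempts before giving up.
#' @return A tibble with one row per trial: `trial_index`, `image_id`,
#'   `novelty` (`"novel"`/`"repeated"`), `n_back` (`NA` for novel trials) and
#'   `on_target` (`NA` for novel trials).
#' @export
gen_sequence <- function(images, spec = nback_spec(), seed = NULL,
                         max_tries = 100) {
  n_images <- nrow(images)
  n_on <- sum(spec$counts)
  if (n_on > n_images) {
    abort(sprintf(
      "infeasible n-back targets: %d on-target pairs requested but only %d images.",
      n_on, n_images))
  }
  n_trials <- 2L * n_images
  if (max(spec$levels) > n_trials - 1L) {
    abort("largest n-back level does not fit in the sequence length.")
  }
  with_stream(seed, "sequence", {
    placed <- NULL
    for (try in seq_len(max_tries)) {
      placed <- try_place_sequence(spec, n_trials)
      if (!is.null(placed)) break
    }
    if (is.null(placed)) {
      abort("could not realize the requested n-back distribution; targets may be infeasible.")
    }
    # assign images to pairs at random
    ord <- sample.int(n_images)
    pairs <- placed[sample.int(nrow(placed)), , drop = FALSE]
    img <- images$image_id[ord[seq_len(nrow(pairs))]]
    novelty <- character(n_trials)
    image_id <- character(n_trials)
    n_back <- rep(NA_integer_, n_trials)
    on_target <- rep(NA, n_trials)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      image_id[c(i, j)] <- img[k]
      novelty[i] <- "novel"; novelty[j] <- "repeated"
      n_back[j] <- j - i
      on_target[j] <- as.logical(pairs[k, 3])
    }
    tibble::tibble(
      trial_index = seq_len(n_trials),
      image_id = image_id,
      novelty = novelty,
      n_back = n_back,
      on_target = on_target
    )
  })
}

# One randomized attempt at slotting the on-target pairs, then fillers.
# Returns a matrix with columns (novel_pos, repeat_pos, on_target) or NULL.
try_place_sequence <- function(spec, n_trials) {
  occupied <- logical(n_trials)
  demands <- rep(spec$levels, spec$counts)
  demands <- demands[order(-demands, runif(length(demands)))]
  out <- matrix(0L, nrow = 0, ncol = 3)
  for (d in demands) {
    i_ok <- which(!occupied[seq_len(n_trials - d)] &
                    !occupied[seq_len(n_trials - d) + d])
    if (length(i_ok) == 0L) return(NULL)
    i <- i_ok[sample.int(length(i_ok), 1L)]
    occupied[c(i, i + d)] <- TRUE
    out <- rbind(out, c(i, i + d, 1L))
  }
  free <- which(!occupied)
  while (length(free) > 0L) {
    i <- free[1L]
    free <- free[-1L]
    j_idx <- if (length(free) == 1L) 1L else sample.int(length(free), 1L)
    j <- free[j_idx]
    free <- free[-j_idx]
    out <- rbind(out, c(i, j, 0L))
  }
  out
}

# ---------------------------------------------------------------------------
# units
# ---------------------------------------------------------------------------

#' Draw per-unit tuning parameters for a region configuration
#'
#' Each unit receives a baseline rate, a peak evoked amplitude, an exponential
#' selectivity (tuning decay) constant, a memorability gain, repetition
#' suppression parameters, response/memory latencies, and an independent random
#' ranking of the image set (its tuning order).
#'
#' @param config A [region_config()].
#' @param n_units Number of units.
#' @param images Image tibble (defines the rank maps).
#' @param seed Optional integer seed.
#' @return A tibble with one row per unit; `image_rank` is a list-column of
#'   0-based integer ranks named by `image_id` (0 = best image).
#' @export
gen_units <- function(config, n_units, images, seed = NULL) {
  if (!is_scalar_number(n_units) || n_units < 1) abort("`n_units` must be >= 1.")
  if (nrow(images) == 0) abort("empty image set.")
  n_units <- as.integer(n_units)
  with_stream(seed, "units", {
    u <- tibble::tibble(
      unit_id = sprintf("u%04d", seq_len(n_units)),
      baseline_rate = pmax(0, sample_par(config$baseline_rate, n_units)),
      peak_amplitude = pmax(0, sample_par(config$peak_amplitude, n_units)),
      selectivity = pmax(0, sample_par(config$selectivity, n_units)),
      memorability_gain = sample_par(config$memorability_gain, n_units),
      suppression_base = pmin(1, pmax(1e-3, sample_par(config$suppression_base, n_units))),
      suppression_exponent = pmax(1, sample_par(config$suppression_exponent, n_units)),
      response_latency = sample_par(config$response_latency, n_units),
      memory_onset = sample_par(config$memory_onset, n_units)
    )
    u$image_rank <- lapply(seq_len(n_units), function(i) {
      r <- sample.int(nrow(images)) - 1L
      names(r) <- images$image_id
      r
    })
    u
  })
}

# ---------------------------------------------------------------------------
# expected rates and session simulation
# ---------------------------------------------------------------------------

# Expected evoked rate (spikes/s) of every unit to one image, by condition.
# Returns list(novel, repeated, n_clipped).
evoked_rates <- function(units, image_id, memorability, mb_slope) {
  rank <- vapply(units$image_rank, function(r) r[[image_id]], numeric(1))
  gain <- 1 + units$memorability_gain * (memorability - 0.5)
  n_clipped <- sum(gain < 0)
  gain <- pmax(0, gain)
  nov <- units$peak_amplitude * exp(-units$selectivity * rank) * gain
  s_eff <- pmin(1, pmax(0.01, units$suppression_base - mb_slope * (memorability - 0.5)))
  ref <- pmax(units$peak_amplitude, 1e-12)
  rep_ <- s_eff * ref * (nov / ref)^units$suppression_exponent
  rep_[nov == 0] <- 0
  list(novel = nov, repeated = pmin(rep_, nov), n_clipped = n_clipped)
}

#' Simulate a recording session of Poisson spike counts
#'
#' For every unit, trial and time bin a spike count is drawn from a Poisson
#' distribution whose rate is the unit baseline before the response latency
#' and baseline plus evoked rate afterwards. The evoked rate is the unit's
#' exponential tuning curve scaled by a memorability gain; on repeated trials
#' the evoked rate is suppressed from the unit's memory-onset latency onward
#' (bins straddling a latency use the exact time-integral of the piecewise
#' rate). Negative computed rates are clipped to zero and counted.
#'
#' @param units Tibble from [gen_units()].
#' @param sequence Trial tibble from [gen_sequence()].
#' @param images Image tibble.
#' @param config The [region_config()] that defines binning.
#' @param seed Optional integer seed.
#' @return A `session_recording` object: list with `counts` (units x trials x
#'   bins integer array), `trials`, `images`, `units`, `bin_edges`, and a
#'   `clip_count` attribute recording how many rate evaluations were clipped
#'   at zero.
#' @export
simulate_session <- function(units, sequence, images, config, seed = NULL) {
  if (!all(sequence$image_id %in% images$image_id)) {
    abort("sequence refers to images missing from the image set.")
  }
  bin_edges <- seq(config$trial_window[1], config$trial_window[2], by = config$bin_width)
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  n_units <- nrow(units)
  n_trials <- nrow(sequence)
  n_bins <- length(lo)
  mem <- setNames(images$memorability, images$image_id)

  # per-unit bin overlap (ms) with [latency, Inf) and [memory_onset, Inf)
  ov_after <- function(onset) {
    t(vapply(onset, function(o) pmax(0, hi - pmax(lo, o)), numeric(n_bins)))
  }
  ov_lat <- ov_after(units$response_latency)   # units x bins, evoked epoch
  ov_mem <- ov_after(units$memory_onset)       # units x bins, memory epoch
  ov_pre <- ov_lat - ov_mem                    # evoked but pre-memory

  lam <- array(0, dim = c(n_units, n_trials, n_bins))
  base_ms <- units$baseline_rate / 1000
  binw <- hi - lo
  clip_total <- 0L
  for (t_i in seq_len(n_trials)) {
    img <- sequence$image_id[t_i]
    ev <- evoked_rates(units, img, mem[[img]], config$suppression_mb_slope)
    clip_total <- clip_total + ev$n_clipped
    if (sequence$novelty[t_i] == "novel") {
      lam[, t_i, ] <- outer(base_ms, binw) + (ev$novel / 1000) * ov_lat
    } else {
      lam[, t_i, ] <- outer(base_ms, binw) +
        (ev$novel / 1000) * ov_pre + (ev$repeated / 1000) * ov_mem
    }
  }
  counts <- with_stream(seed, "spikes", {
    array(rpois(length(lam), lam), dim = dim(lam))
  })
  if (clip_total > 0) {
    warn(sprintf("%d negative computed rates were clipped to zero.", clip_total))
  }
  structure(
    list(
      counts = counts,
      trials = sequence,
      images = images,
      units = units,
      bin_edges = bin_edges,
      config_name = config$name,
      clip_count = clip_total
    ),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<session_recording: %d units x %d trials x %d bins (%s)>\n",
              d[1], d[2], d[3], x$config_name %null% "custom"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# behavior
# ---------------------------------------------------------------------------

#' Behavioral choice model parameters
#'
#' Logistic model of the per-trial probability of reporting "repeated".
#' For repeated trials the hit probability increases with memorability and
#' decreases with the log of the n-back gap; for novel trials the false-alarm
#' probability is non-increasing in memorability.
#'
#' @param hit_intercept,hit_mb_slope,hit_nback_slope Logit-scale terms for
#'   repeated trials: `logit(P) = hit_intercept + hit_mb_slope * (m - 0.5) -
#'   hit_nback_slope * log(n_back)`.
#' @param fa_intercept,fa_mb_slope Logit-scale terms for novel trials:
#'   `logit(P) = fa_intercept + fa_mb_slope * (m - 0.5)`; `fa_mb_slope` must
#'   be `<= 0`.
#' @return A `behavior_params` list.
#' @export
behavior_params <- function(hit_intercept = 2.6, hit_mb_slope = 2.2,
                            hit_nback_slope = 0.25,
                            fa_intercept = -2.2, fa_mb_slope = -0.1) {
  if (hit_mb_slope < 0) abort("hit_mb_slope must be >= 0 (accuracy increases with memorability).")
  if (hit_nback_slope < 0) abort("hit_nback_slope must be >= 0.")
  if (fa_mb_slope > 0) abort("fa_mb_slope must be <= 0.")
  structure(list(hit_intercept = hit_intercept, hit_mb_slope = hit_mb_slope,
                 hit_nback_slope = hit_nback_slope, fa_intercept = fa_intercept,
                 fa_mb_slope = fa_mb_slope), class = "behavior_params")
}

#' Simulate behavioral choices for a trial sequence
#'
#' @param sequence Trial tibble from [gen_sequence()].
#' @param images Image tibble.
#' @param params A [behavior_params()].
#' @param seed Optional integer seed.
#' @return The sequence tibble with `p_repeated`, `choice` and `correct`
#'   columns appended.
#' @export
simulate_behavior <- function(sequence, images, params = behavior_params(),
                              seed = NULL) {
  mem <- setNames(images$memorability, images$image_id)
  m <- unname(mem[sequence$image_id])
  p <- ifelse(
    sequence$novelty == "repeated",
    plogis(params$hit_intercept + params$hit_mb_slope * (m - 0.5) -
             params$hit_nback_slope * log(pmax(1L, sequence$n_back))),
    plogis(params$fa_intercept + params$fa_mb_slope * (m - 0.5))
  )
  if (any(p < 0 | p > 1)) abort("choice probabilities outside [0, 1].")
  report_rep <- with_stream(seed, "behavior", rbinom(length(p), 1L, p) == 1L)
  dplyr::mutate(
    sequence,
    p_repeated = p,
    choice = ifelse(report_rep, "repeated", "novel"),
    correct = .data$choice == .data$novelty
  )
}

#' Behavioral accuracy by memorability quartile
#'
#' Summarizes simulated (or observed) choices into per-condition accuracy in
#' four memorability bins whose boundaries are the quartiles of the image
#' memorability distribution; bin centers are the midpoints between
#' consecutive boundaries. This is the behavioral benchmark against which
#' decoded predictions are scored.
#'
#' @param choices Tibble from [simulate_behavior()] (needs `novelty`,
#'   `image_id`, `correct`).
#' @param images Image tibble.
#' @param boundaries Optional 5-vector of quartile boundaries; defaults to the
#'   quartiles of `images$memorability`.
#' @return Tibble with `condition`, `quartile`, `bin_center`, `accuracy`
#'   (fraction correct in `[0, 1]`) and `n_trials`.
#' @export
behavior_by_quartile <- function(choices, images, boundaries = NULL) {
  boundaries <- boundaries %null%
    unname(quantile(images$memorability, probs = seq(0, 1, 0.25)))
  centers <- (boundaries[-1] + boundaries[-5]) / 2
  mem <- setNames(images$memorability, images$image_id)
  choices |>
    dplyr::mutate(
      memorability = unname(mem[.data$image_id]),
      quartile = cut_quartile(.data$memorability, boundaries)
    ) |>
    dplyr::group_by(condition = .data$novelty, quartile = .data$quartile) |>
    dplyr::summarise(accuracy = mean(.data$correct), n_trials = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(bin_center = centers[.data$quartile]) |>
    dplyr::select("condition", "quartile", "bin_center", "accuracy", "n_trials")
}

cut_quartile <- function(m, boundaries) {
  q <- findInterval(m, boundaries, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(q, 1L), 4L)
}
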