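## Exponential tuning-curve fits by Poisson maximum likelihood, synthetic
## regeneration from fits, threshold modification, and the threshold sweep.

#' Rank images along a unit's tuning curve
#'
#' Ranks the novel/repeated-averaged spike counts from best (rank 0, highest
#' count) to worst. Ties are broken by image order, deterministically.
#'
#' @param avg_counts Numeric vector of per-image counts averaged across the
#'   novel and repeated presentations.
#' @param image_ids Optional ids (defaults to index order).
#' @return Integer vector of 0-based ranks, named by image id.
#' @export
rank_images <- function(avg_counts, image_ids = NULL) {
  n <- length(avg_counts)
  image_ids <- image_ids %null% as.character(seq_len(n))
  ord <- order(-avg_counts, seq_len(n))
  ranks <- integer(n)
  ranks[ord] <- seq_len(n) - 1L
  names(ranks) <- image_ids
  ranks
}

#' Fit one unit's exponential tuning curve by Poisson maximum likelihood
#'
#' Fits `y(x; M) = A_M * exp(-alpha * x)` (separate novel/repeated
#' amplitudes, shared decay `alpha >= 0`) to window spike counts given the
#' unit's image ranks. The model is a Poisson GLM with log link
#' (`count ~ condition + rank`); when the unconstrained decay is negative
#' the model is refit with the rank term dropped (`alpha = 0`, flagged
#' `flat`). All-zero counts yield zero amplitudes with `converged = FALSE`.
#'
#' @param novel_counts,repeated_counts Integer window spike counts per
#'   image.
#' @param ranks 0-based image ranks along the tuning curve (see
#'   [rank_images()]).
#' @return One-row tibble: `a_novel`, `a_repeated`, `alpha`, `loglik`,
#'   `converged`, `flat`.
#' @export
fit_tuning_unit <- function(novel_counts, repeated_counts, ranks) {
  k <- c(novel_counts, repeated_counts)
  if (all(k == 0)) {
    return(tibble::tibble(a_novel = 0, a_repeated = 0, alpha = 0,
                          loglik = 0, converged = FALSE, flat = TRUE))
  }
  x <- c(ranks, ranks)
  cond <- factor(rep(c("novel", "repeated"), each = length(ranks)),
                 levels = c("novel", "repeated"))
  fit <- suppressWarnings(stats::glm(k ~ cond + x, family = stats::poisson()))
  alpha <- -unname(coef(fit)["x"])
  flat <- FALSE
  if (!is.finite(alpha) || alpha < 0) {
    fit <- suppressWarnings(stats::glm(k ~ cond, family = stats::poisson()))
    alpha <- 0
    flat <- TRUE
  }
  b <- coef(fit)
  a_n <- exp(unname(b["(Intercept)"]))
  a_r <- exp(unname(b["(Intercept)"]) + unname(b["condrepeated"]))
  tibble::tibble(a_novel = a_n, a_repeated = a_r, alpha = alpha,
                 loglik = as.numeric(logLik(fit)),
                 converged = isTRUE(fit$converged), flat = flat)
}

#' Fit exponential tuning curves to every unit of a pseudopopulation
#'
#' For each unit, images are ranked by the unit's average observed spike
#' count ([rank_images()]) and a three-parameter exponential model
#' `y(x; M) = A_M * exp(-alpha * x)` (novel and repeated amplitudes, shared
#' decay) is fit by Poisson maximum likelihood to the window spike counts.
#' `y` is the expected spike *count* in the window, not a rate.
#'
#' @param pop A `pseudopop`.
#' @param window Spike-count window in ms (default 100-500 ms).
#' @return A `tuning_fits` tibble (`unit_id`, `a_novel`, `a_repeated`,
#'   `alpha`, `loglik`, `converged`, `flat`) with the per-unit rank matrix
#'   (units x images) and the pseudoimage memorabilities stored as
#'   attributes.
#' @export
fit_tuning <- function(pop, window = c(100, 500)) {
  wc <- window_counts(pop, window)
  n_units <- nrow(wc$novel)
  ranks <- matrix(0L, n_units, ncol(wc$novel))
  rows <- lapply(seq_len(n_units), function(u) {
    avg <- (wc$novel[u, ] + wc$repeated[u, ]) / 2
    r <- rank_images(avg)
    ranks[u, ] <<- r
    fit_tuning_unit(wc$novel[u, ], wc$repeated[u, ], r)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble::tibble(unit_id = pop$unit_ids), out)
  attr(out, "ranks") <- ranks
  attr(out, "memorability") <- pop$pseudoimages$memorability
  attr(out, "window") <- window
  class(out) <- c("tuning_fits", class(out))
  out
}

#' Predicted spike counts from tuning fits, with optional thresholding
#'
#' Evaluates `y(x; M) = A_M * exp(-alpha * x)` for every unit and image
#' rank. With `threshold_fraction = N > 0`, the fraction `N` of each unit's
#' ranked tuning curve is modified: for ranks at or beyond the cutoff rank
#' `floor((1 - N) * n_images)`, the prediction is replaced for both
#' conditions. The default replacement (`mode = "cutoff_repeated"`) is the
#' repeated-curve value *at the cutoff rank*, collapsing both curves onto a
#' flat tail that carries no memory signal; `mode = "per_rank_repeated"`
#' instead substitutes each rank's own repeated value (preserving
#' sub-threshold tuning while removing memory information only for novel
#' presentations).
#'
#' @param fits A `tuning_fits` object.
#' @param condition `"novel"` or `"repeated"`.
#' @param threshold_fraction Fraction `N` of the curve modified, in
#'   `[0, 1]`.
#' @param mode Replacement rule (see above).
#' @return Matrix (units x images) of expected window spike counts.
#' @export
predict_tuning <- function(fits, condition = c("novel", "repeated"),
                           threshold_fraction = 0,
                           mode = c("cutoff_repeated", "per_rank_repeated")) {
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  if (threshold_fraction < 0 || threshold_fraction > 1) {
    abort("threshold_fraction must lie in [0, 1].")
  }
  ranks <- attr(fits, "ranks")
  n_img <- ncol(ranks)
  amp <- if (condition == "novel") fits$a_novel else fits$a_repeated
  y <- amp * exp(-fits$alpha * ranks)  # units x images (row-recycled)
  if (threshold_fraction > 0) {
    cutoff <- floor((1 - threshold_fraction) * n_img)
    mod <- ranks >= cutoff
    if (mode == "cutoff_repeated") {
      floor_val <- fits$a_repeated * exp(-fits$alpha * cutoff)
      y[mod] <- (matrix(floor_val, nrow(y), ncol(y)))[mod]
    } else {
      y_rep <- fits$a_repeated * exp(-fits$alpha * ranks)
      y[mod] <- y_rep[mod]
    }
  }
  if (any(y < 0)) abort("negative fitted spike count; fits are corrupt.")
  y
}

#' Synthesize a Poisson pseudopopulation from tuning fits
#'
#' Draws one Poisson spike count per unit, image and condition with mean
#' `y(x; M)` (optionally threshold-modified). Memorability is carried over
#' from the source images, so the synthetic population inherits the
#' original memorability alignment. The result is a single-bin
#' `pseudopop` whose bin spans the fitting window.
#'
#' @inheritParams predict_tuning
#' @param seed Optional integer seed.
#' @return A `pseudopop` with one time bin.
#' @export
synthesize_from_fits <- function(fits, threshold_fraction = 0,
                                 mode = c("cutoff_repeated", "per_rank_repeated"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  y_n <- predict_tuning(fits, "novel", threshold_fraction, mode)
  y_r <- predict_tuning(fits, "repeated", threshold_fraction, mode)
  mem <- attr(fits, "memorability")
  window <- attr(fits, "window") %null% c(100, 500)
  n_units <- nrow(y_n); n_img <- ncol(y_n)
  counts <- array(0L, dim = c(n_units, n_img, 2L, 1L))
  with_stream(seed, "synthesize", {
    counts[, , 1L, 1L] <- rpois(length(y_n), y_n)
    counts[, , 2L, 1L] <- rpois(length(y_r), y_r)
  })
  structure(
    list(
      counts = counts,
      pseudoimages = tibble::tibble(
        pseudoimage = seq_len(n_img),
        memorability = mem,
        mb_bin = NA_integer_, n_back = NA_character_
      ),
      unit_ids = fits$unit_id,
      bin_edges = window
    ),
    class = "pseudopop"
  )
}

#' Threshold sweep over synthetic populations
#'
#' For each threshold fraction, synthesizes a threshold-modified population
#' from the fits and computes (a) the repeated-condition
#' memorability-to-GMFR correlation with a bootstrap confidence interval
#' and (b) cross-validated FLD memory accuracy. The Poisson draws at every
#' fraction share one seed, so fraction 0 reproduces the unmodified
#' population exactly.
#'
#' @param fits A `tuning_fits` object.
#' @param fractions Grid of threshold fractions in `[0, 1]`.
#' @param n_folds Cross-validation folds.
#' @param n_boot Bootstrap resamples for the correlation CI.
#' @param seed Optional integer seed.
#' @param mode Threshold replacement rule (see [predict_tuning()]).
#' @return A `threshold_sweep` tibble: `fraction`, `r`, `conf_low`,
#'   `conf_high`, `accuracy`, `sd_folds`.
#' @export
threshold_sweep <- function(fits, fractions = seq(0, 1, by = 0.05),
                            n_folds = 5, n_boot = 200, seed = NULL,
                            mode = c("cutoff_repeated", "per_rank_repeated")) {
  mode <- match.arg(mode)
  if (any(fractions < 0 | fractions > 1)) abort("fractions must lie in [0, 1].")
  rows <- lapply(fractions, function(fr) {
    pop <- synthesize_from_fits(fits, threshold_fraction = fr, mode = mode,
                                seed = seed)
    window <- pop$bin_edges
    tb <- gmfr(pop, window = window)
    m <- tb$memorability; y <- tb$repeated
    r_obs <- if (sd(y) == 0) NA_real_ else cor(m, y)
    boot <- with_stream(seed, "sweep_boot", {
      vapply(seq_len(n_boot), function(i) {
        ii <- sample.int(length(y), replace = TRUE)
        if (sd(m[ii]) == 0 || sd(y[ii]) == 0) return(NA_real_)
        cor(m[ii], y[ii])
      }, numeric(1))
    })
    ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
    cv <- cv_performance(pop, method = "fld", window = window,
                         n_folds = n_folds, seed = seed)
    tibble::tibble(fraction = fr, r = r_obs, conf_low = ci[1],
                   conf_high = ci[2], accuracy = mean(cv$accuracy),
                   sd_folds = sd(cv$accuracy))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("threshold_sweep", class(out))
  out
}
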