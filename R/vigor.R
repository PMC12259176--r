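## Population-vigor statistics: grand mean firing rate vs memorability,
## correlations, permutation slope test, suppression magnitude/scaling, and
## the sliding-window correlation time course.

#' Grand mean firing rate per pseudoimage
#'
#' For each pseudoimage and condition, the mean over units of the window
#' spike count divided by the window duration, in spikes/s.
#'
#' @param pop A `pseudopop`.
#' @param window `[start, end]` ms spike-count window (default 300-500 ms).
#' @return A `gmfr_table` tibble: `pseudoimage`, `memorability`, `novel`,
#'   `repeated` (spikes/s), with the window stored as an attribute.
#' @export
gmfr <- function(pop, window = c(300, 500)) {
  wc <- window_counts(pop, window)
  out <- tibble::tibble(
    pseudoimage = pop$pseudoimages$pseudoimage,
    memorability = pop$pseudoimages$memorability,
    novel = colMeans(wc$novel) / wc$duration_s,
    repeated = colMeans(wc$repeated) / wc$duration_s
  )
  attr(out, "window") <- window
  class(out) <- c("gmfr_table", class(out))
  out
}

#' Pearson correlation between memorability and GMFR
#'
#' Two-sided p-value from the exact t transform with `df = n - 2`.
#'
#' @param table A [gmfr()] table.
#' @param novelty `"novel"` or `"repeated"`.
#' @return Tibble with `novelty`, `r`, `df`, `p`.
#' @export
memorability_correlation <- function(table, novelty = c("repeated", "novel")) {
  novelty <- match.arg(novelty)
  y <- table[[novelty]]
  m <- table$memorability
  if (length(m) < 3) abort("need at least 3 pseudoimages for a correlation.")
  if (sd(m) == 0 || sd(y) == 0) {
    warn("zero variance in memorability or GMFR; correlation undefined.")
    return(tibble::tibble(novelty = novelty, r = NA_real_,
                          df = length(m) - 2L, p = NA_real_))
  }
  ct <- stats::cor.test(m, y, method = "pearson")
  tibble::tibble(novelty = novelty, r = unname(ct$estimate),
                 df = unname(ct$parameter), p = ct$p.value)
}

ls_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Least-squares regression of GMFR on memorability
#'
#' @param table A [gmfr()] table.
#' @param novelty Condition column to regress.
#' @param conf_level Confidence level for the slope interval.
#' @return Tibble with `novelty`, `slope` (spikes/s per memorability unit),
#'   `intercept`, `conf_low`, `conf_high`, `sigma`.
#' @export
gmfr_regression <- function(table, novelty = c("repeated", "novel"),
                            conf_level = 0.95) {
  novelty <- match.arg(novelty)
  fit <- lm(table[[novelty]] ~ table$memorability)
  ci <- stats::confint(fit, level = conf_level)[2, ]
  tibble::tibble(
    novelty = novelty,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    conf_low = unname(ci[1]),
    conf_high = unname(ci[2]),
    sigma = summary(fit)$sigma
  )
}

#' Permutation test for a difference in GMFR-vs-memorability slopes
#'
#' The null distribution is built by randomly reassigning the region label
#' to each data point without replacement, refitting the two regressions and
#' recording the slope difference; this is repeated `n_perm` times. The
#' two-sided p-value counts null `|slope difference|` at least as large as
#' observed, including the observed statistic in the null set (so
#' `p >= 1 / (n_perm + 1)`).
#'
#' @param table_a,table_b [gmfr()] tables for the two populations.
#' @param novelty Condition column compared.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Optional integer seed.
#' @return Tibble with `observed_delta` (slope A minus slope B), `p`,
#'   `n_perm`.
#' @export
permutation_slope_test <- function(table_a, table_b,
                                   novelty = c("repeated", "novel"),
                                   n_perm = 10000, seed = NULL) {
  novelty <- match.arg(novelty)
  if (n_perm < 100) abort("n_perm must be at least 100.")
  if (nrow(table_a) == 0 || nrow(table_b) == 0) abort("both tables must be non-empty.")
  xa <- table_a$memorability; ya <- table_a[[novelty]]
  xb <- table_b$memorability; yb <- table_b[[novelty]]
  obs <- ls_slope(xa, ya) - ls_slope(xb, yb)
  x <- c(xa, xb); y <- c(ya, yb)
  na <- length(xa); n <- length(x)
  null_delta <- with_stream(seed, "permutation", {
    vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(n, na)
      ls_slope(x[ia], y[ia]) - ls_slope(x[-ia], y[-ia])
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_delta) >= abs(obs))) / (n_perm + 1)
  tibble::tibble(novelty = novelty, observed_delta = obs, p = p,
                 n_perm = as.integer(n_perm))
}

#' Repetition-suppression magnitude
#'
#' Mean percent suppression across pseudoimages,
#' `100 * (novel - repeated) / novel`, overall and by memorability quartile.
#' Rows with a novel GMFR of zero are excluded (and counted).
#'
#' @param table A [gmfr()] table with paired novel/repeated rows.
#' @return List with `mean_percent`, `by_quartile` tibble and `n_excluded`.
#' @export
suppression_stats <- function(table) {
  bad <- table$novel == 0
  if (any(bad)) inform(sprintf("%d rows with zero novel GMFR excluded.", sum(bad)))
  tb <- table[!bad, , drop = FALSE]
  pct <- 100 * (tb$novel - tb$repeated) / tb$novel
  qs <- unname(quantile(tb$memorability, probs = seq(0, 1, 0.25)))
  by_q <- tibble::tibble(
    quartile = cut_quartile(tb$memorability, qs),
    percent = pct
  ) |>
    dplyr::group_by(.data$quartile) |>
    dplyr::summarise(mean_percent = mean(.data$percent), n = dplyr::n(),
                     .groups = "drop")
  list(mean_percent = mean(pct), by_quartile = by_q, n_excluded = sum(bad))
}

#' Scaling of repetition suppression with response vigor
#'
#' Least-squares slope of `log(repeated GMFR)` on `log(novel GMFR)` across
#' pseudoimages. A slope of 1 corresponds to constant proportional
#' suppression; the suppression-exponent convention of the synthetic
#' generator is recovered by this estimator. Non-positive rates are
#' excluded. A percentile bootstrap over pseudoimages gives the confidence
#' interval.
#'
#' @param table A [gmfr()] table.
#' @param n_boot Bootstrap resamples.
#' @param conf_level Confidence level.
#' @param seed Optional integer seed.
#' @return Tibble with `exponent`, `conf_low`, `conf_high`, `n`.
#' @export
suppression_scaling <- function(table, n_boot = 1000, conf_level = 0.95,
                                seed = NULL) {
  keep <- table$novel > 0 & table$repeated > 0
  x <- log(table$novel[keep]); y <- log(table$repeated[keep])
  if (length(x) < 3) abort("need at least 3 pseudoimages with positive rates.")
  est <- ls_slope(x, y)
  boot <- with_stream(seed, "scaling_boot", {
    vapply(seq_len(n_boot), function(i) {
      ii <- sample.int(length(x), replace = TRUE)
      ls_slope(x[ii], y[ii])
    }, numeric(1))
  })
  a <- (1 - conf_level) / 2
  ci <- unname(quantile(boot, c(a, 1 - a), na.rm = TRUE))
  tibble::tibble(exponent = est, conf_low = ci[1], conf_high = ci[2],
                 n = length(x))
}

#' Sliding-window memorability-correlation time course
#'
#' At each window start, computes the Pearson correlation between
#' memorability and the window GMFR, with a percentile bootstrap confidence
#' interval over pseudoimages. Windows extending past the recorded bins are
#' dropped.
#'
#' @param pop A `pseudopop`.
#' @param novelty Condition analyzed.
#' @param window_len Window length in ms (default 150).
#' @param step Window step in ms (default 20).
#' @param n_boot Bootstrap resamples per window.
#' @param conf_level Confidence level.
#' @param seed Optional integer seed.
#' @return A `correlation_timecourse` tibble: `window_start`, `window_end`,
#'   `r`, `df`, `p`, `conf_low`, `conf_high`, `significant` (CI excludes 0).
#' @export
correlation_timecourse <- function(pop, novelty = c("repeated", "novel"),
                                   window_len = 150, step = 20,
                                   n_boot = 10000, conf_level = 0.95,
                                   seed = NULL) {
  novelty <- match.arg(novelty)
  t0 <- pop$bin_edges[1]
  t_end <- pop$bin_edges[length(pop$bin_edges)]
  starts <- seq(t0, t_end - window_len, by = step)
  m <- pop$pseudoimages$memorability
  a <- (1 - conf_level) / 2
  rows <- with_stream(seed, "cor_timecourse", {
    lapply(starts, function(s) {
      tb <- gmfr(pop, window = c(s, s + window_len))
      y <- tb[[novelty]]
      ct <- memorability_correlation(tb, novelty)
      boot <- vapply(seq_len(n_boot), function(i) {
        ii <- sample.int(length(y), replace = TRUE)
        if (sd(m[ii]) == 0 || sd(y[ii]) == 0) return(NA_real_)
        cor(m[ii], y[ii])
      }, numeric(1))
      ci <- unname(quantile(boot, c(a, 1 - a), na.rm = TRUE))
      tibble::tibble(window_start = s, window_end = s + window_len,
                     r = ct$r, df = ct$df, p = ct$p,
                     conf_low = ci[1], conf_high = ci[2],
                     significant = ci[1] > 0 | ci[2] < 0)
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("correlation_timecourse", class(out))
  out
}
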