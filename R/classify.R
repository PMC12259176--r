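## Linear memory decoders: per-unit d-prime, diagonal-covariance FLD,
## population-vigor (all-ones) decoder, cross-validation, sliding-window
## decoding, and ranked unit-removal curves.

#' Per-unit sensitivity to memory (d-prime)
#'
#' `d' = (mean novel - mean repeated) / pooled SD`, with pooled SD the
#' square root of the two-condition average variance. Positive values mark
#' repetition suppression (the unit fires less to repeated presentations).
#' Units with zero pooled SD get `d' = 0`.
#'
#' @param pop A `pseudopop`.
#' @param window Spike-count window in ms.
#' @return Tibble with `unit_id`, `mean_novel`, `mean_repeated`, `dprime`.
#' @export
unit_dprime <- function(pop, window = c(300, 500)) {
  wc <- window_counts(pop, window)
  if (ncol(wc$novel) < 2) abort("need at least 2 pseudoimages.")
  mu_n <- rowMeans(wc$novel)
  mu_r <- rowMeans(wc$repeated)
  pooled <- sqrt((apply(wc$novel, 1, var) + apply(wc$repeated, 1, var)) / 2)
  d <- ifelse(pooled > 0, (mu_n - mu_r) / pooled, 0)
  if (any(pooled == 0)) inform(sprintf("%d zero-variance units set to d' = 0.",
                                       sum(pooled == 0)))
  tibble::tibble(unit_id = pop$unit_ids, mean_novel = mu_n,
                 mean_repeated = mu_r, dprime = d)
}

new_linclf <- function(w, b, mu1, mu2, var_bar = NULL, method = "custom",
                       unit_ids = NULL) {
  structure(
    list(w = as.numeric(w), b = as.numeric(b), mu1 = mu1, mu2 = mu2,
         var_bar = var_bar, method = method, unit_ids = unit_ids),
    class = "linclf"
  )
}

#' @export
print.linclf <- function(x, ...) {
  cat(sprintf("<linclf (%s): %d units, bias %.4g>\n",
              x$method, length(x$w), x$b))
  invisible(x)
}

midpoint_bias <- function(w, mu1, mu2) 0.5 * sum(w * (mu1 + mu2))

#' Diagonal-covariance Fisher linear discriminant weights
#'
#' `w_i = (mu_novel_i - mu_repeated_i) / var_i`, where `var_i` is the
#' per-unit variance averaged across the two conditions (the off-diagonal
#' covariance terms are set to zero, so the classifier effectively weights
#' each unit by its d-prime). The bias is the class-mean midpoint rule,
#' `b = w . (mu_novel + mu_repeated) / 2`. Per-unit variances are floored
#' at `1e-6` of the mean variance; fully zero-variance units get weight 0.
#'
#' @param x_novel,x_repeated Training matrices, units x pseudoimages.
#' @return A `linclf` object.
#' @export
fld_weights <- function(x_novel, x_repeated) {
  mu_n <- rowMeans(x_novel)
  mu_r <- rowMeans(x_repeated)
  v <- (apply(x_novel, 1, var) + apply(x_repeated, 1, var)) / 2
  vbar <- mean(v)
  if (vbar == 0) {
    w <- rep(0, length(mu_n))
  } else {
    v_floor <- pmax(v, 1e-6 * vbar)
    w <- (mu_n - mu_r) / v_floor
    w[v == 0] <- 0
  }
  new_linclf(w, midpoint_bias(w, mu_n, mu_r), mu_n, mu_r, v, method = "fld")
}

#' Population-vigor (repetition-suppression) decoder
#'
#' All-ones weights, so the decision value reduces to the total population
#' count minus a threshold; the bias is the class-mean midpoint rule on the
#' training data.
#'
#' @param x_novel,x_repeated Training matrices, units x pseudoimages.
#' @return A `linclf` object.
#' @export
rs_weights <- function(x_novel, x_repeated) {
  mu_n <- rowMeans(x_novel)
  mu_r <- rowMeans(x_repeated)
  w <- rep(1, nrow(x_novel))
  new_linclf(w, midpoint_bias(w, mu_n, mu_r), mu_n, mu_r, method = "rs")
}

#' Classify population response vectors
#'
#' The class is determined by the sign of `f(x) = w . x - b`: positive is
#' novel, negative is repeated; the measure-zero tie `f(x) = 0` (possible
#' with integer counts) is resolved as repeated.
#'
#' @param clf A `linclf`.
#' @param x A response vector (length = units) or matrix (units x
#'   responses).
#' @return Character vector of `"novel"` / `"repeated"` labels.
#' @export
decide <- function(clf, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (nrow(x) != length(clf$w)) abort("dimension mismatch between classifier and responses.")
  f <- drop(crossprod(x, clf$w)) - clf$b
  ifelse(f > 0, "novel", "repeated")
}

#' Decision values of a classifier
#' @inheritParams decide
#' @return Numeric vector `w . x - b`.
#' @export
decision_values <- function(clf, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  drop(crossprod(x, clf$w)) - clf$b
}

train_clf <- function(x_novel, x_repeated, method = c("fld", "rs")) {
  method <- match.arg(method)
  if (method == "fld") fld_weights(x_novel, x_repeated)
  else rs_weights(x_novel, x_repeated)
}

#' Cross-validation folds stratified by memorability bin
#'
#' Pseudoimages are partitioned into folds; the novel and repeated
#' presentations of a pseudoimage always stay in the same fold. Folds are
#' balanced within memorability deciles so that each fold spans the score
#' range.
#'
#' @param pop A `pseudopop`.
#' @param n_folds Number of folds (>= 2).
#' @param seed Optional integer seed.
#' @return Integer vector of fold assignments per pseudoimage.
#' @export
make_folds <- function(pop, n_folds = 10, seed = NULL) {
  if (n_folds < 2) abort("n_folds must be >= 2.")
  n <- nrow(pop$pseudoimages)
  if (n < n_folds) abort("more folds than pseudoimages.")
  m <- pop$pseudoimages$memorability
  with_stream(seed, "folds", {
    # order by memorability with random tie-breaks, then deal folds out
    # round-robin: folds are balanced in size and span the score range
    ord <- order(m, runif(n))
    fold <- integer(n)
    fold[ord] <- rep_len(sample.int(n_folds), n)
    fold
  })
}

#' Cross-validated memory-decoding performance
#'
#' Trains the classifier on the complement of each fold and tests on the
#' held-out pseudoimages (both presentations). With
#' `shuffle_alignment_flag = TRUE` the memorability alignment of the
#' pseudopopulation is broken first (see [shuffle_alignment()]), which is
#' how the decoder is run when memorability should not confound it.
#'
#' @param pop A `pseudopop`.
#' @param method `"fld"` or `"rs"`.
#' @param window Spike-count window in ms.
#' @param n_folds Number of folds.
#' @param seed Optional integer seed (controls folds and any shuffling).
#' @param shuffle_alignment_flag Break memorability alignment before
#'   decoding.
#' @return A `cv_result` tibble with one row per fold: `fold`, `accuracy`,
#'   `acc_novel`, `acc_repeated`, `n_test`.
#' @export
cv_performance <- function(pop, method = c("fld", "rs"), window = c(300, 500),
                           n_folds = 10, seed = NULL,
                           shuffle_alignment_flag = FALSE) {
  method <- match.arg(method)
  if (shuffle_alignment_flag) pop <- shuffle_alignment(pop, seed = seed)
  folds <- make_folds(pop, n_folds, seed = seed)
  wc <- window_counts(pop, window)
  cv_from_counts(wc$novel, wc$repeated, folds, method)
}

cv_from_counts <- function(xn, xr, folds, method) {
  rows <- lapply(sort(unique(folds)), function(f) {
    te <- which(folds == f); tr <- which(folds != f)
    if (length(tr) < 2) abort("fold leaves no training data.")
    clf <- train_clf(xn[, tr, drop = FALSE], xr[, tr, drop = FALSE], method)
    pred_n <- decide(clf, xn[, te, drop = FALSE])
    pred_r <- decide(clf, xr[, te, drop = FALSE])
    tibble::tibble(
      fold = f,
      accuracy = mean(c(pred_n == "novel", pred_r == "repeated")),
      acc_novel = mean(pred_n == "novel"),
      acc_repeated = mean(pred_r == "repeated"),
      n_test = length(te)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cv_result", class(out))
  out
}

#' Sliding-window decoding time course
#'
#' [cv_performance()] in consecutive sliding windows, using the same folds
#' at every window (same seed), so the time course reflects signal
#' evolution rather than fold noise.
#'
#' @inheritParams cv_performance
#' @param window_len Window length in ms (default 150).
#' @param step Window step in ms (default 20).
#' @return A `decoding_timecourse` tibble: `window_start`, `window_end`,
#'   `accuracy` (mean across folds), `sd_folds`, `acc_novel`,
#'   `acc_repeated`.
#' @export
decoding_timecourse <- function(pop, method = c("fld", "rs"),
                                window_len = 150, step = 20, n_folds = 10,
                                seed = NULL, shuffle_alignment_flag = FALSE) {
  method <- match.arg(method)
  if (shuffle_alignment_flag) pop <- shuffle_alignment(pop, seed = seed)
  folds <- make_folds(pop, n_folds, seed = seed)
  t0 <- pop$bin_edges[1]
  t_end <- pop$bin_edges[length(pop$bin_edges)]
  starts <- seq(t0, t_end - window_len, by = step)
  rows <- lapply(starts, function(s) {
    wc <- window_counts(pop, c(s, s + window_len))
    cv <- cv_from_counts(wc$novel, wc$repeated, folds, method)
    tibble::tibble(window_start = s, window_end = s + window_len,
                   accuracy = mean(cv$accuracy), sd_folds = sd(cv$accuracy),
                   acc_novel = mean(cv$acc_novel),
                   acc_repeated = mean(cv$acc_repeated))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("decoding_timecourse", class(out))
  out
}

#' Ranked-FLD unit-removal curves
#'
#' Within each cross-validation iteration, FLD weights are computed on the
#' training fold, units are ranked by those signed weights, a fraction of
#' units is removed from one end of the ranking, and the weights and
#' threshold are recomputed on the remaining units before testing.
#'
#' @param pop A `pseudopop`.
#' @param window Spike-count window in ms.
#' @param removal_fractions Fractions of units to remove (in `[0, 1)`).
#' @param remove_end `"suppressed"` removes from the most positive (most
#'   repetition-suppressed) end, `"enhanced"` from the most negative end.
#' @param n_folds,seed As in [cv_performance()].
#' @return Tibble with `fraction_removed`, `remove_end`, `accuracy`,
#'   `sd_folds`.
#' @export
ranked_fld <- function(pop, window = c(300, 500),
                       removal_fractions = seq(0, 0.9, by = 0.1),
                       remove_end = c("suppressed", "enhanced"),
                       n_folds = 10, seed = NULL) {
  remove_end <- match.arg(remove_end)
  if (any(removal_fractions < 0 | removal_fractions >= 1)) {
    abort("removal fractions must lie in [0, 1); removing all units is not allowed.")
  }
  folds <- make_folds(pop, n_folds, seed = seed)
  wc <- window_counts(pop, window)
  n_units <- nrow(wc$novel)
  rows <- lapply(removal_fractions, function(fr) {
    accs <- vapply(sort(unique(folds)), function(f) {
      te <- which(folds == f); tr <- which(folds != f)
      clf0 <- fld_weights(wc$novel[, tr, drop = FALSE],
                          wc$repeated[, tr, drop = FALSE])
      n_rm <- floor(fr * n_units)
      ord <- order(clf0$w)  # ascending: enhanced first
      drop_idx <- if (n_rm == 0) integer(0)
        else if (remove_end == "suppressed") tail(ord, n_rm) else head(ord, n_rm)
      keep <- setdiff(seq_len(n_units), drop_idx)
      clf <- fld_weights(wc$novel[keep, tr, drop = FALSE],
                         wc$repeated[keep, tr, drop = FALSE])
      pred_n <- decide(clf, wc$novel[keep, te, drop = FALSE])
      pred_r <- decide(clf, wc$repeated[keep, te, drop = FALSE])
      mean(c(pred_n == "novel", pred_r == "repeated"))
    }, numeric(1))
    tibble::tibble(fraction_removed = fr, remove_end = remove_end,
                   accuracy = mean(accs), sd_folds = sd(accs))
  })
  dplyr::bind_rows(rows)
}
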