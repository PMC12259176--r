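## The memorability-corrected decoder: MB prototype axis, RS-MB plane
## geometry, rotated classifier family, plane projections with one-SD
## ellipses, the prediction-quality statistic, behavior prediction with
## rescaling, and the rotation sweep.

#' Memorability prototype classifier
#'
#' A "prototype" decoder separating high- from low-memorability images:
#' `w = mu_high - mu_low`, the difference between the mean population
#' response to images in the top and bottom halves of the (training)
#' memorability distribution. By default novel and repeated presentations
#' are pooled; the bias is the class-mean midpoint rule.
#'
#' @param x_novel,x_repeated Training matrices, units x pseudoimages.
#' @param memorability Per-pseudoimage memorability scores.
#' @param presentations `"pooled"`, `"novel"` or `"repeated"`: which
#'   presentations enter the class means.
#' @return A `linclf` object (method `"mb"`).
#' @export
mb_weights <- function(x_novel, x_repeated, memorability,
                       presentations = c("pooled", "novel", "repeated")) {
  presentations <- match.arg(presentations)
  if (sd(memorability) == 0) abort("all memorability scores identical; median split undefined.")
  med <- median(memorability)
  hi <- memorability > med
  if (!any(hi) || all(hi)) {
    # degenerate median (many ties): split at the median by rank instead
    hi <- rank(memorability, ties.method = "first") > length(memorability) / 2
  }
  x <- switch(presentations,
    pooled = cbind(x_novel, x_repeated),
    novel = x_novel,
    repeated = x_repeated
  )
  grp <- switch(presentations, pooled = c(hi, hi), novel = hi, repeated = hi)
  mu_h <- rowMeans(x[, grp, drop = FALSE])
  mu_l <- rowMeans(x[, !grp, drop = FALSE])
  w <- mu_h - mu_l
  new_linclf(w, midpoint_bias(w, mu_h, mu_l), mu_h, mu_l, method = "mb")
}

#' Geometry of the RS-MB plane
#'
#' The plane is spanned by the normalized all-ones repetition-suppression
#' axis and the unit memorability axis; `gamma` is the angle between them
#' in degrees.
#'
#' @param w_rs,w_mb Weight vectors (or `linclf` objects) for the RS and MB
#'   axes.
#' @param tol Degeneracy tolerance in degrees.
#' @return A `plane_geometry` object: `one_hat`, `mb_hat`, `gamma`
#'   (degrees).
#' @export
plane_gamma <- function(w_rs, w_mb, tol = 1e-4) {
  if (inherits(w_rs, "linclf")) w_rs <- w_rs$w
  if (inherits(w_mb, "linclf")) w_mb <- w_mb$w
  nr <- sqrt(sum(w_rs^2)); nm <- sqrt(sum(w_mb^2))
  if (nr == 0 || nm == 0) abort("zero vector cannot define the plane.")
  one_hat <- w_rs / nr
  mb_hat <- w_mb / nm
  cg <- sum(one_hat * mb_hat)
  gamma <- acos(pmin(1, pmax(-1, cg))) * 180 / pi
  if (gamma < tol || gamma > 180 - tol) {
    abort("RS and MB axes are collinear; the plane is degenerate.")
  }
  structure(list(one_hat = one_hat, mb_hat = mb_hat, gamma = gamma),
            class = "plane_geometry")
}

#' @export
print.plane_geometry <- function(x, ...) {
  cat(sprintf("<plane_geometry: %d units, gamma = %.2f deg>\n",
              length(x$one_hat), x$gamma))
  invisible(x)
}

#' Rotated decoder weights within the RS-MB plane
#'
#' `W(theta) = (cos(theta) - cot(gamma) sin(theta)) one_hat +
#' (csc(gamma) sin(theta)) mb_hat`. The result is unit-norm for every
#' `theta`, `W(0)` is the RS axis and `W(gamma)` is the MB axis; the angle
#' between `W(theta)` and the RS axis equals `theta`.
#'
#' @param theta Rotation in degrees from the RS axis.
#' @param geom A [plane_gamma()] geometry.
#' @return Numeric weight vector.
#' @export
rotated_weights <- function(theta, geom) {
  g <- geom$gamma * pi / 180
  th <- theta * pi / 180
  (cos(th) - sin(th) / tan(g)) * geom$one_hat + (sin(th) / sin(g)) * geom$mb_hat
}

#' Project population responses onto the RS-MB plane
#'
#' Each response is projected onto the plane spanned by the non-orthogonal
#' RS and MB axes and expressed in an orthonormal in-plane basis (the RS
#' axis and its in-plane orthogonal complement toward the MB axis), then
#' rotated within the plane for display; an isotropic cloud therefore
#' projects to a circle, and the MB axis sits `gamma` degrees from the RS
#' axis in the plot. Responses are grouped by condition and memorability
#' quartile (8 groups); for each group with at least 3 points, the
#' eigen-decomposition of the coordinate covariance gives the
#' one-standard-deviation ellipse.
#'
#' @param x_novel,x_repeated Response matrices, units x pseudoimages.
#' @param memorability Per-pseudoimage scores.
#' @param geom A [plane_gamma()] geometry.
#' @param rotate_view In-plane display rotation in degrees (default 45).
#' @return A `plane_projection` list: `points` tibble (`condition`,
#'   `quartile`, `u`, `v`) and `ellipses` tibble (`condition`, `quartile`,
#'   centers, axis lengths = sqrt eigenvalues, orientation in degrees).
#' @export
project_plane <- function(x_novel, x_repeated, memorability, geom,
                          rotate_view = 45) {
  g <- geom$gamma * pi / 180
  e1 <- geom$one_hat
  e2 <- (geom$mb_hat - cos(g) * e1) / sin(g)  # in-plane orthonormal complement
  coords <- function(x) {
    rbind(drop(crossprod(x, e1)), drop(crossprod(x, e2)))
  }
  a <- rotate_view * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  qs <- unname(quantile(memorability, probs = seq(0, 1, 0.25)))
  quart <- cut_quartile(memorability, qs)
  pts <- dplyr::bind_rows(
    tibble::tibble(condition = "novel", quartile = quart,
                   t(rot %*% coords(x_novel)) |> as.data.frame() |>
                     setNames(c("u", "v"))),
    tibble::tibble(condition = "repeated", quartile = quart,
                   t(rot %*% coords(x_repeated)) |> as.data.frame() |>
                     setNames(c("u", "v")))
  )
  ell <- pts |>
    dplyr::group_by(.data$condition, .data$quartile) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        return(tibble::tibble(center_u = NA_real_, center_v = NA_real_,
                              major = NA_real_, minor = NA_real_,
                              angle = NA_real_, ok = FALSE))
      }
      cv <- stats::cov(cbind(d$u, d$v))
      eg <- eigen(cv, symmetric = TRUE)
      tibble::tibble(center_u = mean(d$u), center_v = mean(d$v),
                     major = sqrt(eg$values[1]), minor = sqrt(max(0, eg$values[2])),
                     angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi,
                     ok = TRUE)
    }) |>
    dplyr::ungroup()
  structure(list(points = pts, ellipses = ell, rotate_view = rotate_view),
            class = "plane_projection")
}

#' Decoded behavioral predictions by memorability quartile
#'
#' Classifies held-out responses and reports the fraction classified
#' correctly per condition and memorability quartile (quartile boundaries
#' from the overall memorability distribution unless supplied).
#'
#' @param clf A `linclf`.
#' @param x_novel,x_repeated Held-out test matrices, units x pseudoimages.
#' @param memorability Per-pseudoimage scores for the test set.
#' @param boundaries Optional 5-vector of quartile boundaries.
#' @return Tibble with `condition`, `quartile`, `bin_center`, `accuracy`
#'   (fraction in `[0, 1]`), `n`.
#' @export
predict_behavior <- function(clf, x_novel, x_repeated, memorability,
                             boundaries = NULL) {
  boundaries <- boundaries %null%
    unname(quantile(memorability, probs = seq(0, 1, 0.25)))
  centers <- (boundaries[-1] + boundaries[-5]) / 2
  quart <- cut_quartile(memorability, boundaries)
  ok_n <- decide(clf, x_novel) == "novel"
  ok_r <- decide(clf, x_repeated) == "repeated"
  tibble::tibble(
    condition = rep(c("novel", "repeated"), each = length(quart)),
    quartile = rep(quart, 2),
    correct = c(ok_n, ok_r)
  ) |>
    dplyr::group_by(.data$condition, .data$quartile) |>
    dplyr::summarise(accuracy = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(bin_center = centers[.data$quartile]) |>
    dplyr::select("condition", "quartile", "bin_center", "accuracy", "n")
}

slope_angle_deg <- function(bin_center, accuracy) {
  atan(ls_slope(bin_center, accuracy)) * 180 / pi
}

#' Prediction quality of decoded behavior
#'
#' Fits least-squares lines to behavioral and predicted accuracy as a
#' function of memorability bin center (per condition), takes the angular
#' difference between the two slopes, reflects any difference above 90
#' degrees (`180 - delta`), and scores `PQ = 1 - delta / 90`: 1 when the
#' slopes are perfectly aligned, 0 when they are perpendicular. The final
#' PQ is the average of the novel and repeated PQs. Accuracies are
#' fractions in `[0, 1]` so slopes are commensurate with the memorability
#' axis.
#'
#' @param behavior,prediction Tibbles with `condition`, `bin_center`,
#'   `accuracy` (at least 2 bins per condition).
#' @return A `pq_result` tibble: one row per condition plus the averaged
#'   `pq` attached as attribute `pq_mean` and in the `pq` column of the
#'   `"mean"` row.
#' @export
pq <- function(behavior, prediction) {
  conds <- intersect(unique(behavior$condition), unique(prediction$condition))
  if (length(conds) == 0) abort("behavior and prediction share no condition.")
  rows <- lapply(conds, function(cc) {
    b <- behavior[behavior$condition == cc, ]
    p <- prediction[prediction$condition == cc, ]
    if (nrow(b) < 2 || nrow(p) < 2) abort("need at least 2 bins per condition.")
    ang_b <- slope_angle_deg(b$bin_center, b$accuracy)
    ang_p <- slope_angle_deg(p$bin_center, p$accuracy)
    d <- abs(ang_b - ang_p)
    if (d > 90) d <- 180 - d
    tibble::tibble(condition = cc, behavioral_angle = ang_b,
                   predicted_angle = ang_p, delta_theta = d,
                   pq = 1 - d / 90)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(condition = "mean", behavioral_angle = NA_real_,
                   predicted_angle = NA_real_,
                   delta_theta = mean(out$delta_theta),
                   pq = mean(out$pq))
  )
  class(out) <- c("pq_result", class(out))
  out
}

#' Rescale decoded predictions to the behavioral range
#'
#' Solves for the single multiplicative factor minimizing the squared error
#' between predicted and behavioral accuracies (closed form
#' `sum(p * b) / sum(p^2)`); the factor does not change the slope sign.
#' Rescaled values above 100% are clamped to 100 and flagged.
#'
#' @param prediction,behavior Tibbles with `condition`, `quartile`,
#'   `accuracy` (fractions).
#' @return Tibble joining the two with `rescaled_percent` and `clamped`,
#'   with the factor as attribute `"factor"`.
#' @export
rescale_predictions <- function(prediction, behavior) {
  j <- dplyr::inner_join(
    dplyr::rename(prediction, predicted = "accuracy"),
    dplyr::select(behavior, "condition", "quartile", behavioral = "accuracy"),
    by = c("condition", "quartile")
  )
  if (all(j$predicted == 0)) abort("all predictions are zero; rescaling undefined.")
  fac <- sum(j$predicted * j$behavioral) / sum(j$predicted^2)
  j$rescaled_percent <- pmin(100, 100 * fac * j$predicted)
  j$clamped <- 100 * fac * j$predicted > 100
  attr(j, "factor") <- fac
  j
}

#' Sweep of rotated decoders within the RS-MB plane
#'
#' Cross-validated: per fold, the MB axis is trained on the training
#' pseudoimages, the plane geometry is formed with the all-ones RS axis,
#' and for every rotation `theta` the rotated weights (bias refit by the
#' midpoint rule on training data) classify the held-out pseudoimages.
#' Test-set predictions are pooled across folds into per-quartile accuracy
#' curves, scored against behavior with [pq()], alongside overall memory
#' accuracy. The best-PQ rotation is the grid argmax (ties broken toward
#' the rotation orthogonal to the MB axis).
#'
#' @param pop A `pseudopop`.
#' @param behavior Behavioral benchmark tibble from
#'   [behavior_by_quartile()].
#' @param theta Grid of rotations in degrees. The default covers the full
#'   turn (0..359) because rotated decoders are signed vectors: `W(theta)`
#'   and `W(theta + 180)` define the same line but opposite decisions, and
#'   the behavior-aligned decoder can fall on either side of the RS axis.
#' @param window Spike-count window in ms (default 100-500).
#' @param n_folds,seed Cross-validation controls.
#' @param n_reps Number of repeated cross-validation rounds (different fold
#'   splits, same data); per-quartile accuracies are averaged across rounds,
#'   stabilizing the prediction slopes that enter the PQ statistic.
#' @param presentations Passed to [mb_weights()].
#' @return A `theta_sweep` tibble (`theta`, `pq_novel`, `pq_repeated`,
#'   `pq`, `accuracy`) with attributes `best_theta`, `gamma` (mean across
#'   folds) and `predictions` (per-theta pooled quartile accuracies).
#' @export
theta_sweep <- function(pop, behavior, theta = seq(0, 359, by = 1),
                        window = c(100, 500), n_folds = 10, seed = NULL,
                        n_reps = 1, presentations = "pooled") {
  wc <- window_counts(pop, window)
  mem <- pop$pseudoimages$memorability
  boundaries <- unname(quantile(mem, probs = seq(0, 1, 0.25)))
  centers <- (boundaries[-1] + boundaries[-5]) / 2
  n_units <- nrow(wc$novel)
  th <- theta * pi / 180
  gammas <- numeric(0)

  # accumulated per-theta test outcomes (averaged over CV repetitions)
  n_theta <- length(theta)
  correct_n <- matrix(0, n_theta, ncol(wc$novel))
  correct_r <- matrix(0, n_theta, ncol(wc$novel))

  for (rep_i in seq_len(n_reps)) {
    rep_seed <- if (is.null(seed)) NULL else seed + (rep_i - 1L) * 7919L
    folds <- make_folds(pop, n_folds, seed = rep_seed)
    for (f in sort(unique(folds))) {
      te <- which(folds == f); tr <- which(folds != f)
      xn_tr <- wc$novel[, tr, drop = FALSE]
      xr_tr <- wc$repeated[, tr, drop = FALSE]
      mb <- mb_weights(xn_tr, xr_tr, mem[tr], presentations = presentations)
      geom <- plane_gamma(rep(1, n_units), mb$w)
      gammas <- c(gammas, geom$gamma)
      g <- geom$gamma * pi / 180
      ca <- cos(th) - sin(th) / tan(g)   # coefficient on one_hat
      cb <- sin(th) / sin(g)             # coefficient on mb_hat
      # projections onto the two axes: train class means and test responses
      p1 <- function(x) drop(crossprod(x, geom$one_hat))
      p2 <- function(x) drop(crossprod(x, geom$mb_hat))
      mu_sum1 <- mean(p1(xn_tr)) + mean(p1(xr_tr))
      mu_sum2 <- mean(p2(xn_tr)) + mean(p2(xr_tr))
      b_theta <- 0.5 * (ca * mu_sum1 + cb * mu_sum2)
      tn1 <- p1(wc$novel[, te, drop = FALSE]); tn2 <- p2(wc$novel[, te, drop = FALSE])
      tr1 <- p1(wc$repeated[, te, drop = FALSE]); tr2 <- p2(wc$repeated[, te, drop = FALSE])
      f_n <- outer(ca, tn1) + outer(cb, tn2) - b_theta  # theta x test
      f_r <- outer(ca, tr1) + outer(cb, tr2) - b_theta
      correct_n[, te] <- correct_n[, te] + (f_n > 0) / n_reps
      correct_r[, te] <- correct_r[, te] + (f_r <= 0) / n_reps
    }
  }

  quart <- cut_quartile(mem, boundaries)
  pred_list <- vector("list", n_theta)
  rows <- lapply(seq_len(n_theta), function(i) {
    pred <- tibble::tibble(
      condition = rep(c("novel", "repeated"), each = length(mem)),
      quartile = rep(quart, 2),
      correct = c(correct_n[i, ], correct_r[i, ])
    ) |>
      dplyr::group_by(.data$condition, .data$quartile) |>
      dplyr::summarise(accuracy = mean(.data$correct), n = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(bin_center = centers[.data$quartile])
    pred_list[[i]] <<- pred
    pq_i <- pq(behavior, pred)
    tibble::tibble(
      theta = theta[i],
      pq_novel = pq_i$pq[pq_i$condition == "novel"],
      pq_repeated = pq_i$pq[pq_i$condition == "repeated"],
      pq = pq_i$pq[pq_i$condition == "mean"],
      accuracy = mean(c(correct_n[i, ], correct_r[i, ]))
    )
  })
  out <- dplyr::bind_rows(rows)
  gamma_mean <- mean(gammas)
  best <- which(out$pq == max(out$pq))
  if (length(best) > 1) {
    ortho <- (gamma_mean + 90) %% 180
    best <- best[which.min(pmin(abs(out$theta[best] - ortho),
                                180 - abs(out$theta[best] - ortho)))]
  }
  attr(out, "best_theta") <- out$theta[best]
  attr(out, "gamma") <- gamma_mean
  attr(out, "predictions") <- pred_list
  class(out) <- c("theta_sweep", class(out))
  out
}
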