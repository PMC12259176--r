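## broom-style tidiers for fitted objects.

#' Tidy a linear classifier
#'
#' @param x A `linclf`.
#' @param ... Unused.
#' @return Tibble with `unit_id` (index order when ids are unknown),
#'   `weight`, and the class means behind each weight.
#' @export
tidy.linclf <- function(x, ...) {
  tibble::tibble(
    unit_id = x$unit_ids %null% sprintf("u%04d", seq_along(x$w)),
    weight = x$w,
    mu1 = x$mu1,
    mu2 = x$mu2
  )
}

#' @rdname tidy.linclf
#' @export
glance.linclf <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_units = length(x$w),
    bias = x$b,
    weight_norm = sqrt(sum(x$w^2))
  )
}

#' Summarize a cross-validation result
#'
#' @param x A `cv_result` tibble (per-fold rows).
#' @param ... Unused.
#' @return One-row tibble with mean and SD across folds, overall and per
#'   condition.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x),
    accuracy = mean(x$accuracy),
    sd_folds = sd(x$accuracy),
    acc_novel = mean(x$acc_novel),
    acc_repeated = mean(x$acc_repeated)
  )
}

#' Summarize tuning fits
#'
#' @param x A `tuning_fits` tibble.
#' @param ... Unused.
#' @return One-row tibble with amplitude/decay medians, the mean
#'   suppression ratio and the convergence rate.
#' @export
glance.tuning_fits <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x),
    median_a_novel = median(x$a_novel),
    median_a_repeated = median(x$a_repeated),
    median_alpha = median(x$alpha),
    mean_suppression_ratio = mean(ifelse(x$a_novel > 0, x$a_repeated / x$a_novel, NA),
                                  na.rm = TRUE),
    converged_rate = mean(x$converged)
  )
}
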