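## Diagnostic ggplot2 figures for the main result types.

#' Plot GMFR against memorability
#'
#' Scatter of novel and repeated grand mean firing rates with least-squares
#' lines; the dashed line is the overall mean rate (the naive
#' population-vigor decision boundary).
#'
#' @param object A [gmfr()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gmfr_table <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("novel", "repeated"),
                              names_to = "condition", values_to = "gmfr")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$memorability, y = .data$gmfr,
                                     color = .data$condition)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = mean(long$gmfr), linetype = "dashed",
                        color = "grey40") +
    ggplot2::scale_color_manual(values = c(novel = "#2166ac", repeated = "#b2182b")) +
    ggplot2::labs(x = "memorability", y = "grand mean firing rate (sp/s)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window correlation time course
#' @param object A [correlation_timecourse()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_start, y = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(data = dplyr::filter(object, .data$significant),
                        size = 0.8, color = "black") +
    ggplot2::labs(x = "window start (ms from onset)",
                  y = "memorability-GMFR correlation (r)") +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window decoding time course
#' @param object A [decoding_timecourse()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_start, y = .data$accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$accuracy - .data$sd_folds,
                                      ymax = .data$accuracy + .data$sd_folds),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "window start (ms from onset)", y = "decoding accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#' @param object A [threshold_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot with the memorability correlation and memory accuracy
#'   against the modified fraction.
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "fraction", correlation = "r", accuracy = "accuracy"),
    c("correlation", "accuracy"), names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "fraction of tuning curve modified", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a rotation sweep
#' @param object A [theta_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot of PQ and memory accuracy against rotation, with the
#'   best-PQ rotation marked.
#' @export
autoplot.theta_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "theta", "pq", "accuracy"),
    c("pq", "accuracy"), names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$theta, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best_theta"),
                        linetype = "dashed", color = "grey40") +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "rotation from RS axis (deg)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot plane projections with one-SD ellipses
#' @param object A [project_plane()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plane_projection <- function(object, ...) {
  ell <- dplyr::filter(object$ellipses, .data$ok)
  tt <- seq(0, 2 * pi, length.out = 73)
  ell_pts <- dplyr::bind_rows(lapply(seq_len(nrow(ell)), function(i) {
    e <- ell[i, ]
    a <- e$angle * pi / 180
    u <- e$major * cos(tt); v <- e$minor * sin(tt)
    tibble::tibble(condition = e$condition, quartile = e$quartile,
                   u = e$center_u + u * cos(a) - v * sin(a),
                   v = e$center_v + u * sin(a) + v * cos(a))
  }))
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$u, y = .data$v,
                               color = .data$condition,
                               alpha = .data$quartile)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_path(data = ell_pts,
                       ggplot2::aes(group = interaction(.data$condition, .data$quartile))) +
    ggplot2::scale_color_manual(values = c(novel = "#2166ac", repeated = "#b2182b")) +
    ggplot2::scale_alpha_continuous(range = c(0.35, 1)) +
    ggplot2::labs(x = "in-plane coordinate 1", y = "in-plane coordinate 2",
                  color = NULL, alpha = "memorability\nquartile") +
    ggplot2::theme_minimal()
}
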