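#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an HRF kernel
#'
#' @param object An [canonical_hrf()] kernel.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hrf_kernel <- function(object, ...) {
  df <- tibble::tibble(
    time_s = seq(0, by = object$dt_seconds,
                 length.out = length(object$samples)),
    amplitude = object$samples)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "response (peak-normalised)",
                  title = "Canonical hemodynamic response") +
    ggplot2::theme_minimal()
}

#' Plot a BOLD or neuronal time series
#'
#' @param object A [bold_series()] or [neuronal_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bold_series <- function(object, ...) {
  df <- tibble::tibble(
    time_s = (seq_len(object$n_scans) - 1) * object$tr_seconds,
    value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "signal",
                  title = object$label %||% "BOLD series") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bold_series
#' @export
autoplot.neuronal_series <- function(object, ...) {
  df <- tibble::tibble(
    time_s = (seq_len(object$n_points) - 1) * object$dt_seconds,
    value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "activity (a.u.)",
                  title = "Neuronal-level series") +
    ggplot2::theme_minimal()
}

#' Histogram of a group t map
#'
#' @param object A [one_sample_t()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_map <- function(object, ...) {
  df <- tibble::tibble(t = object$t_values[object$mask])
  df <- df[is.finite(df$t), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$t)) +
    ggplot2::geom_histogram(bins = 80, fill = "grey40") +
    ggplot2::labs(x = "t statistic", y = "voxels",
                  title = sprintf("Group t map (n = %d, dof = %d)",
                                  object$n_subjects, object$dof)) +
    ggplot2::theme_minimal()
}

#' Bar-and-dot plot of deconvolved-vs-raw regressor correlations
#'
#' Mean correlation per ROI pair and sample as bars, individual subjects as
#' dots.
#'
#' @param per_subject Tibble with columns `pair`, `group`, `r` (from
#'   [run_deconv_comparison()]).
#' @return A ggplot.
#' @export
plot_deconv_comparison <- function(per_subject) {
  means <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$pair, .data$group),
    mean_r = mean(.data$r), .groups = "drop")
  ggplot2::ggplot() +
    ggplot2::geom_col(data = means,
                      ggplot2::aes(.data$pair, .data$mean_r,
                                   fill = .data$group),
                      position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7, alpha = 0.6) +
    ggplot2::geom_point(data = per_subject,
                        ggplot2::aes(.data$pair, .data$r,
                                     colour = .data$group),
                        position = ggplot2::position_jitterdodge(
                          dodge.width = 0.8, jitter.width = 0.15),
                        size = 0.8) +
    ggplot2::labs(x = "ROI pair", y = "Pearson r (deconvolved vs raw)") +
    ggplot2::theme_minimal()
}
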