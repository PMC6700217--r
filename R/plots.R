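#' Plot a power spectral density estimate
#'
#' dB PSD per channel on a shared frequency axis.
#' @param object A `spectral_estimate` from [epoch_psd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectral_estimate
#' @export
autoplot.spectral_estimate <- function(object, ...) {
  df <- tibble::tibble(
    freq_hz = rep(object$freqs, times = nrow(object$psd_db)),
    channel = rep(object$channel_labels, each = length(object$freqs)),
    psd_db = as.vector(t(object$psd_db))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$psd_db,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "PSD (dB re 1 µV²/Hz)",
                  colour = "Channel") +
    ggplot2::theme_minimal()
}

#' Plot real vs. permuted accuracy distributions
#'
#' Overlaid histograms of the real model's per-repetition cross-validated
#' accuracies and the label-permutation null means, the key visual for
#' judging whether the classifier beats chance.
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tidy.permutation_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$accuracy,
                                   fill = .data$distribution)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 20) +
    ggplot2::geom_vline(xintercept = 100 * object$real_mean, linetype = 2) +
    ggplot2::labs(x = "Cross-validated accuracy (%)", y = "Count",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot drinking trajectories by phenotype group
#'
#' Per-session g/kg consumed, one line per subject, coloured by group.
#' @param drinking Drinking tibble with `subject_id`, `session_index`,
#'   `g_per_kg` and a group/label column.
#' @param group_col Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_drinking <- function(drinking, group_col = "group") {
  ggplot2::ggplot(drinking,
                  ggplot2::aes(x = .data$session_index, y = .data$g_per_kg,
                               group = .data$subject_id,
                               colour = .data[[group_col]])) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Session", y = "Alcohol consumed (g/kg)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot single-feature importance
#'
#' Real accuracy per feature against its permutation-null 95th percentile,
#' flagged features highlighted.
#' @param importance A `feature_importance` tibble.
#' @param top_n Show only the top `top_n` features by real accuracy.
#' @return A ggplot object.
#' @export
plot_feature_importance <- function(importance, top_n = 20) {
  df <- dplyr::slice_head(importance, n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = 100 * .data$real_accuracy,
    y = stats::reorder(.data$feature, .data$real_accuracy),
    colour = .data$exceeds_null_95)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(ggplot2::aes(x = 100 * .data$null_p95), shape = 4,
                        colour = "grey40") +
    ggplot2::labs(x = "Single-feature CV accuracy (%)", y = NULL,
                  colour = "Above null 95th pct") +
    ggplot2::theme_minimal()
}
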