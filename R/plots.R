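# ggplot2 displays for synchrony tables and cluster solutions.

#' Plot EEG synchrony by region of interest
#'
#' EuDist per ROI (lower = stronger inter-member alignment), one panel per
#' frequency band, dyads as points with the phase-pooled mean overlaid.
#'
#' @param eeg_sync EEG synchrony tibble from [eeg_synchrony()] or
#'   `run_pipeline()$tables$eeg_synchrony`.
#' @param hemisphere Which cells to show (default the whole-ROI cells).
#' @return A ggplot object.
#' @export
plot_synchrony <- function(eeg_sync, hemisphere = "both") {
  d <- dplyr::filter(eeg_sync, .data$hemisphere == !!hemisphere)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roi, y = .data$eudist)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4, color = "firebrick") +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "EuDist (lower = stronger alignment)") +
    ggplot2::theme_minimal()
}

#' Plot a gap-statistic curve
#'
#' @param gap Result of [gap_statistic()].
#' @return A ggplot object.
#' @export
plot_gap <- function(gap) {
  ggplot2::ggplot(gap$table, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$se,
                                          ymax = .data$gap + .data$se)) +
    ggplot2::geom_vline(xintercept = gap$k_hat, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = gap$table$k) +
    ggplot2::labs(x = "number of clusters k", y = "gap statistic") +
    ggplot2::theme_minimal()
}

#' @rdname cluster_hrv
#' @param object An `hrv_clusters` object.
#' @export
autoplot.hrv_clusters <- function(object, ...) {
  cen <- as_tibble(object$centroids, rownames = "cluster") %>%
    tidyr::pivot_longer(-"cluster", names_to = "phase",
                        values_to = "value") %>%
    mutate(phase = factor(.data$phase, levels = task_phases()))
  ggplot2::ggplot(cen, ggplot2::aes(x = .data$phase, y = .data$value,
                                    color = .data$cluster,
                                    group = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "HRV synchrony feature (standardized)",
                  color = "cluster") +
    ggplot2::theme_minimal()
}
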