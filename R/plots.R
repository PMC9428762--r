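#' Plot a stress-strain hysteresis loop
#'
#' Draws the loading and unloading branches of one stress-strain cycle and
#' marks the peak (rightmost) point whose coordinates define peak strain
#' and peak stress.
#'
#' @param object A `stress_strain_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stress_strain_curve <- function(object, ...) {
  pk <- peak_point(object)
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$strain, y = .data$stress_kpa,
                                   colour = .data$phase)) +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::annotate("point", x = pk$peak_strain, y = pk$peak_stress,
                      size = 2.5) +
    ggplot2::labs(x = "Compressive strain (%)", y = "Stress (kPa)",
                  colour = NULL,
                  title = sprintf("Peak (%.1f%%, %.0f kPa), EDR %.1f%%",
                                  pk$peak_strain, pk$peak_stress,
                                  loop_areas(object)$edr)) +
    ggplot2::theme_minimal()
}

#' Plot the recorded channels of a stance recording
#'
#' Thickness, force and contact area against time over one stance phase.
#'
#' @param object A `stance_recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stance_recording <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("thickness_mm", "force_N", "area_cm2"),
                        names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cohort property plot
#'
#' Jittered per-leg values with group median/quartile boxes for one
#' material property, split by loading status.
#'
#' @param props A cohort property table (see [cohort_properties()]).
#' @param property Property column to plot.
#' @return A ggplot object.
#' @export
plot_cohort_property <- function(props, property = "viscous_modulus_kpa_s") {
  ggplot2::ggplot(props, ggplot2::aes(x = .data$group, y = .data[[property]],
                                      colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.2) +
    ggplot2::facet_wrap(~status) +
    ggplot2::labs(x = NULL, y = property) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
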