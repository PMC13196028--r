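#' Plot a simulated trajectory
#'
#' Resource pools and live biomass over time; OD600 (live biomass) is drawn
#' on top.
#'
#' @param object A `lysis_trajectory` from [simulate_lysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lysis_trajectory <- function(object, ...) {
  long <- tibble::tibble(
    time = rep(object$time, 4),
    value = c(object$C_g, object$C_l, object$B_WT, object$od),
    series = rep(c("glucose C_g", "lysate C_l", "WT biomass", "OD (live)"),
                 each = nrow(object))
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "OD-equivalent", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot replicate growth curves
#'
#' Replicate means with SD ribbons for a set of growth-curve datasets, on a
#' log OD scale.
#'
#' @param datasets A list of [growth_dataset] objects.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(datasets) {
  if (inherits(datasets, "growth_dataset")) datasets <- list(datasets)
  df <- dplyr::bind_rows(lapply(datasets, function(d) {
    tibble::tibble(mix = d$mix_label, time_h = d$times,
                   od = d$od_mean, sd = d$od_sd)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$od,
                                   colour = .data$mix,
                                   fill = .data$mix)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$od - .data$sd,
                                                  1e-6),
                                      ymax = .data$od + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "OD600", colour = "mix",
                  fill = "mix") +
    ggplot2::theme_minimal()
}

#' Plot single-cell growth-rate distributions by condition
#'
#' Violin plot of retained single-cell growth rates with per-replicate mean
#' overlays.
#'
#' @param records Growth-rate records from [filter_tracks()].
#' @return A ggplot object.
#' @export
plot_condition_rates <- function(records) {
  kept <- dplyr::filter(records, .data$rejected_reason == "none")
  rep_means <- dplyr::summarise(
    dplyr::group_by(kept, .data$condition, .data$replicate),
    mean_rate = mean(.data$rate), .groups = "drop"
  )
  ggplot2::ggplot(kept, ggplot2::aes(.data$condition, .data$rate)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey50") +
    ggplot2::geom_point(data = rep_means,
                        ggplot2::aes(y = .data$mean_rate,
                                     colour = .data$replicate),
                        size = 2) +
    ggplot2::labs(x = NULL, y = "growth rate (1/h)",
                  colour = "replicate") +
    ggplot2::theme_minimal()
}
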