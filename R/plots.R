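#' Plot saliency-fixation comparison metrics by scene category
#'
#' Bar chart (mean +/- SEM over participants) of D_KL, AUC and r for social
#' vs non-social scenes.
#'
#' @param metrics_by_participant Tibble from [analyze_cohort()]
#'   (`participant_id`, `category`, `d_kl`, `auc`, `r`).
#' @return A ggplot object.
#' @export
plot_metric_comparison <- function(metrics_by_participant) {
  df <- metrics_by_participant |>
    tidyr::pivot_longer(dplyr::all_of(c("d_kl", "auc", "r")),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric, .data$category) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$mean,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean over participants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot ROI gaze allocation and ROI saliency
#'
#' Bar charts (mean +/- SEM) of the area-normalized fixation density per
#' ROI (over participants) and of the relative saliency per ROI (over
#' scenes).
#'
#' @param roi_density_by_participant,roi_saliency_by_scene Tibbles from
#'   [analyze_cohort()].
#' @return A ggplot object (two facets).
#' @export
plot_roi_scores <- function(roi_density_by_participant,
                            roi_saliency_by_scene) {
  a <- roi_density_by_participant |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(mean = mean(.data$rel_norm_density),
                     sem = stats::sd(.data$rel_norm_density) /
                       sqrt(dplyr::n()), .groups = "drop") |>
    dplyr::mutate(panel = "area-normalized fixation density")
  b <- roi_saliency_by_scene |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(mean = mean(.data$rel_saliency),
                     sem = stats::sd(.data$rel_saliency) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(panel = "relative saliency")
  ggplot2::ggplot(dplyr::bind_rows(a, b),
                  ggplot2::aes(.data$roi, .data$mean)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "region of interest", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the early-fixation time course
#'
#' Line plots (mean +/- SEM over participants) of the foveal-window
#' relative saliency by fixation rank and category, and of the
#' area-normalized ROI hit frequency by fixation rank.
#'
#' @param ranked_saliency,ranked_roi Tibbles from [analyze_cohort()].
#' @return A list of two ggplot objects (`saliency`, `roi`).
#' @export
plot_time_course <- function(ranked_saliency, ranked_roi) {
  p1 <- ranked_saliency |>
    dplyr::group_by(.data$fixation_number, .data$category) |>
    dplyr::summarise(mean = mean(.data$rel_window_saliency),
                     sem = stats::sd(.data$rel_window_saliency) /
                       sqrt(dplyr::n()), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(.data$fixation_number, .data$mean,
                                 color = .data$category,
                                 group = .data$category)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = "fixation number", y = "relative window saliency") +
    ggplot2::theme_minimal()
  p2 <- ranked_roi |>
    dplyr::group_by(.data$fixation_number, .data$roi) |>
    dplyr::summarise(mean = mean(.data$norm_frequency),
                     sem = stats::sd(.data$norm_frequency) /
                       sqrt(dplyr::n()), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(.data$fixation_number, .data$mean,
                                 color = .data$roi, group = .data$roi)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = "fixation number",
                  y = "area-normalized ROI hit frequency") +
    ggplot2::theme_minimal()
  list(saliency = p1, roi = p2)
}

#' Plot decile-bin summaries of patch fixation density
#'
#' @param decile_bins Tibble from [analyze_cohort()] (`predictor`, `bin`,
#'   `mean_rel_fix_density`, `sem`).
#' @return A ggplot object faceted by predictor.
#' @export
plot_decile_bins <- function(decile_bins) {
  ggplot2::ggplot(decile_bins,
                  ggplot2::aes(.data$bin, .data$mean_rel_fix_density)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rel_fix_density - .data$sem,
                   ymax = .data$mean_rel_fix_density + .data$sem),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "predictor decile bin (0 = no coverage)",
                  y = "mean relative fixation density") +
    ggplot2::theme_minimal()
}
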