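#' Relative saliency in a foveal window around a fixation
#'
#' Mean saliency over the in-image pixels whose centers lie within a
#' circular window (default diameter 72 px, i.e. 2 degrees of visual angle
#' in the default geometry) around the fixation position, divided by the
#' mean saliency of the whole scene. Windows partially off-image are clipped
#' to the image; a window fully off-image yields NA.
#'
#' @param x,y Fixation position(s) in px (0-based; vectors allowed).
#' @param saliency A `saliency_map` or matrix.
#' @param diameter_px Window diameter in px (default 72).
#' @return Numeric vector of relative window saliencies.
#' @export
fixation_window_saliency <- function(x, y, saliency, diameter_px = 72) {
  s <- map_values(saliency)
  h <- nrow(s); w <- ncol(s)
  radius <- diameter_px / 2
  scene_mean <- mean(s)
  vapply(seq_along(x), function(i) {
    c0 <- max(0L, floor(x[i] - radius)); c1 <- min(w - 1L, ceiling(x[i] + radius))
    r0 <- max(0L, floor(y[i] - radius)); r1 <- min(h - 1L, ceiling(y[i] + radius))
    if (c0 > c1 || r0 > r1) return(NA_real_)
    cols <- c0:c1; rows <- r0:r1
    d2 <- outer((rows - y[i])^2, (cols - x[i])^2, `+`)
    inside <- d2 <= radius^2
    if (!any(inside)) return(NA_real_)
    mean(s[rows + 1L, cols + 1L, drop = FALSE][inside]) / scene_mean
  }, numeric(1))
}

# Pool fixation ranks into 1..max_rank plus a "6+" bin.
rank_bin <- function(rank, max_rank = 5L) {
  factor(ifelse(rank <= max_rank, as.character(rank),
                paste0(max_rank + 1, "+")),
         levels = c(as.character(seq_len(max_rank)),
                    paste0(max_rank + 1, "+")))
}

#' Early-fixation relative saliency by fixation rank and scene category
#'
#' For each participant, the mean relative foveal-window saliency
#' ([fixation_window_saliency()]) of the first `max_rank` fixations of each
#' trial (plus a pooled "6+" bin), separately per scene category. Trials
#' whose drift-correction baseline was replaced are excluded, since their
#' starting position is unreliable for early fixations.
#'
#' @param fixations Drift-corrected fixation tibble with `participant_id`,
#'   `trial_id`, `scene_id`, `rank`, `x`, `y` and (if present)
#'   `baseline_replaced`.
#' @param saliency_maps Named list of `saliency_map`s keyed by `scene_id`.
#' @param categories Tibble `scene_id`, `category`.
#' @param max_rank Number of individually resolved fixation ranks
#'   (default 5).
#' @return Tibble `participant_id`, `category`, `fixation_number`
#'   (factor 1..5, "6+"), `rel_window_saliency` (participant mean).
#' @export
ranked_saliency_table <- function(fixations, saliency_maps, categories,
                                  max_rank = 5L) {
  if ("baseline_replaced" %in% names(fixations)) {
    fixations <- dplyr::filter(fixations, !.data$baseline_replaced)
  }
  fixations |>
    dplyr::mutate(fixation_number = rank_bin(.data$rank, max_rank)) |>
    dplyr::group_by(.data$scene_id) |>
    dplyr::group_modify(function(df, key) {
      sal <- saliency_maps[[as.character(key$scene_id)]]
      df$rel_window_saliency <- fixation_window_saliency(df$x, df$y, sal)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$rel_window_saliency)) |>
    dplyr::inner_join(categories, by = "scene_id") |>
    dplyr::group_by(.data$participant_id, .data$category,
                    .data$fixation_number) |>
    dplyr::summarise(rel_window_saliency = mean(.data$rel_window_saliency),
                     .groups = "drop")
}

# ROI label of a fixation position; NA off-image.
roi_label_at <- function(x, y, roi_set) {
  h <- nrow(roi_set$head); w <- ncol(roi_set$head)
  px <- round(x); py <- round(y)
  vapply(seq_along(px), function(i) {
    if (px[i] < 0 || px[i] >= w || py[i] < 0 || py[i] >= h) {
      return(NA_character_)
    }
    r <- py[i] + 1L; c <- px[i] + 1L
    for (nm in roi_names) if (roi_set[[nm]][r, c]) return(nm)
    NA_character_
  }, character(1))
}

#' Area-normalized ROI hit frequencies by fixation rank
#'
#' For social scenes, determines which ROI each of the first `max_rank`
#' fixations landed on. Per participant and fixation rank, the relative
#' frequency of each ROI (hits divided by total in-image hits across ROIs)
#' is normalized by the mean area fraction of that ROI over exactly the
#' scenes contributing to the frequency. Off-image fixations are excluded;
#' baseline-replaced trials are excluded.
#'
#' @param fixations Drift-corrected fixation tibble (social trials), with
#'   `participant_id`, `trial_id`, `scene_id`, `rank`, `x`, `y`, optionally
#'   `baseline_replaced`.
#' @param roi_sets Named list of `roi_set`s keyed by `scene_id`.
#' @param max_rank Number of individually resolved ranks (default 5).
#' @return Tibble `participant_id`, `fixation_number`, `roi`,
#'   `rel_frequency` (sums to 1 over ROIs within participant x rank) and
#'   `norm_frequency` (area-normalized).
#' @export
ranked_roi_frequencies <- function(fixations, roi_sets, max_rank = 5L) {
  if ("baseline_replaced" %in% names(fixations)) {
    fixations <- dplyr::filter(fixations, !.data$baseline_replaced)
  }
  hits <- fixations |>
    dplyr::mutate(fixation_number = rank_bin(.data$rank, max_rank)) |>
    dplyr::group_by(.data$scene_id) |>
    dplyr::group_modify(function(df, key) {
      rs <- roi_sets[[as.character(key$scene_id)]]
      df$roi <- roi_label_at(df$x, df$y, rs)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$roi))

  area_tbl <- purrr::imap_dfr(roi_sets, function(rs, sid) {
    dplyr::mutate(rs$areas, scene_id = sid)
  })
  agg_ranked_roi(hits, area_tbl)
}

# Aggregate ROI hits (participant_id, scene_id, fixation_number, roi) into
# per-participant x rank relative and area-normalized frequencies, using
# the per-scene area table (scene_id, roi, area_fraction). The normalizer
# is the mean area of the ROI across exactly the scenes represented in the
# participant x rank cell.
agg_ranked_roi <- function(hits, area_tbl) {
  area_tbl$roi <- as.character(area_tbl$roi)
  hits |>
    dplyr::group_by(.data$participant_id, .data$fixation_number) |>
    dplyr::group_modify(function(df, key) {
      total <- nrow(df)
      scenes <- unique(as.character(df$scene_id))
      sub_area <- area_tbl[area_tbl$scene_id %in% scenes, ]
      purrr::map_dfr(roi_names, function(r) {
        n_hit <- sum(df$roi == r)
        mean_area <- mean(sub_area$area_fraction[sub_area$roi == r])
        tibble::tibble(
          roi = r,
          rel_frequency = n_hit / total,
          norm_frequency = (n_hit / total) / mean_area
        )
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(roi = factor(.data$roi, levels = roi_names))
}
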