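#' Four-region partition of a social scene
#'
#' Partitions every pixel of a social scene into head, body (excluding
#' heads), lower-saliency and higher-saliency regions. Among pixels outside
#' head and body, the 80th percentile ("eighth decile") of saliency is the
#' cut: pixels with saliency smaller than or equal to the threshold form the
#' lower-saliency region, the remainder the higher-saliency region. The
#' percentile uses midpoint interpolation (`stats::quantile` type 7) by
#' default; a sample order statistic (type 1) can be selected instead.
#'
#' @param head_mask,body_mask Logical matrices on the scene grid; head
#'   pixels are removed from the body mask if the drawn masks overlap.
#' @param saliency A `saliency_map` (or matrix) on the same grid.
#' @param quantile_type Passed to [stats::quantile()] (default 7,
#'   interpolated).
#' @return An object of class `roi_set`: list of four logical masks
#'   (`head`, `body`, `lower`, `higher`) that partition the scene, plus an
#'   `areas` tibble with per-ROI pixel counts and scene fractions.
#' @export
build_roi_set <- function(head_mask, body_mask, saliency, quantile_type = 7) {
  s <- map_values(saliency)
  stopifnot(identical(dim(head_mask), dim(s)),
            identical(dim(body_mask), dim(s)))
  body_mask <- body_mask & !head_mask
  social <- head_mask | body_mask
  if (all(social)) {
    stop("social masks cover the entire scene; no saliency split possible",
         call. = FALSE)
  }
  out <- s[!social]
  thr <- stats::quantile(out, 0.8, type = quantile_type, names = FALSE)
  lower <- !social & s <= thr
  higher <- !social & s > thr
  if (!any(higher)) {
    warning("constant saliency outside social regions: higher-saliency ROI is empty")
  }
  masks <- list(head = head_mask, body = body_mask,
                lower = lower, higher = higher)
  n_px <- length(s)
  areas <- tibble::tibble(
    roi = factor(names(masks), levels = names(masks)),
    n_pixels = unname(vapply(masks, sum, integer(1))),
    area_fraction = unname(vapply(masks, sum, integer(1))) / n_px
  )
  structure(c(masks, list(areas = areas)), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> area fractions:",
      paste(sprintf("%s %.3f", x$areas$roi, x$areas$area_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

roi_names <- c("head", "body", "lower", "higher")

#' Relative saliency per region of interest
#'
#' Mean saliency within each ROI divided by the mean saliency of the whole
#' scene; a uniform saliency map scores exactly 1 in every ROI, and the
#' area-weighted average across ROIs is exactly 1.
#'
#' @param roi_set A [build_roi_set()] result.
#' @param saliency A `saliency_map` or matrix on the same grid.
#' @return Tibble `roi`, `rel_saliency` (NA, flagged by `defined = FALSE`,
#'   for empty ROIs).
#' @export
roi_relative_saliency <- function(roi_set, saliency) {
  s <- map_values(saliency)
  scene_mean <- mean(s)
  purrr::map_dfr(roi_names, function(nm) {
    mask <- roi_set[[nm]]
    n <- sum(mask)
    tibble::tibble(
      roi = nm,
      rel_saliency = if (n > 0) mean(s[mask]) / scene_mean else NA_real_,
      defined = n > 0
    )
  }) |>
    dplyr::mutate(roi = factor(.data$roi, levels = roi_names))
}

#' Area-normalized fixation density per region of interest
#'
#' The proportion of the scene's total fixation density falling in each ROI,
#' divided by the ROI's fraction of scene area: a uniformly distributed
#' density scores exactly 1 in every ROI, values above 1 indicate
#' preferential fixation beyond what the region's size predicts.
#'
#' @param roi_set A [build_roi_set()] result.
#' @param density A `density_map` or matrix from a valid trial.
#' @return Tibble `roi`, `proportion`, `rel_norm_density`.
#' @export
roi_norm_fixation_density <- function(roi_set, density) {
  d <- map_values(density)
  total <- sum(d)
  if (total <= 0) stop("density map has zero total mass", call. = FALSE)
  purrr::map_dfr(roi_names, function(nm) {
    mask <- roi_set[[nm]]
    frac <- roi_set$areas$area_fraction[roi_set$areas$roi == nm]
    prop <- sum(d[mask]) / total
    tibble::tibble(
      roi = nm,
      proportion = prop,
      rel_norm_density = if (frac > 0) prop / frac else NA_real_
    )
  }) |>
    dplyr::mutate(roi = factor(.data$roi, levels = roi_names))
}
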