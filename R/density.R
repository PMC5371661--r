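#' Duration-weighted fixation density map
#'
#' Each fixation's duration (ms) is additively assigned to an all-zero
#' accumulator at the fixation's rounded pixel position; the accumulator is
#' then smoothed with an isotropic two-dimensional Gaussian kernel
#' (`sigma_px`, truncated at 4 sigma, zero padding beyond the image border)
#' and min-max normalized to \[0, 1\]. The default sigma of 36 px
#' corresponds to 1 degree of visual angle in the default geometry, so the
#' +/- 2 sigma kernel span resembles the functional field of the fovea.
#'
#' Because the accumulator contains only isolated impulses, the smoothing is
#' computed as a direct sum of truncated Gaussian kernels placed at the
#' fixation pixels, which equals the full convolution exactly.
#'
#' @param fixations Fixation tibble for a single participant x scene
#'   (columns `x`, `y` in px, `duration` in ms). Off-image fixations are
#'   dropped with a warning.
#' @param geometry A [viewing_geometry()] (supplies the map dimensions).
#' @param sigma_px Gaussian kernel standard deviation in pixels (default 36).
#' @param participant_id,scene_id Identifiers attached to the map.
#' @return A `density_map` with values in \[0, 1\] (all zero, flagged via
#'   `n_fixations = 0`, when no fixation contributes).
#' @export
build_density_map <- function(fixations, geometry, sigma_px = 36,
                              participant_id = NA_character_,
                              scene_id = NA_character_) {
  stopifnot(sigma_px > 0)
  h <- geometry$image_height_px
  w <- geometry$image_width_px
  px <- round(fixations$x)
  py <- round(fixations$y)
  on_image <- px >= 0 & px < w & py >= 0 & py < h
  if (any(!on_image)) {
    warning(sprintf("%d off-image fixation(s) dropped", sum(!on_image)))
  }
  px <- px[on_image]; py <- py[on_image]
  dur <- fixations$duration[on_image]
  if (length(px) == 0L) {
    return(new_density_map(array(0, dim = c(h, w)), participant_id, scene_id,
                           0L, 0))
  }

  half <- ceiling(4 * sigma_px)
  offs <- (-half):half
  k1 <- exp(-offs^2 / (2 * sigma_px^2))
  k1 <- k1 / sum(k1)  # normalized 1-D kernel; outer product = 2-D kernel

  m <- array(0, dim = c(h, w))
  for (i in seq_along(px)) {
    rows <- (py[i] + 1L) + offs
    cols <- (px[i] + 1L) + offs
    okr <- rows >= 1L & rows <= h
    okc <- cols >= 1L & cols <= w
    m[rows[okr], cols[okc]] <- m[rows[okr], cols[okc]] +
      dur[i] * (k1[okr] %o% k1[okc])
  }
  new_density_map(minmax01(m), participant_id, scene_id,
                  length(px), sum(dur))
}

# Raw (pre-normalization) impulse accumulator; exposed for mass-conservation
# checks.
density_accumulator <- function(fixations, geometry) {
  h <- geometry$image_height_px
  w <- geometry$image_width_px
  m <- array(0, dim = c(h, w))
  px <- round(fixations$x); py <- round(fixations$y)
  ok <- px >= 0 & px < w & py >= 0 & py < h
  for (i in which(ok)) {
    m[py[i] + 1L, px[i] + 1L] <- m[py[i] + 1L, px[i] + 1L] +
      fixations$duration[i]
  }
  m
}
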