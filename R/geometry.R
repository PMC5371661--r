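#' Viewing geometry of the eye-tracking setup
#'
#' Bundles the physical screen dimensions, viewing distance and image raster
#' size needed to convert between pixels and degrees of visual angle. The
#' default values describe a 30.6 x 23.0 cm stimulus viewed from 52.5 cm,
#' rendered at 1200 x 900 px, which subtends 32.5 x 24.7 degrees.
#'
#' @param screen_width_cm Physical stimulus width in cm.
#' @param screen_height_cm Physical stimulus height in cm.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @param image_width_px Image width in pixels.
#' @param image_height_px Image height in pixels.
#' @return An object of class `viewing_geometry`: a list with the five fields
#'   plus the derived full horizontal/vertical visual angles and
#'   pixels-per-degree scale factors.
#' @examples
#' geom <- viewing_geometry()
#' geom$angle_x_deg  # ~32.5
#' @export
viewing_geometry <- function(screen_width_cm = 30.6,
                             screen_height_cm = 23.0,
                             viewing_distance_cm = 52.5,
                             image_width_px = 1200L,
                             image_height_px = 900L) {
  stopifnot(
    screen_width_cm > 0, screen_height_cm > 0, viewing_distance_cm > 0,
    image_width_px > 0, image_height_px > 0
  )
  angle_x <- visual_angle_deg(screen_width_cm, viewing_distance_cm)
  angle_y <- visual_angle_deg(screen_height_cm, viewing_distance_cm)
  structure(
    list(
      screen_width_cm = screen_width_cm,
      screen_height_cm = screen_height_cm,
      viewing_distance_cm = viewing_distance_cm,
      image_width_px = as.integer(image_width_px),
      image_height_px = as.integer(image_height_px),
      angle_x_deg = angle_x,
      angle_y_deg = angle_y,
      px_per_deg_x = image_width_px / angle_x,
      px_per_deg_y = image_height_px / angle_y
    ),
    class = "viewing_geometry"
  )
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat(sprintf(
    "<viewing_geometry> %.1f x %.1f cm @ %.1f cm -> %.1f x %.1f deg; %d x %d px (%.2f px/deg horizontal)\n",
    x$screen_width_cm, x$screen_height_cm, x$viewing_distance_cm,
    x$angle_x_deg, x$angle_y_deg, x$image_width_px, x$image_height_px,
    x$px_per_deg_x
  ))
  invisible(x)
}

#' Visual angle subtended by a physical extent
#'
#' Uses the exact tangent formula `2 * atan(extent / (2 * distance))`,
#' returned in degrees. Monotone increasing in the extent and symmetric in
#' sign; zero extent gives zero angle.
#'
#' @param extent_cm Physical extent in cm (may be a vector).
#' @param distance_cm Viewing distance in cm; must be strictly positive.
#' @return Visual angle(s) in degrees.
#' @examples
#' visual_angle_deg(30.6, 52.5)  # ~32.5
#' @export
visual_angle_deg <- function(extent_cm, distance_cm) {
  if (any(distance_cm <= 0)) {
    stop("`distance_cm` must be strictly positive.", call. = FALSE)
  }
  2 * atan(extent_cm / (2 * distance_cm)) * 180 / pi
}

#' Convert degrees of visual angle to pixels (and back)
#'
#' Linear small-angle scaling by the geometry's pixels-per-degree factor for
#' the requested axis, so that the full image extent maps exactly to the full
#' visual angle.
#'
#' @param angle_deg Angle(s) in degrees.
#' @param geometry A [viewing_geometry()] object.
#' @param axis `"x"` (horizontal, default) or `"y"`.
#' @return Extent in pixels.
#' @export
deg_to_px <- function(angle_deg, geometry, axis = c("x", "y")) {
  axis <- match.arg(axis)
  scale <- if (axis == "x") geometry$px_per_deg_x else geometry$px_per_deg_y
  angle_deg * scale
}

#' @rdname deg_to_px
#' @param px Extent in pixels.
#' @export
px_to_deg <- function(px, geometry, axis = c("x", "y")) {
  axis <- match.arg(axis)
  scale <- if (axis == "x") geometry$px_per_deg_x else geometry$px_per_deg_y
  px / scale
}

# Euclidean pixel distance -> degrees, using the mean of the two axis scales
# (the default raster is very nearly isotropic: 36.9 vs 36.4 px/deg).
px_dist_to_deg <- function(d_px, geometry) {
  d_px / mean(c(geometry$px_per_deg_x, geometry$px_per_deg_y))
}
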