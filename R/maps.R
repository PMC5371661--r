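#' Map containers
#'
#' Saliency and fixation density maps are real-valued matrices on the scene's
#' pixel grid, stored row-major with row 1 = top of the image (matrix row =
#' pixel y + 1, matrix column = pixel x + 1; pixel coordinates are 0-based).
#'
#' @name map-containers
NULL

new_saliency_map <- function(values, scene_id = NA_character_) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(list(values = values, scene_id = scene_id), class = "saliency_map")
}

new_density_map <- function(values, participant_id = NA_character_,
                            scene_id = NA_character_, n_fixations = 0L,
                            total_duration_ms = 0) {
  stopifnot(is.matrix(values))
  structure(
    list(
      values = values, participant_id = participant_id, scene_id = scene_id,
      n_fixations = as.integer(n_fixations),
      total_duration_ms = total_duration_ms
    ),
    class = "density_map"
  )
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf(
    "<saliency_map> scene %s: %d x %d px, range [%.3g, %.3g]\n",
    x$scene_id, ncol(x$values), nrow(x$values),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> participant %s, scene %s: %d fixations, %.0f ms\n",
    x$participant_id, x$scene_id, x$n_fixations, x$total_duration_ms
  ))
  invisible(x)
}

map_values <- function(map) {
  if (is.matrix(map)) map else map$values
}

# min-max rescale to [0, 1]; a constant matrix maps to all zeros.
minmax01 <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) {
    array(0, dim = dim(m))
  } else {
    (m - rng[1]) / (rng[2] - rng[1])
  }
}

#' Load a saliency map from a float-matrix file
#'
#' Reads a single-channel float matrix stored as TIFF (32-bit float) or as a
#' plain TSV of numbers, and min-max rescales it to the unit interval if it
#' is not already inside it. A map already in \[0, 1\] is returned unchanged.
#'
#' @param path File path (`.tif`/`.tiff` or text matrix).
#' @param scene_id Identifier attached to the map.
#' @param expected_dim Optional `c(height, width)`; a mismatch is an error.
#' @return A `saliency_map`.
#' @export
load_saliency_map <- function(path, scene_id = NA_character_,
                              expected_dim = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = FALSE)
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  if (!is.null(expected_dim) && !identical(dim(m), as.integer(expected_dim))) {
    stop(sprintf(
      "saliency map %s is %d x %d, expected %d x %d",
      path, nrow(m), ncol(m), expected_dim[1], expected_dim[2]
    ), call. = FALSE)
  }
  m <- minmax01(m)  # idempotent for maps already spanning [0, 1]
  new_saliency_map(m, scene_id)
}

#' Write a saliency or density map to a 32-bit float TIFF
#'
#' @param map A `saliency_map`, `density_map`, or plain matrix.
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  m <- map_values(map)
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  invisible(path)
}

#' Summarize a map's pixel values
#'
#' @param map A `saliency_map`, `density_map`, or matrix.
#' @return A one-row tibble with `mean` and `sd` (sample SD, n - 1
#'   denominator) of all pixel values.
#' @export
map_summary <- function(map) {
  v <- as.vector(map_values(map))
  tibble::tibble(mean = mean(v), sd = stats::sd(v))
}
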