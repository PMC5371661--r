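#' Reference bottom-up saliency model
#'
#' A simplified Itti-Koch-style center-surround saliency model used as a
#' documented, pluggable stand-in for any external saliency model: feature
#' channels for intensity, two color-opponency axes (R-G, B-Y) and four
#' orientation-energy channels, each band-pass filtered
#' (difference-of-Gaussians) at `n_scales` dyadic scales, summed across
#' scales, max-normalized per channel, and averaged with equal weights.
#' An optional isotropic Gaussian center-bias field can be multiplied in.
#' The output is min-max normalized to \[0, 1\].
#'
#' Saliency maps for externally computed models (e.g. graph-based saliency)
#' can be supplied instead through [load_saliency_map()]; every downstream
#' stage is agnostic to the map's origin.
#'
#' @param image Either an `height x width x 3` array with values in \[0, 1\]
#'   (RGB) or a grayscale matrix (color channels are then zero, with a
#'   warning).
#' @param n_scales Number of dyadic center-surround scales (default 4).
#' @param center_bias_strength Non-negative multiplier of the squared
#'   normalized distance from image center in the Gaussian bias field
#'   `exp(-strength * d_norm^2)`; 0 (default) disables the bias.
#' @param scene_id Identifier attached to the resulting map.
#' @return A `saliency_map` with values in \[0, 1\].
#' @export
compute_reference_saliency <- function(image, n_scales = 4L,
                                       center_bias_strength = 0,
                                       scene_id = NA_character_) {
  if (is.matrix(image)) {
    warning("grayscale input: color-opponency channels are zero")
    gray <- image
    rg <- by <- array(0, dim = dim(gray))
  } else {
    stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
    r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
    gray <- (r + g + b) / 3
    rg <- r - g
    by <- b - (r + g) / 2
  }
  if (nrow(gray) < 64 || ncol(gray) < 64) {
    stop("image must be at least 64 px in each dimension", call. = FALSE)
  }
  stopifnot(n_scales >= 1, center_bias_strength >= 0)

  orients <- lapply(c(0, 45, 90, 135) * pi / 180, function(theta) {
    abs(conv2d(gray, gabor_kernel(theta)))
  })
  channels <- c(list(gray, rg, by), orients)

  consp <- lapply(channels, function(f) {
    acc <- array(0, dim = dim(f))
    for (s in seq_len(n_scales)) {
      sigma_c <- 1.5 * 2^(s - 1)
      acc <- acc + abs(gauss_blur(f, sigma_c) - gauss_blur(f, 3 * sigma_c))
    }
    mx <- max(acc)
    # guard against amplifying numerical dust on featureless channels
    if (mx > 1e-9) acc / mx else array(0, dim = dim(f))
  })

  sal <- Reduce(`+`, consp) / length(consp)

  if (center_bias_strength > 0) {
    h <- nrow(sal); w <- ncol(sal)
    cy <- (h - 1) / 2; cx <- (w - 1) / 2
    d2 <- outer((seq_len(h) - 1 - cy)^2, (seq_len(w) - 1 - cx)^2, `+`)
    sal <- sal * exp(-center_bias_strength * d2 / (cx^2 + cy^2))
  }

  new_saliency_map(minmax01(sal), scene_id)
}

# --- small convolution helpers (zero padding) ------------------------------

# 1-D zero-padded convolution of each row/column with a symmetric kernel,
# via direct shift-and-add (kernels here are short).
conv1d_zero <- function(m, k, along = c("rows", "cols")) {
  along <- match.arg(along)
  half <- (length(k) - 1L) / 2L
  out <- array(0, dim = dim(m))
  n <- if (along == "rows") ncol(m) else nrow(m)
  for (j in seq_along(k)) {
    off <- j - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    if (along == "rows") {
      out[, which(ok)] <- out[, which(ok)] + k[j] * m[, src[ok]]
    } else {
      out[which(ok), ] <- out[which(ok), ] + k[j] * m[src[ok], ]
    }
  }
  out
}

# Separable Gaussian blur, truncated at 4 sigma, with border renormalization
# (dividing by the blurred all-ones field) so constant regions stay constant
# up to the image edge.
gauss_blur <- function(m, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  num <- conv1d_zero(conv1d_zero(m, k, "rows"), k, "cols")
  ones <- array(1, dim = dim(m))
  den <- conv1d_zero(conv1d_zero(ones, k, "rows"), k, "cols")
  num / den
}

# Dense 2-D convolution with a small kernel, replicate padding (so
# zero-mean kernels respond zero on constant regions, including borders).
conv2d <- function(m, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  hy <- (kh - 1L) / 2L; hx <- (kw - 1L) / 2L
  h <- nrow(m); w <- ncol(m)
  out <- array(0, dim = c(h, w))
  for (i in seq_len(kh)) {
    ry <- pmin(pmax(seq_len(h) + (i - 1L - hy), 1L), h)
    for (j in seq_len(kw)) {
      if (kern[i, j] == 0) next
      rx <- pmin(pmax(seq_len(w) + (j - 1L - hx), 1L), w)
      out <- out + kern[i, j] * m[ry, rx]
    }
  }
  out
}

# Even (cosine-phase) Gabor kernel, zero-mean so constant regions respond 0.
gabor_kernel <- function(theta, sigma = 2, lambda = 6, gamma = 0.8) {
  half <- ceiling(3 * sigma)
  g <- outer((-half):half, (-half):half, function(y, x) {
    xp <- x * cos(theta) + y * sin(theta)
    yp <- -x * sin(theta) + y * cos(theta)
    exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / lambda)
  })
  g - mean(g)
}
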