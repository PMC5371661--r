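#' Compare a saliency map with a fixation density map
#'
#' Computes three metrics of divergence/correspondence between physical
#' saliency and empirical fixation density on the same pixel grid:
#'
#' * `d_kl`: Kullback-Leibler divergence D(F || S) of the sum-normalized
#'   density F from the sum-normalized saliency S (natural log by default) —
#'   larger means saliency describes the fixation distribution worse.
#' * `auc`: area under the ROC curve for predicting above-mean density
#'   pixels from saliency scores (midrank Mann-Whitney formulation); 0.5 is
#'   chance level.
#' * `r`: Pearson correlation of the two sum-normalized maps over all
#'   pixels.
#'
#' Before the KL computation, `epsilon` is added to every cell of both maps
#' and each map is rescaled to sum to 1 (this also regularizes empty
#' regions against log 0).
#'
#' @param saliency A `saliency_map` (or matrix).
#' @param density A `density_map` (or matrix) of the same dimensions; must
#'   stem from at least one fixation.
#' @param epsilon Regularization constant added to every cell (default
#'   1e-12).
#' @param log_base Base of the KL logarithm (default `exp(1)`, nats).
#' @param saliency_ranks Optional precomputed `rank(saliency values,
#'   ties.method = "average")`, reusable across participants viewing the
#'   same scene.
#' @return One-row tibble: `d_kl`, `auc`, `r`, `r_defined` (FALSE when the
#'   saliency map is constant, in which case `r` is reported as 0 and `auc`
#'   as 0.5 by convention).
#' @export
compare_maps <- function(saliency, density, epsilon = 1e-12,
                         log_base = exp(1), saliency_ranks = NULL) {
  s <- map_values(saliency)
  f <- map_values(density)
  if (!identical(dim(s), dim(f))) {
    stop("saliency and density maps differ in shape", call. = FALSE)
  }
  if (!is.matrix(density) && density$n_fixations == 0L) {
    stop("density map has no fixations", call. = FALSE)
  }
  if (all(f == f[1L])) stop("density map is constant", call. = FALSE)

  sv <- as.vector(s)
  fv <- as.vector(f)
  sn <- (sv + epsilon); sn <- sn / sum(sn)
  fn <- (fv + epsilon); fn <- fn / sum(fn)

  d_kl <- sum(fn * (log(fn) - log(sn))) / log(log_base)

  constant_sal <- all(sv == sv[1L])
  if (constant_sal) {
    auc <- 0.5
    r <- 0
  } else {
    labels <- fv > mean(fv)
    rk <- if (is.null(saliency_ranks)) {
      rank(sv, ties.method = "average")
    } else {
      saliency_ranks
    }
    n1 <- as.numeric(sum(labels))
    n0 <- length(labels) - n1
    auc <- (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    r <- stats::cor(fn, sn)
  }
  tibble::tibble(d_kl = d_kl, auc = auc, r = r, r_defined = !constant_sal)
}

#' Aggregate map-comparison metrics by participant and scene category
#'
#' Per participant, the arithmetic mean of each metric over valid trials of
#' each scene category; the resulting table feeds paired tests contrasting
#' social vs non-social scenes.
#'
#' @param results Per-trial tibble with `participant_id`, `scene_id`,
#'   `d_kl`, `auc`, `r`.
#' @param trials Per-trial validity tibble (`participant_id`, `trial_id` or
#'   `scene_id`, `valid`); invalid trials are excluded.
#' @param categories Tibble `scene_id`, `category`.
#' @return Tibble `participant_id`, `category`, `d_kl`, `auc`, `r` (means).
#'   Participants with zero valid trials in a category are dropped with a
#'   warning.
#' @export
aggregate_by_category <- function(results, trials, categories) {
  key <- intersect(c("trial_id", "scene_id"), names(trials))[1]
  valid <- trials |>
    dplyr::filter(.data$valid) |>
    dplyr::select(dplyr::all_of(c("participant_id", key)))
  out <- results |>
    dplyr::inner_join(valid, by = intersect(names(results), names(valid))) |>
    dplyr::inner_join(categories, by = "scene_id") |>
    dplyr::group_by(.data$participant_id, .data$category) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("d_kl", "auc", "r")),
                                   mean), .groups = "drop")
  n_cat <- length(unique(categories$category))
  counts <- dplyr::count(out, .data$participant_id)
  if (any(counts$n < n_cat)) {
    warning("some participants lack valid trials in a category")
  }
  out
}
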