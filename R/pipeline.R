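#' Run the full gaze analysis on a cohort in memory
#'
#' Executes every stage of the analysis on a (typically synthetic) cohort:
#' drift correction, per-trial fixation density maps, saliency-density
#' comparison metrics with per-participant category means and paired tests,
#' ROI saliency and area-normalized ROI fixation density with
#' repeated-measures ANOVAs, the early-fixation time course (foveal-window
#' saliency by fixation rank and area-normalized ROI hit frequencies), and
#' the scene-patch mixed-model ladder with likelihood-ratio comparisons and
#' decile-bin summaries. Scenes are regenerated one at a time from their
#' seeds, so memory stays flat in the number of scenes.
#'
#' @param cohort A [generate_cohort()] result (fixation-level).
#' @param sigma_px Density-map Gaussian SD in px (default 36).
#' @param window_diameter_px Foveal window diameter in px (default 72).
#' @param models Model-ladder ids to fit (default
#'   `c("1a","2","3a","4","5a","6")`); `NULL` skips the mixed models.
#' @param epsilon Regularization for the comparison metrics.
#' @param max_rank Individually resolved fixation ranks (default 5).
#' @return A list of result tables (all tibbles):
#'   `metrics_by_trial`, `metrics_by_participant`, `metric_tests`,
#'   `roi_saliency_by_scene`, `roi_saliency_anova`,
#'   `roi_density_by_participant`, `roi_density_anova`, `roi_posthoc`,
#'   `ranked_saliency`, `ranked_saliency_anova`, `ranked_roi`,
#'   `ranked_roi_anova`, `patch_table`, `model_fits` (list of
#'   `patch_lmm_fit`), `model_summary`, `lrt_table`, `decile_bins`.
#' @export
analyze_cohort <- function(cohort, sigma_px = 36, window_diameter_px = 72,
                           models = c("1a", "2", "3a", "4", "5a", "6"),
                           epsilon = 1e-12, max_rank = 5L) {
  geometry <- cohort$geometry
  cross <- cohort$truth$cross
  corrected <- drift_correct(cohort$fixations, cohort$baselines,
                             cross_position = cross)
  valid_trials <- cohort$trials[cohort$trials$valid, ]
  corrected <- dplyr::semi_join(
    corrected, valid_trials, by = c("participant_id", "trial_id")
  )

  metric_rows <- list(); roi_sal_rows <- list(); roi_den_rows <- list()
  patch_rows <- list(); fixrows <- list(); area_rows <- list()

  for (si in seq_len(nrow(cohort$scenes))) {
    sid <- cohort$scenes$scene_id[si]
    category <- cohort$scenes$category[si]
    scene <- cohort_scene(cohort, sid)
    sal <- scene$saliency
    sal_ranks <- rank(as.vector(sal$values), ties.method = "average")
    scene_fix <- corrected[corrected$scene_id == sid, ]
    if (nrow(scene_fix) == 0L) next

    roi_set <- NULL
    if (category == "social") {
      roi_set <- build_roi_set(scene$head_mask, scene$body_mask, sal)
      roi_sal_rows[[sid]] <- roi_relative_saliency(roi_set, sal) |>
        dplyr::mutate(scene_id = sid)
      area_rows[[sid]] <- dplyr::mutate(roi_set$areas, scene_id = sid)
    }

    # per-fixation window saliency and ROI label (time course)
    fr <- scene_fix[c("participant_id", "scene_id", "rank", "x", "y",
                      "baseline_replaced", "duration")]
    fr$rel_window_saliency <-
      fixation_window_saliency(fr$x, fr$y, sal, window_diameter_px)
    fr$roi <- if (is.null(roi_set)) NA_character_ else
      roi_label_at(fr$x, fr$y, roi_set)
    fr$category <- category
    fixrows[[sid]] <- fr

    for (p in unique(scene_fix$participant_id)) {
      pf <- scene_fix[scene_fix$participant_id == p, ]
      dm <- build_density_map(pf, geometry, sigma_px,
                              participant_id = p, scene_id = sid)
      if (dm$n_fixations == 0L) next
      cmp <- compare_maps(sal, dm, epsilon, saliency_ranks = sal_ranks)
      metric_rows[[length(metric_rows) + 1L]] <-
        dplyr::mutate(cmp, participant_id = p, scene_id = sid,
                      category = category)
      if (!is.null(roi_set)) {
        roi_den_rows[[length(roi_den_rows) + 1L]] <-
          roi_norm_fixation_density(roi_set, dm) |>
          dplyr::mutate(participant_id = p, scene_id = sid)
        patch_rows[[length(patch_rows) + 1L]] <-
          patchify(dm, sal, roi_set) |>
          dplyr::mutate(participant_id = p, scene_id = sid)
      }
    }
  }

  metrics_by_trial <- dplyr::bind_rows(metric_rows)
  metrics_by_participant <- metrics_by_trial |>
    dplyr::group_by(.data$participant_id, .data$category) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("d_kl", "auc", "r")),
                                   mean), .groups = "drop")
  metric_tests <- purrr::map_dfr(c("d_kl", "auc", "r"), function(metric) {
    wide <- tidyr::pivot_wider(
      metrics_by_participant[c("participant_id", "category", metric)],
      names_from = "category", values_from = dplyr::all_of(metric)
    )
    dplyr::mutate(paired_t(wide$social, wide$nonsocial), metric = metric,
                  .before = 1)
  })

  # ROI analyses (social scenes)
  roi_saliency_by_scene <- dplyr::bind_rows(roi_sal_rows)
  roi_saliency_anova <- rm_anova(
    dplyr::rename(roi_saliency_by_scene, value = "rel_saliency"),
    dv = "value", within = "roi", participant = "scene_id"
  )
  roi_density_by_participant <- dplyr::bind_rows(roi_den_rows) |>
    dplyr::group_by(.data$participant_id, .data$roi) |>
    dplyr::summarise(rel_norm_density = mean(.data$rel_norm_density),
                     .groups = "drop")
  roi_density_anova <- rm_anova(roi_density_by_participant,
                                dv = "rel_norm_density", within = "roi")
  roi_posthoc <- bonferroni_posthoc(roi_density_by_participant,
                                    dv = "rel_norm_density",
                                    factor_name = "roi")

  # time course
  per_fix <- dplyr::bind_rows(fixrows) |>
    dplyr::filter(!.data$baseline_replaced) |>
    dplyr::mutate(fixation_number = rank_bin(.data$rank, max_rank))
  ranked_saliency <- per_fix |>
    dplyr::filter(!is.na(.data$rel_window_saliency)) |>
    dplyr::group_by(.data$participant_id, .data$category,
                    .data$fixation_number) |>
    dplyr::summarise(rel_window_saliency = mean(.data$rel_window_saliency),
                     .groups = "drop")
  ranked_saliency_anova <- rm_anova(
    dplyr::filter(ranked_saliency,
                  .data$fixation_number %in% as.character(1:max_rank)),
    dv = "rel_window_saliency",
    within = c("fixation_number", "category")
  )
  area_tbl <- dplyr::bind_rows(area_rows)
  hits <- per_fix |>
    dplyr::filter(.data$category == "social", !is.na(.data$roi))
  ranked_roi <- agg_ranked_roi(hits, area_tbl)
  ranked_roi_anova <- rm_anova(
    dplyr::filter(ranked_roi,
                  .data$fixation_number %in% as.character(1:max_rank)),
    dv = "norm_frequency", within = c("fixation_number", "roi")
  )

  # scene-patch mixed models
  patch_table <- dplyr::bind_rows(patch_rows)
  model_fits <- list(); model_summary <- NULL; lrt_table <- NULL
  decile_bins <- NULL; design <- NULL
  if (!is.null(models) && nrow(patch_table) > 0L) {
    design <- standardize_predictors(patch_table)
    model_fits <- purrr::map(models, function(mid) {
      fit_mixed_model(design, mid)
    })
    names(model_fits) <- models
    model_summary <- purrr::map_dfr(model_fits, glance)
    if (length(model_fits) >= 2L) lrt_table <- compare_models(model_fits)
    decile_bins <- purrr::map_dfr(
      c("dist_center", "rel_saliency", "rel_head", "rel_body"),
      function(pr) dplyr::mutate(
        suppressWarnings(decile_bin_summary(patch_table, pr)),
        predictor = pr, .before = 1
      )
    )
  }

  list(
    metrics_by_trial = metrics_by_trial,
    metrics_by_participant = metrics_by_participant,
    metric_tests = metric_tests,
    roi_saliency_by_scene = roi_saliency_by_scene,
    roi_saliency_anova = roi_saliency_anova,
    roi_density_by_participant = roi_density_by_participant,
    roi_density_anova = roi_density_anova,
    roi_posthoc = roi_posthoc,
    per_fixation = per_fix,
    ranked_saliency = ranked_saliency,
    ranked_saliency_anova = ranked_saliency_anova,
    ranked_roi = ranked_roi,
    ranked_roi_anova = ranked_roi_anova,
    patch_table = patch_table,
    design = design,
    model_fits = model_fits,
    model_summary = model_summary,
    lrt_table = lrt_table,
    decile_bins = decile_bins
  )
}

#' Pipeline configuration
#'
#' @param output_dir Directory for result CSVs and the manifest.
#' @param seed Cohort seed.
#' @param n_participants,n_social,n_nonsocial,trial_duration_ms Cohort
#'   dimensions, see [cohort_config()].
#' @param sigma_px,window_diameter_px,epsilon,models Analysis settings, see
#'   [analyze_cohort()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1L, n_participants = 31L,
                            n_social = 80L, n_nonsocial = 80L,
                            trial_duration_ms = 10000L, sigma_px = 36,
                            window_diameter_px = 72, epsilon = 1e-12,
                            models = c("1a", "2", "3a", "4", "5a", "6")) {
  structure(list(
    output_dir = output_dir, seed = as.integer(seed),
    n_participants = as.integer(n_participants),
    n_social = as.integer(n_social), n_nonsocial = as.integer(n_nonsocial),
    trial_duration_ms = as.integer(trial_duration_ms),
    sigma_px = sigma_px, window_diameter_px = window_diameter_px,
    epsilon = epsilon, models = models
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields;
#'   `output_dir` is required.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  stopifnot("output_dir" %in% names(vals))
  do.call(pipeline_config, vals)
}

#' Run the full pipeline and write result tables
#'
#' Generates the synthetic cohort defined by the config, runs
#' [analyze_cohort()], and writes every result table as CSV plus a
#' `manifest.json` recording the configuration, its hash, the seed, and the
#' row count of every output. Re-running with the same config reproduces
#' identical CSVs.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return Invisibly, the [analyze_cohort()] result list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(
    cohort_config(config$n_participants, config$n_social,
                  config$n_nonsocial, config$trial_duration_ms,
                  seed = config$seed)
  )
  res <- analyze_cohort(cohort, sigma_px = config$sigma_px,
                        window_diameter_px = config$window_diameter_px,
                        models = config$models, epsilon = config$epsilon)
  tables <- res[vapply(res, is.data.frame, logical(1))]
  counts <- list()
  for (nm in names(tables)) {
    f <- file.path(config$output_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    counts[[nm]] <- nrow(tables[[nm]])
  }
  if (length(res$model_fits)) {
    utils::write.csv(purrr::map_dfr(res$model_fits, tidy),
                     file.path(config$output_dir, "model_coefficients.csv"),
                     row.names = FALSE)
  }
  analytic <- unclass(config)
  analytic$output_dir <- NULL  # the hash identifies the analysis, not where it lands
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(analytic),
    seed = config$seed,
    rows = counts
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
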