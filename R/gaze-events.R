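#' Parse raw gaze samples into fixations, saccades and blinks
#'
#' Velocity/acceleration-threshold event detection on nominally 1000-Hz gaze
#' samples. Samples with missing pupil data form blink periods; among the
#' remaining samples, those whose instantaneous velocity exceeds `v_thresh`
#' (deg/s) or whose acceleration exceeds `a_thresh` (deg/s^2) are saccade
#' samples; maximal runs of saccade samples form saccades; maximal
#' inter-saccade, non-blink runs of at least `min_fixation_ms` form
#' fixations whose position is the mean of their member samples. Velocity
#' and acceleration are estimated by central differences over a 5-sample
#' window.
#'
#' @param samples Tibble with columns `participant_id`, `trial_id`, `t_ms`
#'   (strictly increasing within a trial), `x_px`, `y_px`, `pupil_valid`.
#' @param geometry A [viewing_geometry()].
#' @param v_thresh Saccade velocity threshold in deg/s (default 30).
#' @param a_thresh Saccade acceleration threshold in deg/s^2 (default 8000).
#' @param min_fixation_ms Minimum fixation duration in ms (default 40);
#'   shorter stationary runs are left unclassified.
#' @param blink_pad_ms Padding added around missing-pupil runs (default 0).
#' @param smooth_window Odd moving-average window (samples) applied to the
#'   position traces before differentiation (default 7; 1 disables it).
#'   Sample jitter otherwise leaks into the velocity estimate; fixation
#'   positions always use the raw samples.
#' @return A tibble of events, one row per event, with columns
#'   `participant_id`, `trial_id`, `type` (fixation/saccade/blink),
#'   `t_start`, `t_end`, `duration` (ms; the event covers
#'   `[t_start, t_end)`), `x`, `y` (fixation centroid, px; NA otherwise) and
#'   `amplitude_deg` (saccades only).
#' @export
detect_events <- function(samples, geometry, v_thresh = 30, a_thresh = 8000,
                          min_fixation_ms = 40, blink_pad_ms = 0,
                          smooth_window = 7L) {
  stopifnot(all(c("participant_id", "trial_id", "t_ms", "x_px", "y_px",
                  "pupil_valid") %in% names(samples)))
  if (nrow(samples) == 0L) stop("no gaze samples supplied", call. = FALSE)
  samples |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::group_modify(function(df, key) {
      if (is.unsorted(df$t_ms, strictly = TRUE)) {
        stop(sprintf("non-monotone timestamps in trial %s/%s",
                     key$participant_id, key$trial_id), call. = FALSE)
      }
      detect_events_one(df, geometry, v_thresh, a_thresh,
                        min_fixation_ms, blink_pad_ms, smooth_window)
    }) |>
    dplyr::ungroup()
}

detect_events_one <- function(df, geometry, v_thresh, a_thresh,
                              min_fixation_ms, blink_pad_ms,
                              smooth_window = 7L) {
  n <- nrow(df)
  if (n < 20L) stop("trial has fewer than 20 samples", call. = FALSE)
  t <- df$t_ms
  x <- df$x_px
  y <- df$y_px
  xs <- smooth_trace(x, smooth_window)
  ys <- smooth_trace(y, smooth_window)

  blink <- !df$pupil_valid
  if (blink_pad_ms > 0 && any(blink)) {
    idx <- which(blink)
    for (i in idx) {
      blink[t >= t[i] - blink_pad_ms & t <= t[i] + blink_pad_ms] <- TRUE
    }
  }

  # central differences over a 5-sample window (i-2 .. i+2)
  lag2 <- function(v) c(NA, NA, v[seq_len(n - 2)])
  lead2 <- function(v) c(v[-(1:2)], NA, NA)
  dt <- (lead2(t) - lag2(t)) / 1000  # s
  vx <- px_to_deg(lead2(xs) - lag2(xs), geometry, "x") / dt
  vy <- px_to_deg(lead2(ys) - lag2(ys), geometry, "y") / dt
  speed <- sqrt(vx^2 + vy^2)
  accel <- (lead2(speed) - lag2(speed)) / dt
  # samples whose difference window touches a blink get no velocity estimate
  near_blink <- blink | lag2(blink) | lead2(blink)
  speed[near_blink] <- NA
  accel[near_blink] <- NA

  sacc <- !blink &
    ((!is.na(speed) & speed > v_thresh) |
       (!is.na(accel) & abs(accel) > a_thresh))

  state <- ifelse(blink, 2L, ifelse(sacc, 1L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  rows <- lapply(seq_along(r$values), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    t0 <- t[i0]
    t1 <- if (i1 < n) t[i1 + 1L] else t[i1] + 1L  # sample covers [t, t+1)
    dur <- t1 - t0
    if (r$values[k] == 2L) {
      tibble::tibble(type = "blink", t_start = t0, t_end = t1, duration = dur,
                     x = NA_real_, y = NA_real_, amplitude_deg = NA_real_)
    } else if (r$values[k] == 1L) {
      amp <- px_dist_to_deg(
        sqrt((x[i1] - x[i0])^2 + (y[i1] - y[i0])^2), geometry
      )
      tibble::tibble(type = "saccade", t_start = t0, t_end = t1,
                     duration = dur, x = NA_real_, y = NA_real_,
                     amplitude_deg = amp)
    } else if (dur >= min_fixation_ms) {
      tibble::tibble(type = "fixation", t_start = t0, t_end = t1,
                     duration = dur, x = mean(x[i0:i1]), y = mean(y[i0:i1]),
                     amplitude_deg = NA_real_)
    } else {
      NULL
    }
  })
  dplyr::bind_rows(rows)
}

#' Per-trial validity and counts
#'
#' A trial is valid when its aggregated blink time during scene presentation
#' (`[onset_ms, onset_ms + scene_duration_ms)`) is shorter than 2 s.
#'
#' @param events Event tibble from [detect_events()].
#' @param onset_ms Scene onset time (default 0).
#' @param scene_duration_ms Scene presentation duration in ms (default 10000).
#' @param max_blink_ms Validity threshold on total blink time (default 2000).
#' @return Per-trial tibble: `participant_id`, `trial_id`, `n_fixations`,
#'   `blink_ms`, `valid`.
#' @export
trial_summary <- function(events, onset_ms = 0, scene_duration_ms = 10000,
                          max_blink_ms = 2000) {
  offset <- onset_ms + scene_duration_ms
  events |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::summarise(
      n_fixations = sum(.data$type == "fixation" & .data$t_start >= onset_ms &
                          .data$t_start < offset),
      blink_ms = sum(
        pmax(0, pmin(.data$t_end, offset) - pmax(.data$t_start, onset_ms)) *
          (.data$type == "blink")
      ),
      valid = .data$blink_ms < max_blink_ms,
      .groups = "drop"
    )
}

#' Fixations attributable to scene viewing
#'
#' Keeps fixations that started at or after scene onset; fixations straddling
#' scene offset are truncated at the offset (their duration shrinks
#' accordingly).
#'
#' @inheritParams trial_summary
#' @return Fixation rows of `events`, truncated, with a `rank` column (order
#'   of occurrence within the trial).
#' @export
scene_fixations <- function(events, onset_ms = 0, scene_duration_ms = 10000) {
  offset <- onset_ms + scene_duration_ms
  events |>
    dplyr::filter(.data$type == "fixation", .data$t_start >= onset_ms,
                  .data$t_start < offset) |>
    dplyr::mutate(
      t_end = pmin(.data$t_end, offset),
      duration = .data$t_end - .data$t_start
    ) |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::arrange(.data$t_start, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Recursive outlier removal
#'
#' Repeatedly, the current minimum and maximum of the list are each tested
#' against the mean plus/minus 3 standard deviations of the list with both
#' extremes removed; any extreme lying strictly beyond the bound is discarded
#' permanently and the procedure recurses on the remainder. Terminates when
#' neither extreme is removed. The SD uses the n - 1 denominator.
#'
#' @param values Numeric vector (NA values are ignored and kept apart).
#' @return A list with `kept` and `removed` numeric vectors; together they
#'   hold the non-NA input as a multiset. Inputs with fewer than 3 finite
#'   values are returned unchanged with attribute `flagged = TRUE` on the
#'   list.
#' @export
recursive_outlier_filter <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 3L) {
    return(structure(list(kept = v, removed = numeric(0)), flagged = TRUE))
  }
  removed <- numeric(0)
  repeat {
    i_min <- which.min(v)
    i_max <- which.max(v)
    rest <- v[-unique(c(i_min, i_max))]
    m <- mean(rest)
    s <- stats::sd(rest)
    if (length(rest) < 2L || is.na(s)) break
    drop_idx <- integer(0)
    if (v[i_min] < m - 3 * s) drop_idx <- c(drop_idx, i_min)
    if (i_max != i_min && v[i_max] > m + 3 * s) drop_idx <- c(drop_idx, i_max)
    if (length(drop_idx) == 0L) break
    removed <- c(removed, v[drop_idx])
    v <- v[-drop_idx]
    if (length(v) < 3L) break
  }
  list(kept = v, removed = removed)
}

#' Baseline gaze position before scene onset
#'
#' Mean position of gaze samples that fall inside detected fixation periods
#' within the `baseline_window_ms` directly before scene onset (when the
#' central cross was displayed). Trials without any qualifying sample get NA.
#'
#' @param samples Raw sample tibble (see [detect_events()]); times relative
#'   to scene onset, so the baseline window is `[-baseline_window_ms, 0)`.
#' @param events Event tibble from [detect_events()] on the same samples.
#' @param baseline_window_ms Baseline window length in ms (default 300).
#' @param onset_ms Scene onset time (default 0).
#' @return Per-trial tibble `participant_id`, `trial_id`, `baseline_x`,
#'   `baseline_y`.
#' @export
compute_baselines <- function(samples, events, baseline_window_ms = 300,
                              onset_ms = 0) {
  fix <- dplyr::filter(events, .data$type == "fixation")
  samples |>
    dplyr::filter(.data$t_ms >= onset_ms - baseline_window_ms,
                  .data$t_ms < onset_ms, .data$pupil_valid) |>
    dplyr::inner_join(
      fix,
      by = c("participant_id", "trial_id"),
      relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$t_ms >= .data$t_start, .data$t_ms < .data$t_end) |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::summarise(baseline_x = mean(.data$x_px),
                     baseline_y = mean(.data$y_px), .groups = "drop") |>
    dplyr::right_join(
      dplyr::distinct(samples, .data$participant_id, .data$trial_id),
      by = c("participant_id", "trial_id")
    ) |>
    dplyr::arrange(.data$participant_id, .data$trial_id)
}

#' Baseline drift correction of fixation positions
#'
#' Per participant, the distributions of baseline x and y positions across
#' trials are screened with [recursive_outlier_filter()]; trials whose
#' baseline x or y was flagged, or whose baseline is missing, have their
#' baseline replaced by the mean of the participant's valid baselines
#' (`baseline_replaced = TRUE`). Every fixation is then shifted by
#' `cross_position - baseline`, so that a trial whose baseline sat exactly
#' on the cross is unchanged.
#'
#' @param fixations Fixation tibble (needs `participant_id`, `trial_id`,
#'   `x`, `y`).
#' @param baselines Per-trial tibble from [compute_baselines()] (or supplied
#'   directly): `participant_id`, `trial_id`, `baseline_x`, `baseline_y`.
#' @param cross_position Length-2 numeric, the fixation-cross pixel position
#'   (defaults to the image center of the default geometry).
#' @return `fixations` with corrected `x`, `y` and added columns
#'   `baseline_x`, `baseline_y` (the baseline actually used) and
#'   `baseline_replaced`.
#' @export
drift_correct <- function(fixations, baselines,
                          cross_position = c(599.5, 449.5)) {
  bl <- baselines |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      fx <- recursive_outlier_filter(df$baseline_x)
      fy <- recursive_outlier_filter(df$baseline_y)
      bad <- is.na(df$baseline_x) | is.na(df$baseline_y) |
        df$baseline_x %in% fx$removed | df$baseline_y %in% fy$removed
      if (all(bad)) {
        stop(sprintf("participant %s has no valid baselines",
                     key$participant_id), call. = FALSE)
      }
      df$baseline_replaced <- bad
      df$baseline_x[bad] <- mean(df$baseline_x[!bad])
      df$baseline_y[bad] <- mean(df$baseline_y[!bad])
      df
    }) |>
    dplyr::ungroup()

  fixations |>
    dplyr::inner_join(bl, by = c("participant_id", "trial_id")) |>
    dplyr::mutate(
      x = .data$x + (cross_position[1] - .data$baseline_x),
      y = .data$y + (cross_position[2] - .data$baseline_y)
    )
}


# Centered moving average with edges left unsmoothed.
smooth_trace <- function(v, window) {
  window <- as.integer(window)
  if (window <= 1L) return(v)
  sm <- stats::filter(v, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- v[is.na(sm)]
  sm
}
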