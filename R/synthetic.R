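#' Synthetic cohort, scene and gaze-model configuration
#'
#' The generator emulates the study conditions of a free-viewing experiment:
#' 31 participants viewing 80 social and 80 non-social scenes for 10 s each,
#' producing roughly 31 fixations per trial with a mean duration of 277 ms
#' and mean saccade amplitude of 4.7 degrees; social scenes contain head and
#' body regions of intermediate physical saliency placed about 9.6 degrees
#' from scene center.
#'
#' @param n_participants,n_social,n_nonsocial Cohort dimensions
#'   (defaults 31, 80, 80).
#' @param trial_duration_ms Scene presentation time (default 10000).
#' @param seed Integer seed; fully determines the cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 31L, n_social = 80L,
                          n_nonsocial = 80L, trial_duration_ms = 10000L,
                          seed = 1L) {
  stopifnot(n_participants > 0, n_social > 0, n_nonsocial > 0,
            trial_duration_ms > 0)
  structure(list(n_participants = as.integer(n_participants),
                 n_social = as.integer(n_social),
                 n_nonsocial = as.integer(n_nonsocial),
                 trial_duration_ms = as.integer(trial_duration_ms),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @param w_head,w_body,w_saliency,w_center Non-negative target-selection
#'   weights of the scanpath model (renormalized internally; the head/body
#'   components are dropped on non-social scenes).
#' @param saccade_amp_mean_deg,saccade_amp_sd_deg Saccade amplitude
#'   distribution in degrees (truncated Normal).
#' @param fix_duration_mean_ms,fix_duration_sd_ms Fixation duration
#'   distribution in ms (Normal truncated at 40 ms).
#' @param drift_sd_px Per-trial constant calibration drift SD in px.
#' @param blink_rate_per_trial Expected number of ordinary blinks per trial.
#' @param long_blink_prob Probability of one long (2-3 s) blink making the
#'   trial invalid under the 2-s rule.
#' @param bad_baseline_prob Probability that a trial's pre-scene baseline is
#'   far off the cross (participant did not fixate it), to be caught by the
#'   recursive outlier screen.
#' @param early_social_boost Multiplier on `w_head` for fixation ranks 1-3.
#' @param sal_rank_mult Multipliers on `w_saliency` by fixation rank
#'   (last value reused beyond its length); a decreasing schedule makes
#'   early fixations saliency-seeking.
#' @param sal_gamma Sharpness exponents of saliency-proportional target
#'   sampling by fixation rank (last value reused): early fixations aim at
#'   saliency peaks, late fixations explore nearly uniformly.
#' @param target_persistence Probability that an unreached head/body target
#'   (saccade fell short of the mask) is pursued again by the next saccade,
#'   producing the characteristic two-saccade approach to distant social
#'   features.
#' @param head_rank_mult Multipliers on the head weight by fixation rank
#'   (last value reused): the strong early pull toward heads fades over the
#'   trial, while the body weight stays constant.
#' @param center_rank_mult Multipliers on the center-biased-noise weight by
#'   fixation rank (last value reused): unguided exploration of mostly
#'   low-saliency scene regions grows over the course of a trial.
#' @param revisit_damp Multiplier on a social component's weight while the
#'   gaze already rests inside that component (inhibition of return: an
#'   inspected head is briefly less likely to be re-targeted).
#' @export
gaze_model_params <- function(w_head = 0.35, w_body = 0.25, w_saliency = 0.25,
                              w_center = 0.15,
                              saccade_amp_mean_deg = 4.7,
                              saccade_amp_sd_deg = 1.0,
                              fix_duration_mean_ms = 277,
                              fix_duration_sd_ms = 48,
                              drift_sd_px = 6,
                              blink_rate_per_trial = 2,
                              long_blink_prob = 0.013,
                              bad_baseline_prob = 0.04,
                              early_social_boost = 3.5,
                              sal_rank_mult = c(3.5, 2.2, 1.4, 0.8, 0.55, 0.35),
                              sal_gamma = c(2.5, 1.8, 1.2, 0.75, 0.5, 0.35),
                              target_persistence = 0.95,
                              head_rank_mult = c(1, 1, 1, 0.55, 0.45, 0.35),
                              center_rank_mult = c(1, 1, 1, 1.8, 2.4, 3),
                              revisit_damp = 0.4) {
  w <- c(w_head, w_body, w_saliency, w_center)
  stopifnot(all(w >= 0), sum(w) > 0, early_social_boost >= 0,
            target_persistence >= 0, target_persistence <= 1)
  structure(list(
    w_head = w_head, w_body = w_body, w_saliency = w_saliency,
    w_center = w_center,
    saccade_amp_mean_deg = saccade_amp_mean_deg,
    saccade_amp_sd_deg = saccade_amp_sd_deg,
    fix_duration_mean_ms = fix_duration_mean_ms,
    fix_duration_sd_ms = fix_duration_sd_ms,
    drift_sd_px = drift_sd_px,
    blink_rate_per_trial = blink_rate_per_trial,
    long_blink_prob = long_blink_prob,
    bad_baseline_prob = bad_baseline_prob,
    early_social_boost = early_social_boost,
    sal_rank_mult = sal_rank_mult,
    sal_gamma = sal_gamma,
    target_persistence = target_persistence,
    head_rank_mult = head_rank_mult,
    center_rank_mult = center_rank_mult,
    revisit_damp = revisit_damp
  ), class = "gaze_model_params")
}

#' @rdname cohort_config
#' @param category `"social"` or `"nonsocial"`.
#' @param head_frac,body_frac Scene fraction covered by the head and body
#'   regions (defaults 0.0215 and 0.0895).
#' @param social_dist_center_deg Distance of the head center from scene
#'   center in degrees (default 9.6).
#' @param social_rel_saliency_target Saliency of the social regions relative
#'   to the scene mean (default 1.2, i.e. intermediate: above background,
#'   well below the distractor peaks).
#' @export
scene_spec <- function(category = c("social", "nonsocial"),
                       head_frac = 0.0215, body_frac = 0.0895,
                       social_dist_center_deg = 9.6,
                       social_rel_saliency_target = 1.2) {
  category <- match.arg(category)
  stopifnot(head_frac > 0, head_frac < 1, body_frac > 0, body_frac < 1)
  structure(list(category = category, head_frac = head_frac,
                 body_frac = body_frac,
                 social_dist_center_deg = social_dist_center_deg,
                 social_rel_saliency_target = social_rel_saliency_target),
            class = "scene_spec")
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed %% 2147483647L)
  force(code)
}

rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  stopifnot(lo < hi)
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > 1000L) {  # degenerate truncation window
      x[bad] <- pmin(pmax(mean, lo), hi)
      break
    }
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

# Add an isotropic Gaussian bump (peak `amp`) to matrix m at pixel
# (cx, cy), truncated at 3 sigma.
add_blob <- function(m, cx, cy, sigma, amp) {
  h <- nrow(m); w <- ncol(m)
  half <- ceiling(3 * sigma)
  rows <- (round(cy) + 1L) + (-half):half
  cols <- (round(cx) + 1L) + (-half):half
  okr <- rows >= 1L & rows <= h
  okc <- cols >= 1L & cols <= w
  ky <- exp(-((rows - 1 - cy)^2) / (2 * sigma^2))[okr]
  kx <- exp(-((cols - 1 - cx)^2) / (2 * sigma^2))[okc]
  m[rows[okr], cols[okc]] <- m[rows[okr], cols[okc]] + amp * (ky %o% kx)
  m
}

ellipse_mask <- function(h, w, cx, cy, a, b) {
  dx2 <- ((seq_len(w) - 1 - cx) / a)^2
  dy2 <- ((seq_len(h) - 1 - cy) / b)^2
  outer(dy2, dx2, `+`) <= 1
}

#' Generate one synthetic scene
#'
#' Constructs the scene's saliency map directly (rather than computing it
#' from a rendered image), so that the region-of-interest saliency
#' relationships hold by design: a low-saliency background, 10-14
#' high-saliency distractor blobs concentrated at around 7 degrees from
#' center, and — for social scenes — elliptical head and body regions about
#' `social_dist_center_deg` from center whose saliency is pinned at
#' `social_rel_saliency_target` times the scene mean (intermediate between
#' background and distractor peaks). An RGB rendering consistent with the
#' map can be produced for visual inspection but is not needed by the
#' pipeline.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; the same seed reproduces the scene bit for bit.
#' @param geometry A [viewing_geometry()].
#' @param render_image Also return an RGB array? (default FALSE).
#' @return List: `saliency` (a `saliency_map`), `head_mask`, `body_mask`
#'   (logical matrices; all-FALSE for non-social scenes), `spec`, `seed`,
#'   and optionally `image`.
#' @export
generate_scene <- function(spec, seed, geometry = viewing_geometry(),
                           render_image = FALSE) {
  with_seed(seed, {
    h <- geometry$image_height_px
    w <- geometry$image_width_px
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    px_deg <- mean(c(geometry$px_per_deg_x, geometry$px_per_deg_y))

    head_mask <- body_mask <- matrix(FALSE, h, w)
    if (spec$category == "social") {
      placed <- FALSE
      for (try in seq_len(50)) {
        phi <- stats::runif(1, 0.05 * pi, 0.95 * pi)  # upper semicircle
        d_px <- spec$social_dist_center_deg * px_deg
        hx <- cx + d_px * cos(phi)
        hy <- cy - d_px * sin(phi)
        head_area <- spec$head_frac * h * w
        ha <- sqrt(head_area * 1.35 / pi)   # slightly wide
        hb <- head_area / (pi * ha)
        body_area <- spec$body_frac * h * w * 1.12  # overlap compensation
        beb <- sqrt(body_area / (pi * 0.45))
        bea <- body_area / (pi * beb)
        bex <- hx
        bey <- hy + hb + 0.62 * beb
        if (hx - ha >= 2 && hx + ha <= w - 3 && hy - hb >= 2 &&
            bex - bea >= 2 && bex + bea <= w - 3 && bey + beb <= h - 3) {
          head_mask <- ellipse_mask(h, w, hx, hy, ha, hb)
          body_mask <- ellipse_mask(h, w, bex, bey, bea, beb) & !head_mask
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place social regions inside the image",
                        call. = FALSE)
    }
    social <- head_mask | body_mask

    sal <- matrix(0.18, h, w)
    # broad central elevation: screen-shot saliency models carry an
    # implicit central bias, and early fixations probe it
    sal <- add_blob(sal, cx, cy, sigma = 2.6 * px_deg, amp = 0.6)
    # mid-level background texture everywhere, so that untargeted scene
    # regions carry graded (not uniformly low) saliency
    for (i in seq_len(120)) {
      sal <- add_blob(sal, stats::runif(1, 20, w - 21),
                      stats::runif(1, 20, h - 21),
                      stats::runif(1, 8, 24), stats::runif(1, 0.08, 0.45))
    }
    n_blobs <- sample(10:14, 1)
    placed_blobs <- 0L
    guard <- 0L
    while (placed_blobs < n_blobs && guard < 400L) {
      guard <- guard + 1L
      ang <- stats::runif(1, 0, 2 * pi)
      dist <- rtnorm(1, 6.5 * px_deg, 2.0 * px_deg, lo = 2 * px_deg)
      bx <- cx + dist * cos(ang)
      by <- cy + dist * sin(ang)
      if (bx < 60 || bx > w - 61 || by < 60 || by > h - 61) next
      if (spec$category == "social" &&
          social[round(by) + 1L, round(bx) + 1L]) next
      sal <- add_blob(sal, bx, by, stats::runif(1, 25, 55),
                      stats::runif(1, 0.5, 0.9))
      placed_blobs <- placed_blobs + 1L
    }
    sal <- pmin(sal, 1)

    if (spec$category == "social") {
      # pin the social regions' mean saliency at exactly
      # `social_rel_saliency_target` times the scene mean, with a radial
      # gradation: contrast-driven saliency concentrates on the contours
      # of heads and bodies while their fixated interiors score low
      n_s <- sum(social)
      s_ns <- sum(sal[!social])
      tgt <- spec$social_rel_saliency_target
      v <- tgt * s_ns / (length(sal) - tgt * n_s)
      xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
      ys <- matrix(seq_len(h) - 1, h, w)
      rim <- function(mask, mx, my, ma, mb) {
        r2 <- ((xs[mask] - mx) / ma)^2 + ((ys[mask] - my) / mb)^2
        p <- 0.25 + r2
        p * (v / mean(p))
      }
      sal[head_mask] <- rim(head_mask, hx, hy, ha, hb)
      sal[body_mask] <- rim(body_mask, bex, bey, bea, beb)
    }

    out <- list(
      saliency = new_saliency_map(sal),
      head_mask = head_mask, body_mask = body_mask,
      spec = spec, seed = seed
    )
    if (render_image) {
      img <- array(0, dim = c(h, w, 3))
      img[, , 1] <- sal
      img[, , 2] <- 0.5 * sal + 0.3 * social
      img[, , 3] <- 0.2 + 0.6 * social
      out$image <- img
    }
    out
  })
}

# Coarse block-sum sampler of a saliency map: returns a function drawing
# pixel positions approximately proportional to saliency mass raised to a
# sharpness exponent gamma (gamma > 1 concentrates draws on the peaks,
# gamma -> 0 approaches uniform exploration).
saliency_sampler <- function(sal, block = 20L) {
  m <- map_values(sal)
  h <- nrow(m); w <- ncol(m)
  nb_r <- h %/% block; nb_c <- w %/% block
  mass <- rowsum(m[seq_len(nb_r * block), seq_len(nb_c * block)],
                 rep(seq_len(nb_r), each = block))
  mass <- t(rowsum(t(mass), rep(seq_len(nb_c), each = block)))
  p <- as.vector(mass); p <- p / sum(p)
  function(gamma = 1) {
    pg <- p^gamma
    cell <- sample.int(length(pg), 1L, prob = pg)
    r <- (cell - 1L) %% nb_r
    c <- (cell - 1L) %/% nb_r
    c(x = c * block + stats::runif(1, 0, block),
      y = r * block + stats::runif(1, 0, block))
  }
}

#' Simulate a fixation sequence on a scene
#'
#' Scanpath model: gaze starts at scene center; for each subsequent
#' fixation, a target component is drawn from head / body /
#' saliency-proportional / center-biased-noise with rank-scheduled weights
#' (`early_social_boost` multiplies the head weight for ranks 1-3, and
#' `sal_rank_mult` scales the saliency weight by rank), a target point is
#' drawn within the chosen component, and the landing point moves from the
#' current position toward the target by a truncated-Normal saccade
#' amplitude — so distant targets are typically reached only after two
#' saccades. Durations are Normal, truncated at 40 ms; the sequence stops
#' when cumulative fixation + saccade time exceeds the trial duration
#' (the last fixation is truncated).
#'
#' @param scene A [generate_scene()] result (or any list with `saliency`,
#'   `head_mask`, `body_mask`).
#' @param params A [gaze_model_params()].
#' @param geometry A [viewing_geometry()].
#' @param trial_duration_ms Viewing time (default 10000).
#' @param seed Optional seed (uses the current RNG stream when NULL).
#' @return Fixation tibble: `rank`, `t_start`, `t_end`, `duration`, `x`,
#'   `y` (ground-truth, drift-free positions).
#' @export
simulate_fixation_sequence <- function(scene, params,
                                       geometry = viewing_geometry(),
                                       trial_duration_ms = 10000,
                                       seed = NULL) {
  run <- function() {
    h <- geometry$image_height_px; w <- geometry$image_width_px
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    px_deg <- mean(c(geometry$px_per_deg_x, geometry$px_per_deg_y))
    head_idx <- which(scene$head_mask)
    body_idx <- which(scene$body_mask)
    # social targets cluster on focal points (the face region of a head,
    # the torso of a body) rather than spreading uniformly over the mask
    mask_sampler <- function(mask, idx) {
      xs <- (idx - 1L) %/% h
      ys <- (idx - 1L) %% h
      mux <- mean(xs); muy <- mean(ys)
      sdx <- max(2, 0.22 * stats::sd(xs)); sdy <- max(2, 0.22 * stats::sd(ys))
      function() {
        for (i in 1:10) {
          px <- round(stats::rnorm(1, mux, sdx))
          py <- round(stats::rnorm(1, muy, sdy))
          if (px >= 0 && px < w && py >= 0 && py < h && mask[py + 1L, px + 1L]) {
            return(c(x = px, y = py))
          }
        }
        i <- idx[sample.int(length(idx), 1L)]
        c(x = (i - 1L) %/% h, y = (i - 1L) %% h)
      }
    }
    draw_head <- if (length(head_idx)) mask_sampler(scene$head_mask, head_idx)
    draw_body <- if (length(body_idx)) mask_sampler(scene$body_mask, body_idx)
    sal_draw <- saliency_sampler(scene$saliency)

    # gaze starts on the (pre-onset) central cross fixation, which is not a
    # scene fixation; rank 1 is the landing of the first saccade, made
    # after a short latency
    pos <- c(x = cx, y = cy)
    t_now <- rtnorm(1, 200, 35, lo = 100)  # first-saccade latency
    rows <- vector("list", 64L)
    k <- 0L
    pending <- NULL  # unreached social target carried to the next saccade
    repeat {
      rank_next <- k + 1L
      mult <- params$sal_rank_mult
      w_sal <- params$w_saliency * mult[min(rank_next, length(mult))]
      hmult <- params$head_rank_mult
      late <- hmult[min(rank_next, length(hmult))]
      on_head <- k > 0L &&
        scene$head_mask[round(pos[["y"]]) + 1L, round(pos[["x"]]) + 1L]
      on_body <- k > 0L &&
        scene$body_mask[round(pos[["y"]]) + 1L, round(pos[["x"]]) + 1L]
      w_head <- params$w_head * late *
        (if (on_head) params$revisit_damp else 1) *
        if (rank_next <= 3L) params$early_social_boost else 1
      w_body <- params$w_body * if (on_body) params$revisit_damp else 1
      cmult <- params$center_rank_mult
      w_cen <- params$w_center * cmult[min(rank_next, length(cmult))]
      # two-stage selection: the exploration share is computed from the
      # full guided budget in BOTH scene categories, so social and
      # non-social trials wander equally; on non-social scenes the guided
      # budget goes entirely to saliency-seeking
      w_guided <- w_head + w_body + w_sal
      if (w_guided + w_cen <= 0) {
        stop("all target weights are zero", call. = FALSE)
      }
      if (!is.null(pending) &&
          stats::runif(1) < params$target_persistence) {
        comp <- pending$comp
        target <- pending$target
      } else {
        comp <- if (stats::runif(1) < w_cen / (w_cen + w_guided)) {
          "center"
        } else if (!length(head_idx) && !length(body_idx)) {
          "sal"
        } else {
          sample(c("head", "body", "sal"), 1L,
                 prob = c(if (length(head_idx)) w_head else 0,
                          if (length(body_idx)) w_body else 0, w_sal))
        }
        gam <- params$sal_gamma
        target <- switch(comp,
          head = draw_head(),
          body = draw_body(),
          sal = {
            # saccades prefer salient locations that are actually reachable:
            # among a handful of saliency-sampled candidates, take the one
            # with the smallest distance beyond the typical amplitude
            g <- gam[min(rank_next, length(gam))]
            cand <- vapply(1:4, function(i) sal_draw(g), numeric(2))
            dd <- sqrt((cand[1, ] - pos[["x"]])^2 +
                         (cand[2, ] - pos[["y"]])^2)
            pen <- pmax(0, dd - params$saccade_amp_mean_deg * px_deg)
            # inhibition of return: avoid re-targeting recently fixated spots
            if (k > 0L) {
              prev <- do.call(rbind, rows[seq_len(k)])
              for (jj in 1:4) {
                dprev <- sqrt((prev[, "x"] - cand[1, jj])^2 +
                                (prev[, "y"] - cand[2, jj])^2)
                if (any(dprev < 1.6 * px_deg)) pen[jj] <- pen[jj] + 12 * px_deg
              }
            }
            j <- as.integer(which.min(pen + stats::runif(4, 0, 0.5 * px_deg)))
            c(x = unname(cand[1, j]), y = unname(cand[2, j]))
          },
          center = c(x = cx + stats::rnorm(1, 0, 8 * px_deg),
                     y = cy + stats::rnorm(1, 0, 8 * px_deg))
        )
      }
      amp_px <- rtnorm(1, params$saccade_amp_mean_deg,
                       params$saccade_amp_sd_deg, lo = 0.8,
                       hi = max(9, params$saccade_amp_mean_deg +
                                  3 * params$saccade_amp_sd_deg)) * px_deg
      delta <- c(target[["x"]] - pos[["x"]], target[["y"]] - pos[["y"]])
      d <- sqrt(sum(delta^2))
      step <- if (d <= amp_px) delta else delta * amp_px / d
      pos <- c(x = pos[["x"]] + step[1] + stats::rnorm(1, 0, 0.25 * px_deg),
               y = pos[["y"]] + step[2] + stats::rnorm(1, 0, 0.25 * px_deg))
      pos["x"] <- min(max(pos[["x"]], 0), w - 1)
      pos["y"] <- min(max(pos[["y"]], 0), h - 1)
      # carry an unreached target forward: a social target missed (saccade
      # fell short of the mask) or an exploration target still more than
      # ~1.5 degrees away keeps being pursued by the next saccade
      lr <- round(pos[["y"]]) + 1L; lc <- round(pos[["x"]]) + 1L
      still_far <- sqrt((target[["x"]] - pos[["x"]])^2 +
                          (target[["y"]] - pos[["y"]])^2) > 1.5 * px_deg
      pending <- if (comp == "head" && !scene$head_mask[lr, lc]) {
        list(comp = comp, target = target)
      } else if (comp == "body" && !scene$body_mask[lr, lc]) {
        list(comp = comp, target = target)
      } else if (comp == "center" && still_far) {
        list(comp = comp, target = target)
      } else {
        NULL
      }
      amp_deg <- sqrt(sum(step^2)) / px_deg
      t_now <- t_now + 21 + 2.2 * amp_deg  # saccade duration (main sequence)
      if (t_now >= trial_duration_ms) break

      k <- k + 1L
      dur <- rtnorm(1, params$fix_duration_mean_ms,
                    params$fix_duration_sd_ms, lo = 40)
      t_end <- min(t_now + dur, trial_duration_ms)
      rows[[k]] <- c(rank = k, t_start = t_now, t_end = t_end,
                     x = pos[["x"]], y = pos[["y"]])
      if (t_end >= trial_duration_ms) break
      t_now <- t_end
      if (k == length(rows)) rows <- c(rows, vector("list", 64L))
    }
    df <- tibble::as_tibble(do.call(rbind, rows[seq_len(k)]))
    df$duration <- df$t_end - df$t_start
    df[c("rank", "t_start", "t_end", "duration", "x", "y")]
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Expand fixations into raw 1000-Hz gaze samples
#'
#' Fixation periods become position plus isotropic jitter (SD 0.05 deg);
#' saccades become smooth sigmoid position profiles whose peak velocity
#' well exceeds the 30 deg/s detection threshold; blinks are inserted as
#' `pupil_valid = FALSE` runs; a per-trial constant drift offset is added
#' to every sample; and a pre-onset baseline segment at the cross position
#' (plus drift) is prepended (times `-baseline_ms .. -1`).
#'
#' @param fixations Tibble from [simulate_fixation_sequence()].
#' @param params A [gaze_model_params()].
#' @param geometry A [viewing_geometry()].
#' @param drift Length-2 numeric, the per-trial drift offset in px.
#' @param blink_starts,blink_durations Optional explicit blink times (ms);
#'   when NULL, blinks are drawn from `blink_rate_per_trial`.
#' @param baseline_ms Length of the pre-onset cross segment (default 400).
#' @param jitter_sd_deg Fixation jitter SD in degrees (default 0.05).
#' @param seed Optional seed.
#' @return Sample tibble: `t_ms`, `x_px`, `y_px`, `pupil_valid`.
#' @export
simulate_raw_samples <- function(fixations, params,
                                 geometry = viewing_geometry(),
                                 drift = c(0, 0),
                                 blink_starts = NULL,
                                 blink_durations = NULL,
                                 baseline_ms = 400,
                                 jitter_sd_deg = 0.05,
                                 seed = NULL) {
  run <- function() {
    px_deg <- mean(c(geometry$px_per_deg_x, geometry$px_per_deg_y))
    jit <- jitter_sd_deg * px_deg
    cx <- (geometry$image_width_px - 1) / 2
    cy <- (geometry$image_height_px - 1) / 2
    t_min <- -baseline_ms
    t_max <- max(fixations$t_end)
    t <- seq(t_min, t_max - 1)
    n <- length(t)
    x <- numeric(n); y <- numeric(n)

    # the pre-onset cross fixation continues until the first saccade;
    # model it as a virtual fixation ending ~30 ms before fixation 1
    fixations <- dplyr::bind_rows(
      tibble::tibble(rank = 0, t_start = t_min,
                     t_end = max(t_min + 1, fixations$t_start[1] - 30),
                     duration = NA_real_, x = cx, y = cy),
      fixations
    )
    nf <- nrow(fixations)
    for (i in seq_len(nf)) {
      inside <- t >= fixations$t_start[i] & t < fixations$t_end[i]
      x[inside] <- fixations$x[i]
      y[inside] <- fixations$y[i]
      if (i < nf) {
        gap <- t >= fixations$t_end[i] & t < fixations$t_start[i + 1]
        ng <- sum(gap)
        if (ng > 0) {
          s <- stats::plogis(seq(-6, 6, length.out = ng))  # sigmoid profile
          x[gap] <- fixations$x[i] + s * (fixations$x[i + 1] - fixations$x[i])
          y[gap] <- fixations$y[i] + s * (fixations$y[i + 1] - fixations$y[i])
        }
      }
    }
    x <- x + stats::rnorm(n, 0, jit) + drift[1]
    y <- y + stats::rnorm(n, 0, jit) + drift[2]

    pupil_valid <- rep(TRUE, n)
    if (is.null(blink_starts)) {
      n_blinks <- stats::rpois(1, params$blink_rate_per_trial)
      blink_starts <- stats::runif(n_blinks, 0, t_max - 400)
      blink_durations <- rtnorm(n_blinks, 150, 50, lo = 60, hi = 400)
    }
    for (i in seq_along(blink_starts)) {
      bs <- blink_starts[i]
      pupil_valid[t >= bs & t < bs + blink_durations[i]] <- FALSE
    }
    tibble::tibble(t_ms = t, x_px = x, y_px = y, pupil_valid = pupil_valid)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a full synthetic cohort
#'
#' Draws the scene set (social and non-social), per-trial fixation
#' sequences for every participant, per-trial calibration drift, baseline
#' positions (occasionally far off the cross, to exercise the outlier
#' screen) and blink totals (occasionally exceeding the 2-s validity rule).
#' Scenes are not materialized: each scene regenerates deterministically
#' from its recorded seed via [generate_scene()] (see [cohort_scene()]).
#'
#' @param config A [cohort_config()].
#' @param params A [gaze_model_params()].
#' @param geometry A [viewing_geometry()].
#' @param level `"fixation"` (default; fixations plus per-trial baseline and
#'   validity bookkeeping) or `"sample"` (additionally expands every trial
#'   to raw 1000-Hz samples in `$samples`).
#' @return List of class `gaze_cohort`: `scenes` (tibble: `scene_id`,
#'   `category`, `scene_seed`), `fixations` (observed, i.e. drift-shifted),
#'   `baselines`, `trials` (with `blink_ms`, `valid`), `truth` (drift
#'   offsets, drift-free fixations, params, config), and optionally
#'   `samples`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            params = gaze_model_params(),
                            geometry = viewing_geometry(),
                            level = c("fixation", "sample")) {
  level <- match.arg(level)
  with_seed(config$seed, {
    n_scene <- config$n_social + config$n_nonsocial
    scenes <- tibble::tibble(
      scene_id = sprintf("s%03d", seq_len(n_scene)),
      category = rep(c("social", "nonsocial"),
                     c(config$n_social, config$n_nonsocial)),
      scene_seed = (config$seed + 7919L * seq_len(n_scene)) %% 2147483647L
    )
    cx <- (geometry$image_width_px - 1) / 2
    cy <- (geometry$image_height_px - 1) / 2

    participants <- sprintf("p%02d", seq_len(config$n_participants))
    all_fix <- vector("list", config$n_participants * n_scene)
    trials <- vector("list", length(all_fix))
    samples <- if (level == "sample") vector("list", length(all_fix)) else NULL
    idx <- 0L

    for (si in seq_len(n_scene)) {
      scene <- generate_scene(scene_spec(scenes$category[si]),
                              scenes$scene_seed[si], geometry)
      for (p in participants) {
        idx <- idx + 1L
        fx <- simulate_fixation_sequence(scene, params, geometry,
                                         config$trial_duration_ms)
        drift <- stats::rnorm(2, 0, params$drift_sd_px)
        bad_bl <- stats::runif(1) < params$bad_baseline_prob
        baseline <- if (bad_bl) {
          c(cx, cy) + drift + stats::rnorm(2, 0, 60)
        } else {
          c(cx, cy) + drift + stats::rnorm(2, 0, 1)
        }
        n_blinks <- stats::rpois(1, params$blink_rate_per_trial)
        blink_ms <- sum(rtnorm(n_blinks, 150, 50, lo = 60, hi = 400))
        if (stats::runif(1) < params$long_blink_prob) {
          blink_ms <- blink_ms + stats::runif(1, 2000, 3000)
        }
        obs <- fx
        obs$x <- obs$x + drift[1]
        obs$y <- obs$y + drift[2]
        obs$participant_id <- p
        obs$scene_id <- scenes$scene_id[si]
        obs$trial_id <- scenes$scene_id[si]
        all_fix[[idx]] <- obs
        trials[[idx]] <- tibble::tibble(
          participant_id = p, trial_id = scenes$scene_id[si],
          scene_id = scenes$scene_id[si], category = scenes$category[si],
          drift_x = drift[1], drift_y = drift[2],
          baseline_x = baseline[1], baseline_y = baseline[2],
          bad_baseline = bad_bl,
          blink_ms = blink_ms, valid = blink_ms < 2000
        )
        if (level == "sample") {
          trial_truth <- fx
          n_bl <- stats::rpois(1, params$blink_rate_per_trial)
          samples[[idx]] <- simulate_raw_samples(
            trial_truth, params, geometry, drift = drift,
            blink_starts = stats::runif(n_bl, 0,
                                        config$trial_duration_ms - 400)
          ) |>
            dplyr::mutate(participant_id = p,
                          trial_id = scenes$scene_id[si])
        }
      }
    }
    fixations <- dplyr::bind_rows(all_fix)
    trials <- dplyr::bind_rows(trials)
    truth_fix <- fixations
    truth_fix$x <- truth_fix$x -
      trials$drift_x[match(paste(truth_fix$participant_id, truth_fix$trial_id),
                           paste(trials$participant_id, trials$trial_id))]
    truth_fix$y <- truth_fix$y -
      trials$drift_y[match(paste(truth_fix$participant_id, truth_fix$trial_id),
                           paste(trials$participant_id, trials$trial_id))]
    out <- list(
      scenes = scenes,
      fixations = fixations,
      baselines = trials[c("participant_id", "trial_id",
                           "baseline_x", "baseline_y")],
      trials = trials,
      truth = list(fixations = truth_fix, params = params, config = config,
                   cross = c(cx, cy)),
      geometry = geometry
    )
    if (level == "sample") out$samples <- dplyr::bind_rows(samples)
    structure(out, class = "gaze_cohort")
  })
}

#' Regenerate one scene of a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param scene_id Scene identifier.
#' @return The [generate_scene()] list for that scene.
#' @export
cohort_scene <- function(cohort, scene_id) {
  row <- cohort$scenes[cohort$scenes$scene_id == scene_id, ]
  stopifnot(nrow(row) == 1L)
  generate_scene(scene_spec(row$category), row$scene_seed, cohort$geometry)
}

#' Simulated scene-patch tables with known mixed-model truth
#'
#' Parameter-recovery harness for the scene-patch mixed models: predictors
#' mimic the empirical patch structure (grid-determined center distance,
#' sparse non-negative saliency/head/body coverage, each scene-relative with
#' mean 1), are standardized, and the response is the linear predictor under
#' `betas` plus participant and scene random intercepts plus Gaussian noise.
#'
#' @param n_participants,n_scenes Cohort dimensions (defaults 31 and 79).
#' @param betas Named coefficients on the standardized predictors; any of
#'   `z_dist`, `z_sal`, `z_head`, `z_body`, `z_sal_head`, `z_sal_body`.
#' @param var_participant,var_scene Random-intercept variances
#'   (defaults 0.01 and 0.05).
#' @param var_resid Residual variance (default 1).
#' @param seed Integer seed.
#' @param n_cols,n_rows Patch grid (default 12 x 9).
#' @return List: `design` (standardized, ready for [fit_mixed_model()]),
#'   `truth` (betas and variances).
#' @export
generate_patch_data <- function(n_participants = 31L, n_scenes = 79L,
                                betas = c(z_dist = -0.3, z_sal = 0.15,
                                          z_head = 0.5, z_body = 0.2),
                                var_participant = 0.01, var_scene = 0.05,
                                var_resid = 1, seed = 1L,
                                n_cols = 12L, n_rows = 9L) {
  stopifnot(var_participant >= 0, var_scene >= 0, var_resid >= 0)
  with_seed(seed, {
    n_patch <- n_cols * n_rows
    centers_y <- (seq_len(n_rows) - 1) + 0.5
    centers_x <- (seq_len(n_cols) - 1) + 0.5
    dist <- as.vector(sqrt(outer((centers_y - n_rows / 2)^2,
                                 (centers_x - n_cols / 2)^2, `+`)))

    rel1 <- function(v) v / mean(v)
    scene_feats <- purrr::map(seq_len(n_scenes), function(s) {
      sal <- rel1(stats::rlnorm(n_patch, 0, 0.9))
      head <- numeric(n_patch)
      kh <- sample(2:4, 1)
      head[sample.int(n_patch, kh)] <- stats::runif(kh, 0.2, 1)
      body <- numeric(n_patch)
      kb <- sample(4:8, 1)
      body[sample.int(n_patch, kb)] <- stats::runif(kb, 0.2, 1)
      tibble::tibble(
        scene_id = sprintf("s%03d", s),
        patch = seq_len(n_patch),
        dist_center = dist,
        rel_saliency = sal,
        rel_head = if (sum(head) > 0) rel1(head) else head,
        rel_body = if (sum(body) > 0) rel1(body) else body
      )
    }) |> dplyr::bind_rows()

    design <- tidyr::expand_grid(
      participant_id = sprintf("p%02d", seq_len(n_participants)),
      scene_id = sprintf("s%03d", seq_len(n_scenes))
    ) |>
      dplyr::inner_join(scene_feats, by = "scene_id",
                        relationship = "many-to-many")
    design$rel_fix_density <- 0  # placeholder for standardize_predictors
    design <- standardize_predictors(design)

    b_p <- stats::rnorm(n_participants, 0, sqrt(var_participant))
    names(b_p) <- sprintf("p%02d", seq_len(n_participants))
    b_s <- stats::rnorm(n_scenes, 0, sqrt(var_scene))
    names(b_s) <- sprintf("s%03d", seq_len(n_scenes))

    lp <- rep(0, nrow(design))
    for (nm in names(betas)) lp <- lp + betas[[nm]] * design[[nm]]
    design$rel_fix_density <- unname(
      1 + lp + b_p[design$participant_id] + b_s[design$scene_id] +
        stats::rnorm(nrow(design), 0, sqrt(var_resid))
    )

    list(design = design,
         truth = list(betas = betas, var_participant = var_participant,
                      var_scene = var_scene, var_resid = var_resid))
  })
}

#' Write a synthetic cohort to disk
#'
#' Exports the cohort's gaze data as TSV (one row per fixation), the trial
#' bookkeeping as CSV, and the ground-truth parameters as JSON. Scene
#' saliency maps and ROI masks can additionally be written as float TIFF /
#' PNG per scene (off by default; scenes always regenerate exactly from
#' the seeds recorded in `truth.json`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @param write_maps Also write per-scene saliency maps and masks
#'   (default FALSE).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, write_maps = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$fixations, file.path(dir, "gaze.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$scenes, file.path(dir, "scenes.csv"),
                   row.names = FALSE)
  truth <- list(
    config = unclass(cohort$truth$config),
    params = unclass(cohort$truth$params),
    cross = cohort$truth$cross,
    scene_seeds = stats::setNames(as.list(cohort$scenes$scene_seed),
                                  cohort$scenes$scene_id)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (write_maps) {
    sal_dir <- file.path(dir, "saliency")
    mask_dir <- file.path(dir, "masks")
    dir.create(sal_dir, showWarnings = FALSE)
    dir.create(mask_dir, showWarnings = FALSE)
    for (sid in cohort$scenes$scene_id) {
      scene <- cohort_scene(cohort, sid)
      write_map(scene$saliency, file.path(sal_dir, paste0(sid, ".tif")))
      png::writePNG((scene$head_mask + 2 * scene$body_mask) / 255,
                    file.path(mask_dir, paste0(sid, ".png")))
    }
  }
  invisible(dir)
}
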