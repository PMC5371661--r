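geom <- viewing_geometry()

test_that("scene generation is deterministic and hits the mask fractions", {
  a <- generate_scene(scene_spec("social"), seed = 42)
  b <- generate_scene(scene_spec("social"), seed = 42)
  expect_identical(a$saliency$values, b$saliency$values)
  expect_identical(a$head_mask, b$head_mask)

  expect_equal(mean(a$head_mask), 0.0215, tolerance = 0.2 / 2.15)
  expect_false(any(a$head_mask & a$body_mask))
  expect_true(all(a$saliency$values >= 0 & a$saliency$values <= 1))

  ns <- generate_scene(scene_spec("nonsocial"), seed = 42)
  expect_false(any(ns$head_mask))
})

test_that("constructed scenes realize the intermediate social saliency", {
  sc <- generate_scene(scene_spec("social"), seed = 7)
  rs <- build_roi_set(sc$head_mask, sc$body_mask, sc$saliency)
  sal <- roi_relative_saliency(rs, sc$saliency)
  v <- setNames(sal$rel_saliency, as.character(sal$roi))
  expect_gt(v[["higher"]], v[["head"]])
  expect_gt(v[["head"]], v[["lower"]])
  expect_equal(v[["head"]], v[["body"]], tolerance = 0.05)
  expect_equal(v[["head"]], 1.2, tolerance = 0.05)
})

test_that("social and non-social saliency distributions are comparable", {
  n <- 25
  stats <- purrr::map_dfr(seq_len(2 * n), function(i) {
    cat <- if (i <= n) "social" else "nonsocial"
    sc <- generate_scene(scene_spec(cat), seed = 9000 + i)
    dplyr::mutate(map_summary(sc$saliency), category = cat)
  })
  tt <- t.test(mean ~ category, data = stats)
  expect_gt(tt$p.value, 0.05)
})

test_that("simulated fixation sequences match the trial statistics", {
  sc <- generate_scene(scene_spec("social"), seed = 42)
  params <- gaze_model_params()
  counts <- vapply(1:25, function(i) {
    nrow(simulate_fixation_sequence(sc, params, geom, seed = i))
  }, numeric(1))
  expect_gte(mean(counts), 28)
  expect_lte(mean(counts), 35)

  fx <- simulate_fixation_sequence(sc, params, geom, seed = 3)
  expect_true(all(fx$duration >= 40 | fx$t_end == 10000))
  expect_true(all(diff(fx$t_start) > 0))
  expect_lte(max(fx$t_end), 10000)
  # same seed -> identical
  fx2 <- simulate_fixation_sequence(sc, params, geom, seed = 3)
  expect_identical(fx, fx2)
})

test_that("forced head targeting without amplitude cap stays on the head", {
  sc <- generate_scene(scene_spec("social"), seed = 11)
  params <- gaze_model_params(w_head = 1, w_body = 0, w_saliency = 0,
                              w_center = 0, early_social_boost = 1,
                              head_rank_mult = 1, sal_rank_mult = 1,
                              center_rank_mult = 1,
                              saccade_amp_mean_deg = 40,
                              saccade_amp_sd_deg = 0.1, revisit_damp = 1)
  fx <- simulate_fixation_sequence(sc, params, geom, seed = 4)
  on_head <- vapply(seq_len(nrow(fx)), function(i) {
    sc$head_mask[round(fx$y[i]) + 1, round(fx$x[i]) + 1]
  }, logical(1))
  # landing noise can push a point just outside the mask edge
  expect_gte(mean(on_head), 0.8)
})

test_that("raw sample expansion supports the 2-second blink rule", {
  sc <- generate_scene(scene_spec("nonsocial"), seed = 13)
  fx <- simulate_fixation_sequence(sc, gaze_model_params(), geom, seed = 5)
  smp <- simulate_raw_samples(fx, gaze_model_params(), geom,
                              blink_starts = 3000, blink_durations = 2200,
                              seed = 6)
  smp$participant_id <- "p1"; smp$trial_id <- "t1"
  ts <- trial_summary(detect_events(smp, geom))
  expect_false(ts$valid)
  expect_equal(ts$blink_ms, 2200, tolerance = 0.05 * 2200)
})

test_that("cohort generation is seed-deterministic with correct bookkeeping", {
  cfg <- cohort_config(3, 4, 4, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$fixations, b$fixations)
  expect_identical(a$trials, b$trials)
  expect_equal(nrow(a$scenes), 8L)
  expect_equal(nrow(a$trials), 3L * 8L)
  expect_setequal(unique(a$scenes$category), c("social", "nonsocial"))
  # observed fixations = truth + per-trial drift
  tr <- a$trials[1, ]
  obs <- a$fixations[a$fixations$participant_id == tr$participant_id &
                       a$fixations$trial_id == tr$trial_id, ]
  tru <- a$truth$fixations[
    a$truth$fixations$participant_id == tr$participant_id &
      a$truth$fixations$trial_id == tr$trial_id, ]
  expect_equal(obs$x - tru$x, rep(tr$drift_x, nrow(obs)), tolerance = 1e-12)
  # scenes regenerate identically on demand
  s1 <- cohort_scene(a, "s001")
  s2 <- cohort_scene(a, "s001")
  expect_identical(s1$saliency$values, s2$saliency$values)
})

test_that("patch-data generator embeds the requested linear truth", {
  pd <- generate_patch_data(n_participants = 5, n_scenes = 6,
                            var_participant = 0, var_scene = 0,
                            var_resid = 0, seed = 8)
  d <- pd$design
  lp <- 1 + as.matrix(d[names(pd$truth$betas)]) %*% unlist(pd$truth$betas)
  expect_equal(d$rel_fix_density, as.vector(lp), tolerance = 1e-12)
  # null betas with noise: fitted model finds nothing beyond chance
  pd0 <- generate_patch_data(n_participants = 6, n_scenes = 8,
                             betas = c(z_dist = 0, z_sal = 0, z_head = 0,
                                       z_body = 0), seed = 9)
  f <- suppressMessages(suppressWarnings(fit_mixed_model(pd0$design, "4")))
  td <- tidy(f)
  expect_true(all(abs(td$estimate[td$term != "(Intercept)"]) <
                    3 * td$std_error[td$term != "(Intercept)"]))
})

test_that("cohort export writes gaze, trials and truth files", {
  coh <- generate_cohort(cohort_config(2, 2, 2, trial_duration_ms = 3000,
                                       seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "gaze.tsv")))
  expect_true(file.exists(file.path(dir, "trials.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  gz <- read.delim(file.path(dir, "gaze.tsv"))
  expect_equal(nrow(gz), nrow(coh$fixations))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$config$seed, 3L)
  # recorded seeds regenerate the identical scene
  s1 <- generate_scene(scene_spec(coh$scenes$category[1]),
                       truth$scene_seeds$s001)
  expect_identical(s1$saliency$values, cohort_scene(coh, "s001")$saliency$values)
})
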