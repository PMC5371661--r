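geom <- viewing_geometry()

make_samples <- function(x, y, valid = TRUE, t0 = 0,
                         participant = "p1", trial = "t1") {
  n <- length(x)
  tibble::tibble(
    participant_id = participant, trial_id = trial,
    t_ms = seq(t0, length.out = n), x_px = x, y_px = y,
    pupil_valid = rep_len(valid, n)
  )
}

test_that("a stationary trace yields exactly one fixation and nothing else", {
  s <- make_samples(rep(600, 1000), rep(450, 1000))
  ev <- detect_events(s, geom)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "fixation")
  expect_equal(ev$x, 600)
  expect_equal(ev$y, 450)
  expect_equal(ev$duration, 1000)
})

test_that("a fast traverse between two stationary segments is one saccade", {
  # 400 ms at A, 40 ms linear traverse of ~5 deg (~125 deg/s), 400 ms at B
  px5deg <- deg_to_px(5, geom, "x")
  x <- c(rep(300, 400), seq(300, 300 + px5deg, length.out = 40),
         rep(300 + px5deg, 400))
  s <- make_samples(x, rep(450, length(x)))
  ev <- detect_events(s, geom)
  expect_equal(sum(ev$type == "fixation"), 2L)
  expect_equal(sum(ev$type == "saccade"), 1L)
  expect_equal(ev$amplitude_deg[ev$type == "saccade"], 5, tolerance = 0.15)
  fx <- ev[ev$type == "fixation", ]
  expect_equal(fx$x, c(300, 300 + px5deg), tolerance = 0.01)
})

test_that("blink time over 2 s during presentation invalidates the trial", {
  x <- rep(600, 4000)
  valid <- rep(TRUE, 4000); valid[1000:3500] <- FALSE  # 2501 ms blink
  s <- make_samples(x, rep(450, 4000), valid = valid)
  ev <- detect_events(s, geom)
  ts <- trial_summary(ev, scene_duration_ms = 4000)
  expect_false(ts$valid)
  expect_gte(ts$blink_ms, 2000)

  valid2 <- rep(TRUE, 4000); valid2[1000:2500] <- FALSE  # 1.5 s blink
  ts2 <- trial_summary(detect_events(make_samples(x, rep(450, 4000),
                                                  valid = valid2), geom),
                       scene_duration_ms = 4000)
  expect_true(ts2$valid)
})

test_that("every presentation millisecond is classified or a short run", {
  set.seed(11)
  sc <- generate_scene(scene_spec("nonsocial"), seed = 303)
  fx <- simulate_fixation_sequence(sc, gaze_model_params(), geom,
                                   trial_duration_ms = 3000, seed = 5)
  s <- simulate_raw_samples(fx, gaze_model_params(), geom, seed = 6)
  s$participant_id <- "p1"; s$trial_id <- "t1"
  ev <- detect_events(s, geom)
  # events tile the sampled time span without overlap
  ev <- ev[order(ev$t_start), ]
  expect_true(all(ev$t_start[-1] >= ev$t_end[-nrow(ev)]))
  covered <- sum(ev$duration)
  span <- max(s$t_ms) + 1 - min(s$t_ms)
  expect_gte(covered / span, 0.9)  # short unclassified runs only
})

test_that("detection round-trips the generator on noiseless traces", {
  sc <- generate_scene(scene_spec("social"), seed = 42)
  fx <- simulate_fixation_sequence(sc, gaze_model_params(), geom, seed = 7)
  s <- simulate_raw_samples(fx, gaze_model_params(), geom,
                            blink_starts = numeric(0), jitter_sd_deg = 0,
                            seed = 3)
  s$participant_id <- "p1"; s$trial_id <- "t1"
  det <- scene_fixations(detect_events(s, geom))
  truth <- merge_close_fixations(fx)
  expect_lte(abs(nrow(det) - nrow(truth)), 1)
  # match by onset time; positions recovered within rounding
  j <- vapply(det$t_start, function(t) which.min(abs(truth$t_start - t)),
              integer(1))
  err <- sqrt((det$x - truth$x[j])^2 + (det$y - truth$y[j])^2)
  expect_lt(max(err), 0.75)
})

test_that("recursive outlier filter matches hand-traced recursions", {
  f <- recursive_outlier_filter(c(1, 2, 3, 4, 50))
  expect_equal(sort(f$kept), c(1, 2, 3, 4))
  expect_equal(f$removed, 50)

  f2 <- recursive_outlier_filter(c(5, 5, 5, 5, 5))
  expect_equal(length(f2$removed), 0L)

  f3 <- recursive_outlier_filter(c(-100, 0, 0, 0, 0, 100))
  expect_equal(sort(f3$removed), c(-100, 100))
  expect_equal(f3$kept, c(0, 0, 0, 0))

  # kept + removed partition the input as a multiset
  set.seed(21)
  for (i in 1:20) {
    v <- c(rnorm(30), sample(c(-50, 50, 0), 3, replace = TRUE))
    f <- recursive_outlier_filter(v)
    expect_equal(sort(c(f$kept, f$removed)), sort(v))
    # idempotence: filtering the kept set removes nothing
    f2 <- recursive_outlier_filter(f$kept)
    expect_equal(length(f2$removed), 0L)
  }

  short <- recursive_outlier_filter(c(1, 2))
  expect_true(attr(short, "flagged"))
  expect_equal(short$kept, c(1, 2))
})

test_that("drift correction shifts fixations by cross minus baseline", {
  fx <- tibble::tibble(
    participant_id = "p1", trial_id = rep(c("t1", "t2"), each = 2),
    x = c(100, 200, 300, 400), y = c(100, 150, 200, 250)
  )
  # t1 baseline exactly on the cross, t2 offset by (10, -5)
  bl <- tibble::tibble(
    participant_id = "p1", trial_id = c("t1", "t2"),
    baseline_x = c(599.5, 609.5), baseline_y = c(449.5, 444.5)
  )
  out <- drift_correct(fx, bl, cross_position = c(599.5, 449.5))
  expect_equal(out$x[out$trial_id == "t1"], c(100, 200))
  expect_equal(out$x[out$trial_id == "t2"], c(300, 400) - 10)
  expect_equal(out$y[out$trial_id == "t2"], c(200, 250) + 5)
  expect_false(any(out$baseline_replaced))
})

test_that("an outlying baseline is replaced by the mean of valid baselines", {
  n_tr <- 12
  trials <- sprintf("t%02d", 1:n_tr)
  fx <- tibble::tibble(participant_id = "p1", trial_id = trials,
                       x = 500, y = 400)
  set.seed(9)
  bx <- 599.5 + rnorm(n_tr, 0, 1); by <- 449.5 + rnorm(n_tr, 0, 1)
  bx[4] <- 599.5 + 200  # participant looked far off the cross
  bl <- tibble::tibble(participant_id = "p1", trial_id = trials,
                       baseline_x = bx, baseline_y = by)
  out <- drift_correct(fx, bl)
  # the filter itself is the oracle for which trials are screened out
  fxo <- recursive_outlier_filter(bx)
  fyo <- recursive_outlier_filter(by)
  bad <- bx %in% fxo$removed | by %in% fyo$removed
  expect_true(out$baseline_replaced[out$trial_id == "t04"])
  expect_true(bad[4])
  expect_equal(out$baseline_replaced, bad)
  expect_equal(out$baseline_x[out$trial_id == "t04"], mean(bx[!bad]))
  expect_error(
    drift_correct(fx[1, ],
                  tibble::tibble(participant_id = "p1", trial_id = "t01",
                                 baseline_x = NA_real_, baseline_y = 2)),
    "no valid baselines"
  )
})

test_that("injected drift offsets are recovered within 0.1 degree", {
  geom <- viewing_geometry()
  sc <- generate_scene(scene_spec("nonsocial"), seed = 77)
  params <- gaze_model_params()
  tol_px <- deg_to_px(0.1, geom, "x")
  all_fx <- list(); all_bl <- list(); truth <- list()
  set.seed(31)
  drifts <- cbind(c(6, -4, 2, 0, 8, -6, 3, -2),
                  c(-5, 3, -8, 2, 0, 6, -3, 4))
  for (i in 1:8) {
    fx <- simulate_fixation_sequence(sc, params, geom, seed = 400 + i)
    smp <- simulate_raw_samples(fx, params, geom, drift = drifts[i, ],
                                blink_starts = numeric(0), seed = 500 + i)
    smp$participant_id <- "p1"; smp$trial_id <- sprintf("t%d", i)
    ev <- detect_events(smp, geom)
    bl <- compute_baselines(smp, ev)
    det <- scene_fixations(ev)
    truth[[i]] <- fx
    all_fx[[i]] <- det
    all_bl[[i]] <- bl
  }
  corrected <- drift_correct(dplyr::bind_rows(all_fx),
                             dplyr::bind_rows(all_bl))
  for (i in 1:8) {
    det <- corrected[corrected$trial_id == sprintf("t%d", i), ]
    fx <- truth[[i]]
    j <- vapply(det$t_start, function(t) which.min(abs(fx$t_start - t)),
                integer(1))
    err <- sqrt((det$x - fx$x[j])^2 + (det$y - fx$y[j])^2)
    expect_lt(stats::median(err), tol_px)
  }
})
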