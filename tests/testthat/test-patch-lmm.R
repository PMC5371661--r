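geom <- viewing_geometry()

test_that("patchify produces 108 records with exact relative-mean identities", {
  set.seed(23)
  d <- matrix(rexp(900 * 1200), 900, 1200)
  s <- matrix(runif(900 * 1200), 900, 1200)
  head <- matrix(FALSE, 900, 1200); head[100:180, 200:330] <- TRUE
  body <- matrix(FALSE, 900, 1200); body[181:400, 200:330] <- TRUE
  rs <- build_roi_set(head, body, s)
  pt <- patchify(d, s, rs)
  expect_equal(nrow(pt), 108L)
  expect_equal(mean(pt$rel_fix_density), 1, tolerance = 1e-12)
  expect_equal(mean(pt$rel_saliency), 1, tolerance = 1e-12)
  expect_equal(mean(pt$rel_head), 1, tolerance = 1e-12)
  expect_equal(mean(pt$rel_body), 1, tolerance = 1e-12)
  # 27 distinct center distances; minimum is 50 px on the default grid
  expect_equal(length(unique(round(pt$dist_center, 9))), 27L)
  expect_equal(min(pt$dist_center), 50)
})

test_that("uniform density gives unit relative density everywhere", {
  u <- matrix(1, 900, 1200)
  s <- matrix(runif(900 * 1200), 900, 1200)
  head <- matrix(FALSE, 900, 1200); head[1:50, 1:50] <- TRUE
  rs <- build_roi_set(head, matrix(FALSE, 900, 1200), s)
  pt <- patchify(u, s, rs)
  expect_equal(pt$rel_fix_density, rep(1, 108))
})

test_that("patchify refuses non-divisible grids", {
  s <- matrix(runif(100 * 90), 90, 100)
  rs <- suppressWarnings(
    build_roi_set(matrix(FALSE, 90, 100), matrix(FALSE, 90, 100), s)
  )
  expect_error(patchify(s, s, rs, n_cols = 7, n_rows = 9), "evenly|square")
})

test_that("standardization yields exact zero mean / unit sd and is idempotent", {
  pd <- generate_patch_data(n_participants = 4, n_scenes = 6, seed = 31)
  z <- pd$design
  for (col in c("z_dist", "z_sal", "z_head", "z_body")) {
    expect_lt(abs(mean(z[[col]])), 1e-10)
    expect_equal(sd(z[[col]]), 1, tolerance = 1e-10)
  }
  expect_equal(z$z_sal_head, z$z_sal * z$z_head)
  scal <- attr(z, "scaling")
  expect_equal(nrow(scal), 4L)
  # idempotence on the raw predictors
  z2 <- standardize_predictors(z)
  expect_equal(z2$z_dist, z$z_dist, tolerance = 1e-12)
  # row-count bookkeeping at study scale: 31 participants x 108 patches x
  # mean 78.93548 valid trials
  expect_equal(round(31 * 78.93548 * 108), 264276)
})

test_that("mixed-model fits recover parameters and reduce to OLS limits", {
  pd <- generate_patch_data(n_participants = 8, n_scenes = 12, seed = 2)
  fit <- fit_mixed_model(pd$design, "4")
  td <- tidy(fit)
  for (nm in names(pd$truth$betas)) {
    row <- td[td$term == nm, ]
    expect_lt(abs(row$estimate - pd$truth$betas[[nm]]), 2.5 * row$std_error)
  }
  expect_equal(glance(fit)$n_obs, 8 * 12 * 108)
  expect_true(all(c("satterthwaite", "wald_z") != "" &
                    fit$df_method %in% c("satterthwaite", "wald_z")))

  # noiseless, variance-free limit: exact recovery
  pd0 <- generate_patch_data(n_participants = 4, n_scenes = 6,
                             var_participant = 0, var_scene = 0,
                             var_resid = 0, seed = 3)
  f0 <- suppressWarnings(suppressMessages(fit_mixed_model(pd0$design, "4")))
  est <- f0$fixed_effects$estimate[f0$fixed_effects$term != "(Intercept)"]
  expect_equal(est, unname(pd0$truth$betas), tolerance = 1e-8)

  # zero random variances: coefficients agree with ordinary least squares
  pd_ols <- generate_patch_data(n_participants = 5, n_scenes = 8,
                                var_participant = 0, var_scene = 0,
                                var_resid = 0.5, seed = 4)
  f_lmm <- suppressWarnings(suppressMessages(
    fit_mixed_model(pd_ols$design, "4")
  ))
  f_ols <- lm(rel_fix_density ~ z_dist + z_sal + z_head + z_body,
              data = pd_ols$design)
  expect_equal(
    f_lmm$fixed_effects$estimate,
    unname(coef(f_ols)),
    tolerance = 0.01
  )
})

test_that("aic accounting and likelihood-ratio ladder behave", {
  pd <- generate_patch_data(n_participants = 6, n_scenes = 10, seed = 5)
  fits <- lapply(c("1a", "2", "3a", "4", "5a", "6"),
                 function(m) fit_mixed_model(pd$design, m))
  g <- purrr::map_dfr(fits, glance)
  # AIC = 2k - 2 logLik(ML)
  ks <- vapply(fits, function(f) f$n_params_ml, numeric(1))
  expect_equal(g$aic, 2 * ks - 2 * g$loglik_ml, tolerance = 1e-8)

  lrt <- compare_models(fits)
  expect_equal(nrow(lrt), 5L)
  expect_true(all(lrt$nested))
  expect_true(all(lrt$chisq >= 0))
  # true nonzero effects enter at steps 2 (saliency), 3a (head), 4 (body)
  expect_lt(lrt$p_value[lrt$model_b == "3a"], 0.001)
  expect_lt(lrt$p_value[lrt$model_b == "4"], 0.001)

  # r2 analog never decreases along the nested ladder
  expect_true(all(diff(g$r2_analog) > -1e-8))

  # identical model compared with itself
  self <- compare_models(list(fits[[4]], fits[[4]]))
  expect_equal(self$chisq, 0)
  expect_equal(self$p_value, 1)

  # non-nested pair: LRT refused, AIC still reported
  nn <- compare_models(lapply(c("1c", "1d"),
                              function(m) fit_mixed_model(pd$design, m)))
  expect_false(nn$nested)
  expect_true(is.na(nn$p_value))
  expect_true(is.finite(nn$delta_aic))
})

test_that("decile binning partitions patches and isolates zero coverage", {
  pd <- generate_patch_data(n_participants = 3, n_scenes = 10, seed = 6)
  rec <- pd$design
  bins <- decile_bin_summary(rec, "rel_saliency")
  expect_equal(sum(bins$n), nrow(rec))
  expect_equal(nrow(bins), 10L)

  hb <- decile_bin_summary(rec, "rel_head")
  expect_equal(as.character(hb$bin[1]), "0")
  expect_equal(sum(hb$n), nrow(rec))
  expect_equal(hb$n[1], sum(rec$rel_head == 0))

  db <- decile_bin_summary(rec, "dist_center")
  expect_equal(sum(db$n), nrow(rec))
  # uneven bins from 27 distinct values: between about 7 and 13 percent
  expect_true(all(db$n / nrow(rec) > 0.04 & db$n / nrow(rec) < 0.20))

  # uniform response gives equal bin means
  rec$rel_fix_density <- 2.5
  ub <- decile_bin_summary(rec, "rel_saliency")
  expect_true(all(abs(ub$mean_rel_fix_density - 2.5) < 1e-12))
})
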