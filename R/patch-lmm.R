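#' Scene-patch featurization on a regular grid
#'
#' Overlays the scene with a `n_rows x n_cols` grid of square patches
#' (12 x 9 patches of 100 x 100 px on the default 1200 x 900 raster) and
#' computes, per patch: the mean fixation density divided by the scene-wide
#' average of patch means (`rel_fix_density`), the mean saliency likewise
#' (`rel_saliency`), the head-coverage fraction divided by the scene-wide
#' mean head-coverage fraction (`rel_head`; 0 everywhere, flagged, when the
#' scene contains no head pixels), the body coverage likewise (`rel_body`),
#' and the Euclidean distance from the patch center to the scene center in
#' px (`dist_center`; 27 distinct values on the default grid).
#'
#' @param density A `density_map` or matrix.
#' @param saliency A `saliency_map` or matrix of the same shape.
#' @param roi_set A [build_roi_set()] result for the scene.
#' @param n_cols,n_rows Grid dimensions (default 12 x 9); the image must
#'   divide evenly into the grid and patches must be square.
#' @return Tibble with one row per patch: `patch_row`, `patch_col` (0-based),
#'   `rel_fix_density`, `rel_saliency`, `rel_head`, `rel_body`,
#'   `dist_center`.
#' @export
patchify <- function(density, saliency, roi_set, n_cols = 12L, n_rows = 9L) {
  d <- map_values(density)
  s <- map_values(saliency)
  stopifnot(identical(dim(d), dim(s)))
  h <- nrow(d); w <- ncol(d)
  if (h %% n_rows != 0L || w %% n_cols != 0L) {
    stop("image dimensions must divide evenly into the patch grid",
         call. = FALSE)
  }
  ph <- h %/% n_rows; pw <- w %/% n_cols
  if (ph != pw) stop("patches must be square", call. = FALSE)

  patch_means <- function(m) {
    # mean over each ph x pw block -> n_rows x n_cols matrix
    rowsum_rows <- rowsum(m, rep(seq_len(n_rows), each = ph))
    t(rowsum(t(rowsum_rows), rep(seq_len(n_cols), each = pw))) / (ph * pw)
  }
  rel <- function(pm) {
    mu <- mean(pm)
    if (mu > 0) pm / mu else pm  # all-zero feature stays 0 (flagged upstream)
  }

  pm_d <- patch_means(d)
  pm_s <- patch_means(s)
  pm_h <- patch_means(roi_set$head + 0)
  pm_b <- patch_means(roi_set$body + 0)

  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  centers_y <- (seq_len(n_rows) - 1) * ph + (ph - 1) / 2
  centers_x <- (seq_len(n_cols) - 1) * pw + (pw - 1) / 2
  dist <- sqrt(outer((centers_y - cy)^2, (centers_x - cx)^2, `+`))

  grid <- expand.grid(patch_row = seq_len(n_rows) - 1L,
                      patch_col = seq_len(n_cols) - 1L)
  tibble::tibble(
    patch_row = grid$patch_row,
    patch_col = grid$patch_col,
    rel_fix_density = as.vector(rel(pm_d)),
    rel_saliency = as.vector(rel(pm_s)),
    rel_head = as.vector(rel(pm_h)),
    rel_body = as.vector(rel(pm_b)),
    dist_center = as.vector(dist)
  )
}

#' Standardize the patch predictors
#'
#' Transforms the four predictors (`dist_center`, `rel_saliency`,
#' `rel_head`, `rel_body`) to mean 0 and SD 1 over the pooled table, and
#' forms the two interaction columns as products of the standardized main
#' effects (not re-standardized). Scaling constants are attached as the
#' `"scaling"` attribute (a tibble with `predictor`, `center`, `scale`) for
#' back-transformation.
#'
#' @param records Pooled patch tibble from [patchify()] over all
#'   participants and scenes (needs a `rel_fix_density` response column).
#' @return The design tibble with standardized `z_dist`, `z_sal`, `z_head`,
#'   `z_body`, interaction columns `z_sal_head`, `z_sal_body`, and the
#'   untouched response.
#' @export
standardize_predictors <- function(records) {
  preds <- c(dist_center = "z_dist", rel_saliency = "z_sal",
             rel_head = "z_head", rel_body = "z_body")
  scal <- purrr::imap_dfr(preds, function(zname, raw) {
    v <- records[[raw]]
    s <- stats::sd(v)
    if (s == 0) stop(sprintf("predictor %s has zero variance", raw),
                     call. = FALSE)
    tibble::tibble(predictor = raw, center = mean(v), scale = s)
  })
  out <- records
  for (i in seq_len(nrow(scal))) {
    out[[preds[[scal$predictor[i]]]]] <-
      (records[[scal$predictor[i]]] - scal$center[i]) / scal$scale[i]
  }
  out$z_sal_head <- out$z_sal * out$z_head
  out$z_sal_body <- out$z_sal * out$z_body
  attr(out, "scaling") <- scal
  out
}

# Fixed-effect sets of the model ladder.
model_terms <- list(
  "1a" = "z_dist", "1b" = "z_sal", "1c" = "z_head", "1d" = "z_body",
  "2" = c("z_dist", "z_sal"),
  "3a" = c("z_dist", "z_sal", "z_head"),
  "3b" = c("z_dist", "z_sal", "z_body"),
  "4" = c("z_dist", "z_sal", "z_head", "z_body"),
  "5a" = c("z_dist", "z_sal", "z_head", "z_body", "z_sal_head"),
  "5b" = c("z_dist", "z_sal", "z_head", "z_body", "z_sal_body"),
  "6" = c("z_dist", "z_sal", "z_head", "z_body", "z_sal_head", "z_sal_body"),
  "0" = character(0)
)

#' Fit one model of the scene-patch mixed-model ladder
#'
#' Regresses the relative patch fixation density on the model's fixed
#' effects with crossed random intercepts for participant and scene,
#' fitted by REML (coefficients, SEs, Satterthwaite p-values via
#' lmerTest) and refitted by ML for likelihood-ratio comparison and AIC.
#' The model ladder: 1a/1b/1c/1d single predictors (distance from center,
#' saliency, head, body), 2 = distance + saliency, 3a/3b add head or body,
#' 4 = all four, 5a/5b add one saliency x social interaction, 6 adds both;
#' "0" is the random-effects-only null.
#'
#' @param design Design tibble from [standardize_predictors()] with
#'   `participant_id`, `scene_id`, `rel_fix_density` and the z-columns.
#' @param model_id One of `"0"`, `"1a"`, `"1b"`, `"1c"`, `"1d"`, `"2"`,
#'   `"3a"`, `"3b"`, `"4"`, `"5a"`, `"5b"`, `"6"`.
#' @return Object of class `patch_lmm_fit`; see [tidy.patch_lmm_fit()] and
#'   [glance.patch_lmm_fit()].
#' @export
fit_mixed_model <- function(design, model_id) {
  model_id <- as.character(model_id)
  if (!model_id %in% names(model_terms)) {
    stop("unknown model id: ", model_id, call. = FALSE)
  }
  terms <- model_terms[[model_id]]
  rhs <- paste(c(if (length(terms)) terms else "1",
                 "(1 | participant_id)", "(1 | scene_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste("rel_fix_density ~", rhs))
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = "warning")
  fit_reml <- lmerTest::lmer(form, data = design, REML = TRUE, control = ctrl)
  fit_ml <- lme4::lmer(form, data = design, REML = FALSE, control = ctrl)

  co <- as.data.frame(summary(fit_reml)$coefficients)
  fixed <- tibble::tibble(
    term = rownames(co),
    estimate = co$Estimate,
    std_error = co$`Std. Error`,
    df = if ("df" %in% names(co)) co$df else NA_real_,
    statistic = co$`t value`,
    p_value = if ("Pr(>|t|)" %in% names(co)) co$`Pr(>|t|)` else
      2 * stats::pnorm(-abs(co$`t value`))
  )
  vc <- as.data.frame(lme4::VarCorr(fit_reml))
  get_var <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else NA_real_
  }
  fitted_vals <- stats::fitted(fit_ml)
  obs <- design$rel_fix_density
  structure(
    list(
      model_id = model_id,
      fixed_effects = fixed,
      loglik_reml = as.numeric(stats::logLik(fit_reml)),
      loglik_ml = as.numeric(stats::logLik(fit_ml)),
      n_params_ml = attr(stats::logLik(fit_ml), "df"),
      aic = stats::AIC(fit_ml),
      r2_analog = stats::cor(obs, fitted_vals)^2,
      random_intercept_vars = c(participant = get_var("participant_id"),
                                scene = get_var("scene_id")),
      residual_var = get_var("Residual"),
      n_obs = nrow(design),
      df_method = if ("df" %in% names(co)) "satterthwaite" else "wald_z",
      fit_reml = fit_reml,
      fit_ml = fit_ml
    ),
    class = "patch_lmm_fit"
  )
}

#' @export
print.patch_lmm_fit <- function(x, ...) {
  cat(sprintf("<patch_lmm_fit> model %s: n = %d, AIC(ML) = %.1f, R2 = %.3f\n",
              x$model_id, x$n_obs, x$aic, x$r2_analog))
  print(x$fixed_effects)
  invisible(x)
}

#' Tidy a scene-patch mixed-model fit
#'
#' @param x A `patch_lmm_fit`.
#' @param ... Unused.
#' @return Tibble of fixed effects: `model_id`, `term`, `estimate`,
#'   `std_error`, `df`, `statistic`, `p_value`.
#' @export
tidy.patch_lmm_fit <- function(x, ...) {
  dplyr::mutate(x$fixed_effects, model_id = x$model_id,
                .before = dplyr::everything())
}

#' One-row summary of a scene-patch mixed-model fit
#'
#' @param x A `patch_lmm_fit`.
#' @param ... Unused.
#' @return One-row tibble: `model_id`, `n_obs`, `loglik_ml`, `loglik_reml`,
#'   `aic`, `r2_analog`, `var_participant`, `var_scene`, `var_residual`.
#' @export
glance.patch_lmm_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, n_obs = x$n_obs,
    loglik_ml = x$loglik_ml, loglik_reml = x$loglik_reml,
    aic = x$aic, r2_analog = x$r2_analog,
    var_participant = x$random_intercept_vars[["participant"]],
    var_scene = x$random_intercept_vars[["scene"]],
    var_residual = x$residual_var
  )
}

#' Incremental likelihood-ratio comparison of nested model fits
#'
#' For each consecutive pair of the supplied fits, the likelihood-ratio
#' statistic `chi^2 = 2 * (loglik_ml_larger - loglik_ml_smaller)` with
#' `df = delta k`, its chi-square p-value, and the AIC difference. Pairs
#' whose fixed-effect sets are not nested are refused for the LRT (AIC-only
#' row, `p_value = NA`).
#'
#' @param fits List of `patch_lmm_fit`s, ordered from smallest to largest.
#' @return Tibble with one row per consecutive pair: `model_a`, `model_b`,
#'   `chisq`, `df`, `p_value`, `delta_aic` (AIC_b - AIC_a; negative favors
#'   the larger model), `nested`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2L)
  purrr::map_dfr(seq_len(length(fits) - 1L), function(i) {
    a <- fits[[i]]; b <- fits[[i + 1L]]
    nested <- all(model_terms[[a$model_id]] %in% model_terms[[b$model_id]])
    dk <- b$n_params_ml - a$n_params_ml
    if (nested && dk >= 0) {
      chisq <- max(0, 2 * (b$loglik_ml - a$loglik_ml))
      p <- if (dk == 0) 1 else stats::pchisq(chisq, dk, lower.tail = FALSE)
      tibble::tibble(model_a = a$model_id, model_b = b$model_id,
                     chisq = chisq, df = dk, p_value = p,
                     delta_aic = b$aic - a$aic, nested = TRUE)
    } else {
      tibble::tibble(model_a = a$model_id, model_b = b$model_id,
                     chisq = NA_real_, df = NA_integer_, p_value = NA_real_,
                     delta_aic = b$aic - a$aic, nested = FALSE)
    }
  })
}

#' Decile-bin summary of patch fixation density against one predictor
#'
#' Assigns every scene patch to a decile bin of the chosen predictor and
#' averages the relative fixation density per bin. For head and body
#' coverage, patches containing none of the feature form an additional
#' zero-coverage bin and the deciles are computed over the remaining
#' patches. Distance-from-center has only 27 distinct values on the default
#' grid, so its bins are uneven (roughly 7-13% of patches each); bins are
#' formed by the empirical quantiles with ties assigned to the lower bin.
#'
#' @param records Pooled patch tibble (raw, from [patchify()]).
#' @param predictor One of `"dist_center"`, `"rel_saliency"`, `"rel_head"`,
#'   `"rel_body"`.
#' @return Tibble `bin` (factor; `"0"` = zero-coverage bin where
#'   applicable, then `"1"`-`"10"`), `n`, `mean_rel_fix_density`, `sem`.
#' @export
decile_bin_summary <- function(records,
                               predictor = c("dist_center", "rel_saliency",
                                             "rel_head", "rel_body")) {
  predictor <- match.arg(predictor)
  v <- records[[predictor]]
  y <- records$rel_fix_density
  zero_bin <- predictor %in% c("rel_head", "rel_body")
  keep <- if (zero_bin) v > 0 else rep(TRUE, length(v))
  vk <- v[keep]
  n_distinct_pos <- length(unique(vk))
  n_bins <- min(10L, n_distinct_pos)
  if (n_bins < 10L) warning("fewer than 10 distinct values; coarser bins")
  qs <- stats::quantile(vk, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  qs <- unique(qs)
  bin_idx <- cut(vk, breaks = qs, labels = FALSE)
  df <- tibble::tibble(bin = as.character(bin_idx), y = y[keep])
  if (zero_bin) {
    df <- dplyr::bind_rows(tibble::tibble(bin = "0", y = y[!keep]), df)
  }
  lv <- c(if (zero_bin) "0", as.character(seq_len(max(bin_idx))))
  df |>
    dplyr::mutate(bin = factor(.data$bin, levels = lv)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rel_fix_density = mean(.data$y),
      sem = stats::sd(.data$y) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}
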