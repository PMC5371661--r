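# Independent brute-force oracles used to validate the package's metric and
# ANOVA implementations, plus small shared fixtures.

# KL divergence D(F||S) by explicit cell loop after epsilon-regularized
# sum-normalization.
oracle_kl <- function(f, s, epsilon = 1e-12) {
  fv <- as.vector(f) + epsilon
  sv <- as.vector(s) + epsilon
  fv <- fv / sum(fv)
  sv <- sv / sum(sv)
  total <- 0
  for (i in seq_along(fv)) total <- total + fv[i] * log(fv[i] / sv[i])
  total
}

# AUC by all-pairs concordance counting with 0.5 credit for score ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Pearson r from first principles on the sum-normalized maps.
oracle_r <- function(f, s, epsilon = 1e-12) {
  fv <- as.vector(f) + epsilon; fv <- fv / sum(fv)
  sv <- as.vector(s) + epsilon; sv <- sv / sum(sv)
  num <- sum((fv - mean(fv)) * (sv - mean(sv)))
  num / sqrt(sum((fv - mean(fv))^2) * sum((sv - mean(sv))^2))
}

# One-way within-subject ANOVA via the classic sums-of-squares formulas and
# the textbook Greenhouse-Geisser / Huynh-Feldt epsilon expressions on the
# condition covariance matrix (independent of the package's orthonormal
# contrast route).
oracle_rm_anova_1way <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  grand <- mean(wide)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f_val <- (ss_cond / df1) / (ss_err / df2)
  S <- stats::cov(wide)
  sbar <- mean(S)
  di <- diag(S)
  row_m <- rowMeans(S)
  gg_num <- (k * (mean(di) - sbar))^2
  gg_den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_m^2) + k^2 * sbar^2)
  gg <- gg_num / gg_den
  hf <- (n * (k - 1) * gg - 2) / ((k - 1) * (n - 1 - (k - 1) * gg))
  hf <- min(1, max(hf, 1 / (k - 1)))
  list(
    F = f_val, df1 = df1, df2 = df2,
    gg = gg, hf = hf,
    p_hf = stats::pf(f_val, df1 * hf, df2 * hf, lower.tail = FALSE),
    eta_p = ss_cond / (ss_cond + ss_err)
  )
}

# Gaussian-correlated within-subject null data with AR(1) covariance
# (violates sphericity).
make_ar1_null <- function(n, k, rho = 0.7, sd = 1) {
  S <- sd^2 * rho^abs(outer(seq_len(k), seq_len(k), `-`))
  L <- chol(S)
  matrix(stats::rnorm(n * k), n, k) %*% L
}

# Small viewing geometry for fast map tests: 16 x 12 px toy raster.
toy_geometry <- function(w = 16L, h = 12L) {
  viewing_geometry(image_width_px = w, image_height_px = h)
}

# Long tibble from a participants x conditions matrix.
long_from_wide <- function(wide, factor_name = "cond") {
  df <- tidyr::expand_grid(
    participant_id = seq_len(nrow(wide)),
    lvl = colnames(wide) %||% as.character(seq_len(ncol(wide)))
  )
  df[[factor_name]] <- df$lvl
  df$lvl <- NULL
  df$y <- as.vector(t(wide))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a


# Merge consecutive generator fixations whose separation is below the
# saccade-detectability scale (tiny position shifts produce sub-threshold
# velocities and are legitimately read as one fixation).
merge_close_fixations <- function(fx, min_sep_px = 8) {
  out <- fx[1, ]
  for (i in seq_len(nrow(fx))[-1]) {
    last <- nrow(out)
    d <- sqrt((fx$x[i] - out$x[last])^2 + (fx$y[i] - out$y[last])^2)
    if (d < min_sep_px) {
      w1 <- out$duration[last]; w2 <- fx$duration[i]
      out$x[last] <- (out$x[last] * w1 + fx$x[i] * w2) / (w1 + w2)
      out$y[last] <- (out$y[last] * w1 + fx$y[i] * w2) / (w1 + w2)
      out$t_end[last] <- fx$t_end[i]
      out$duration[last] <- out$duration[last] + fx$duration[i]
    } else {
      out <- rbind(out, fx[i, ])
    }
  }
  out
}


# Fixations whose neighbors are far enough away that detection cannot have
# merged or blended them (position claims are made only for these).
isolated_fixations <- function(fx, min_sep_px = 16) {
  n <- nrow(fx)
  d_prev <- c(Inf, sqrt(diff(fx$x)^2 + diff(fx$y)^2))
  d_next <- c(d_prev[-1], Inf)
  d_prev >= min_sep_px & d_next >= min_sep_px
}
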