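#' Paired t-test with paired effect size
#'
#' Standard two-sided (or one-sided) paired t-test plus Cohen's d for paired
#' data, by default d_z = mean(difference) / SD(difference). The
#' alternative formulation mean(difference) / pooled SD is available via
#' `d_method = "pooled"`.
#'
#' @param a,b Numeric vectors of per-participant means, paired by position;
#'   length >= 3.
#' @param tails `"two"` (default), `"greater"` or `"less"` (alternative for
#'   `a - b`).
#' @param d_method `"dz"` (default) or `"pooled"`.
#' @return One-row tibble: `t`, `df`, `p`, `d`, `mean_diff`. Zero variance
#'   of the differences with a nonzero mean yields infinite `t` (p = 0),
#'   flagged by `degenerate = TRUE`.
#' @export
paired_t <- function(a, b, tails = c("two", "greater", "less"),
                     d_method = c("dz", "pooled")) {
  tails <- match.arg(tails)
  d_method <- match.arg(d_method)
  stopifnot(length(a) == length(b), length(a) >= 3)
  diffs <- a - b
  sd_d <- stats::sd(diffs)
  m_d <- mean(diffs)
  n <- length(diffs)
  if (sd_d == 0) {
    t_val <- if (m_d == 0) 0 else sign(m_d) * Inf
    p <- if (m_d == 0) 1 else 0
    d <- if (m_d == 0) 0 else sign(m_d) * Inf
    return(tibble::tibble(t = t_val, df = n - 1, p = p, d = d,
                          mean_diff = m_d, degenerate = TRUE))
  }
  alt <- switch(tails, two = "two.sided", greater = "greater", less = "less")
  tt <- stats::t.test(a, b, paired = TRUE, alternative = alt)
  d <- switch(d_method,
    dz = m_d / sd_d,
    pooled = m_d / sqrt((stats::var(a) + stats::var(b)) / 2)
  )
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = d, mean_diff = m_d, degenerate = FALSE)
}

#' Cohen's d
#'
#' Two-sample d uses the pooled standard deviation; paired d defaults to
#' d_z (mean difference over SD of differences).
#'
#' @param a,b Numeric vectors (paired by position when `paired = TRUE`).
#' @param paired Paired-data formulation? (default FALSE).
#' @param method For paired data, `"dz"` or `"pooled"`.
#' @return Numeric scalar.
#' @export
cohens_d <- function(a, b, paired = FALSE, method = c("dz", "pooled")) {
  method <- match.arg(method)
  if (paired) {
    stopifnot(length(a) == length(b))
    diffs <- a - b
    if (method == "dz") return(mean(diffs) / stats::sd(diffs))
    return(mean(diffs) / sqrt((stats::var(a) + stats::var(b)) / 2))
  }
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

# Orthonormal contrast basis spanning the deviations-from-mean space of k
# levels (k-1 columns).
orthonormal_contrasts <- function(k) {
  c_full <- stats::contr.helmert(k)
  qr.Q(qr(c_full))
}

# Huynh-Feldt epsilon for one within factor (or interaction) given the
# n x k matrix of scores whose columns are the crossed cells, and the
# contrast matrix C (k x c) defining the effect space.
hf_epsilon <- function(scores, C, n) {
  E <- stats::cov(scores %*% C)  # c x c covariance of contrast scores
  c_dim <- ncol(E)
  gg <- (sum(diag(E)))^2 / (c_dim * sum(E * E))  # Greenhouse-Geisser
  hf <- (n * c_dim * gg - 2) / (c_dim * (n - 1 - c_dim * gg))
  min(1, max(hf, 1 / c_dim))
}

#' Repeated-measures ANOVA with Huynh-Feldt correction
#'
#' Univariate sums-of-squares decomposition for fully within-subject
#' designs with one or two factors, using the participant x factor
#' interaction as the error stratum of each effect. For every effect with
#' more than one numerator degree of freedom, Huynh-Feldt's epsilon is
#' estimated from the covariance matrix of the effect's orthonormal
#' contrast scores and applied to both degrees of freedom before computing
#' the p-value; a two-level factor has epsilon = 1 by definition. Partial
#' eta squared is SS_effect / (SS_effect + SS_error).
#'
#' @param data Long tibble with one row per participant x condition cell
#'   (complete and balanced; one observation per cell).
#' @param dv Name of the response column (string).
#' @param within Character vector of 1 or 2 within-factor column names.
#' @param participant Name of the participant column (default
#'   `"participant_id"`).
#' @return Tibble with one row per effect: `effect`, `df_num`, `df_den`,
#'   `F`, `epsilon_hf`, `p` (HF-corrected), `eta_sq_partial`.
#' @export
rm_anova <- function(data, dv, within, participant = "participant_id") {
  stopifnot(length(within) %in% 1:2)
  data <- dplyr::ungroup(data)
  for (f in c(within, participant)) {
    data[[f]] <- droplevels(factor(data[[f]]))
  }
  cells <- do.call(interaction, c(unname(data[within]), list(drop = FALSE)))
  wide <- tapply(data[[dv]], list(data[[participant]], cells), mean)
  if (anyNA(wide)) {
    drop_n <- sum(apply(wide, 1, anyNA))
    warning(sprintf("incomplete design: %d participant(s) dropped listwise",
                    drop_n))
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  }
  n <- nrow(wide)
  levs <- lapply(within, function(f) levels(data[[f]]))
  ks <- vapply(levs, length, integer(1))
  if (n <= max(ks)) warning("few participants relative to factor levels; Huynh-Feldt epsilon clamped at its lower bound may occur")

  # wide columns are ordered by interaction(): first factor varies fastest
  effects <- list()
  if (length(within) == 1L) {
    C <- orthonormal_contrasts(ks[1])
    effects[[within[1]]] <- C
  } else {
    k1 <- ks[1]; k2 <- ks[2]
    C1 <- orthonormal_contrasts(k1)
    C2 <- orthonormal_contrasts(k2)
    one1 <- matrix(1 / sqrt(k1), k1, 1)
    one2 <- matrix(1 / sqrt(k2), k2, 1)
    # column order: factor 1 fastest within factor 2 (interaction() order)
    effects[[within[1]]] <- kronecker(one2, C1)
    effects[[within[2]]] <- kronecker(C2, one1)
    effects[[paste(within[1], within[2], sep = ":")]] <- kronecker(C2, C1)
  }

  purrr::imap_dfr(effects, function(C, nm) {
    scores <- wide %*% C  # n x c
    c_dim <- ncol(C)
    ss_eff <- n * sum(colMeans(scores)^2)
    ss_err <- sum(sweep(scores, 2, colMeans(scores))^2)
    df_num <- c_dim
    df_den <- c_dim * (n - 1)
    f_val <- (ss_eff / df_num) / (ss_err / df_den)
    eps <- if (c_dim == 1L) 1 else hf_epsilon(wide, C, n)
    p <- stats::pf(f_val, df_num * eps, df_den * eps, lower.tail = FALSE)
    tibble::tibble(effect = nm, df_num = df_num, df_den = df_den,
                   F = f_val, epsilon_hf = eps, p = p,
                   eta_sq_partial = ss_eff / (ss_eff + ss_err))
  })
}

#' Bonferroni-corrected pairwise post hoc tests
#'
#' Paired t-tests for every requested pair of conditions, flagged
#' significant at alpha / m where m is the number of comparisons.
#'
#' @param data Long tibble as in [rm_anova()].
#' @param dv Response column name.
#' @param factor_name Condition column name.
#' @param participant Participant column name.
#' @param comparisons Optional list of length-2 character vectors; default
#'   all pairs of condition levels.
#' @param alpha Family significance level (default 0.05).
#' @return Tibble per pair: `a`, `b`, `t`, `df`, `p`, `d`,
#'   `p_threshold` (= alpha / m), `significant`.
#' @export
bonferroni_posthoc <- function(data, dv, factor_name,
                               participant = "participant_id",
                               comparisons = NULL, alpha = 0.05) {
  data[[factor_name]] <- factor(data[[factor_name]])
  levs <- levels(data[[factor_name]])
  if (is.null(comparisons)) {
    comparisons <- utils::combn(levs, 2, simplify = FALSE)
  }
  m <- length(comparisons)
  thr <- alpha / m
  wide <- tapply(data[[dv]], list(data[[participant]], data[[factor_name]]),
                 mean)
  purrr::map_dfr(comparisons, function(pr) {
    res <- paired_t(wide[, pr[1]], wide[, pr[2]])
    tibble::tibble(a = pr[1], b = pr[2], t = res$t, df = res$df, p = res$p,
                   d = res$d, p_threshold = thr, significant = res$p < thr)
  })
}
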