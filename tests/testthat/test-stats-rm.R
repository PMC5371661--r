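test_that("paired t matches hand computation and handles degeneracy", {
  res <- paired_t(c(2, 4, 7), c(1, 3, 5))
  expect_equal(res$t, 4, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$d, (4 / 3) / sd(c(1, 1, 2)), tolerance = 1e-6)

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_equal(same$p, 1)

  degen <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(degen$degenerate)
  expect_equal(degen$t, Inf)
})

test_that("cohen's d formulations", {
  a <- c(3, 5, 8, 9); b <- c(1, 4, 5, 6)
  expect_equal(cohens_d(a, b, paired = TRUE),
               mean(a - b) / sd(a - b))
  sp <- sqrt((var(a) + var(b)) / 2)
  expect_equal(cohens_d(a, b, paired = TRUE, method = "pooled"),
               mean(a - b) / sp)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
})

test_that("two-level rm anova reproduces the paired t (F = t^2, eps = 1)", {
  set.seed(14)
  wide <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  res <- rm_anova(long_from_wide(wide), "y", "cond")
  tt <- t.test(wide[, 1], wide[, 2], paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$epsilon_hf, 1)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)
})

test_that("one-way rm anova equals the independent matrix-algebra oracle", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(8:25, 1); k <- sample(3:6, 1)
    wide <- make_ar1_null(n, k, rho = runif(1, 0.2, 0.8)) +
      matrix(rnorm(k, 0, 0.5), n, k, byrow = TRUE)
    colnames(wide) <- paste0("c", seq_len(k))
    res <- rm_anova(long_from_wide(wide), "y", "cond")
    orc <- oracle_rm_anova_1way(wide)
    expect_equal(res$F, orc$F, tolerance = 1e-9)
    expect_equal(res$epsilon_hf, orc$hf, tolerance = 1e-9)
    expect_equal(res$p, orc$p_hf, tolerance = 1e-9)
    expect_equal(res$eta_sq_partial, orc$eta_p, tolerance = 1e-9)
  }
})

test_that("partial eta squared is invariant to affine response rescaling", {
  set.seed(16)
  wide <- make_ar1_null(12, 4) + matrix(c(0, 0.3, 0.6, 0.9), 12, 4,
                                        byrow = TRUE)
  colnames(wide) <- paste0("c", 1:4)
  r1 <- rm_anova(long_from_wide(wide), "y", "cond")
  wide2 <- 3.7 * wide + 11
  r2 <- rm_anova(long_from_wide(wide2), "y", "cond")
  expect_equal(r1$eta_sq_partial, r2$eta_sq_partial, tolerance = 1e-9)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
})

test_that("two-way rm anova recovers known main effects and interaction", {
  # deterministic structure plus small noise: check effect attribution
  set.seed(17)
  n <- 16
  d <- tidyr::expand_grid(participant_id = seq_len(n),
                          f1 = c("x", "y", "z"), f2 = c("lo", "hi"))
  main1 <- c(x = 0, y = 1, z = 2)[d$f1]
  main2 <- c(lo = 0, hi = 0.5)[d$f2]
  d$y <- main1 + main2 + rnorm(nrow(d), 0, 0.3)
  res <- rm_anova(d, "y", c("f1", "f2"))
  expect_equal(res$effect, c("f1", "f2", "f1:f2"))
  expect_equal(res$df_num, c(2, 1, 2))
  expect_equal(res$df_den, c(2 * (n - 1), n - 1, 2 * (n - 1)))
  expect_lt(res$p[1], 0.001)
  expect_lt(res$p[2], 0.001)
  expect_gt(res$p[3], 0.05)  # no interaction simulated
  expect_equal(res$epsilon_hf[2], 1)  # 2-level factor
})

test_that("huynh-feldt correction keeps type-I error near nominal under sphericity violation", {
  set.seed(18)
  n_reps <- 400
  rejections <- 0L
  for (i in seq_len(n_reps)) {
    wide <- make_ar1_null(15, 4, rho = 0.75)
    colnames(wide) <- paste0("c", 1:4)
    res <- rm_anova(long_from_wide(wide), "y", "cond")
    if (res$p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_reps, 0.03)
  expect_lte(rejections / n_reps, 0.07)
})

test_that("bonferroni post hocs threshold at alpha over m", {
  set.seed(19)
  wide <- cbind(a = rnorm(12), b = rnorm(12) + 3, c = rnorm(12),
                d = rnorm(12))
  ph <- bonferroni_posthoc(long_from_wide(wide), "y", "cond")
  expect_equal(nrow(ph), 6L)
  expect_equal(unique(ph$p_threshold), 0.05 / 6, tolerance = 1e-9)
  expect_true(all(ph$significant == (ph$p < 0.05 / 6)))
  expect_true(ph$significant[ph$a == "a" & ph$b == "b"])
  # identical conditions are never significant
  same <- bonferroni_posthoc(
    long_from_wide(cbind(a = rnorm(10), b = rnorm(10))), "y", "cond"
  )
  expect_false(any(same$significant))
})
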