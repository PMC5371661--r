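make_masks <- function(h = 60, w = 80, head_frac = 0.02, body_frac = 0.09) {
  head <- matrix(FALSE, h, w); body <- matrix(FALSE, h, w)
  n_head <- round(head_frac * h * w); n_body <- round(body_frac * h * w)
  head[seq_len(n_head)] <- TRUE
  body[n_head + seq_len(n_body)] <- TRUE
  list(head = head, body = body)
}

test_that("the saliency split puts 80% of free pixels in the lower region", {
  set.seed(3)
  h <- 90; w <- 120
  sal <- matrix(runif(h * w), h, w)  # continuous, tie-free
  empty <- matrix(FALSE, h, w)
  rs <- build_roi_set(empty, empty, sal)
  expect_equal(rs$areas$area_fraction[rs$areas$roi == "lower"], 0.80,
               tolerance = 2 / (h * w) / 0.8)
  # rank-based: monotone transform leaves the partition unchanged
  rs2 <- build_roi_set(empty, empty, sal^3 + 2)
  expect_identical(rs$lower, rs2$lower)
})

test_that("the four regions partition the scene exactly", {
  set.seed(13)
  m <- make_masks()
  sal <- matrix(runif(60 * 80), 60, 80)
  rs <- build_roi_set(m$head, m$body, sal)
  total <- rs$head + rs$body + rs$lower + rs$higher
  expect_true(all(total == 1))
  # head 2% + body 9% leaves ~ 0.8 * 0.89 = 71.2% in the lower region
  expect_equal(rs$areas$area_fraction[rs$areas$roi == "lower"],
               0.8 * (1 - 0.02 - 0.09), tolerance = 0.01)
})

test_that("body mask excludes overlapping head pixels", {
  h <- 60; w <- 80
  head <- matrix(FALSE, h, w); head[1:10, 1:10] <- TRUE
  body <- matrix(FALSE, h, w); body[5:20, 1:10] <- TRUE  # overlaps head
  sal <- matrix(runif(h * w), h, w)
  rs <- build_roi_set(head, body, sal)
  expect_false(any(rs$head & rs$body))
  expect_equal(sum(rs$body), 16 * 10 - 6 * 10)
})

test_that("relative saliency identities hold", {
  m <- make_masks()
  uniform <- matrix(0.4, 60, 80)
  rs <- suppressWarnings(build_roi_set(m$head, m$body, uniform))
  # degenerate: constant saliency -> higher region empty, flagged
  expect_equal(sum(rs$higher), 0)

  set.seed(5)
  sal <- matrix(runif(60 * 80), 60, 80)
  rs2 <- build_roi_set(m$head, m$body, sal)
  scores <- roi_relative_saliency(rs2, sal)
  # area-weighted mean of relative saliency is exactly 1
  expect_equal(sum(scores$rel_saliency * rs2$areas$area_fraction), 1,
               tolerance = 1e-12)
  u_scores <- roi_relative_saliency(rs2, matrix(1, 60, 80))
  expect_equal(u_scores$rel_saliency, rep(1, 4))
})

test_that("area-normalized fixation density identities hold", {
  m <- make_masks()
  set.seed(6)
  sal <- matrix(runif(60 * 80), 60, 80)
  rs <- build_roi_set(m$head, m$body, sal)

  uniform_density <- matrix(0.5, 60, 80)
  sc <- roi_norm_fixation_density(rs, uniform_density)
  expect_equal(sc$rel_norm_density, rep(1, 4), tolerance = 1e-12)
  expect_equal(sum(sc$proportion), 1, tolerance = 1e-12)

  # all mass in the head region: score = 1 / head area fraction
  d <- matrix(0, 60, 80); d[rs$head] <- 1
  sc2 <- roi_norm_fixation_density(rs, d)
  head_frac <- rs$areas$area_fraction[rs$areas$roi == "head"]
  expect_equal(sc2$rel_norm_density[sc2$roi == "head"], 1 / head_frac)
  expect_equal(sc2$rel_norm_density[sc2$roi != "head"], rep(0, 3))

  # area-fraction-weighted mean of scores is exactly 1
  set.seed(8)
  d3 <- matrix(rexp(60 * 80), 60, 80)
  sc3 <- roi_norm_fixation_density(rs, d3)
  expect_equal(sum(sc3$rel_norm_density * rs$areas$area_fraction), 1,
               tolerance = 1e-12)
  expect_error(roi_norm_fixation_density(rs, matrix(0, 60, 80)), "zero")
})

test_that("social masks covering the whole scene are refused", {
  h <- 64; w <- 64
  head <- matrix(FALSE, h, w); head[, 1:32] <- TRUE
  body <- matrix(FALSE, h, w); body[, 33:64] <- TRUE
  expect_error(build_roi_set(head, body, matrix(runif(h * w), h, w)),
               "entire scene")
})
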