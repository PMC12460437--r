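test_that("contrast mask matches the hand-evaluated box filter", {
  img <- matrix(0, 5, 5)
  img[3, 3] <- 1
  m <- contrast_mask(img, window = 3, threshold = 0.5)
  # centre: (1 - 1/9)^2 ~ 0.790 > 0.5; 4-neighbours: (0 - 1/9)^2 ~ 0.012
  expect_equal(m[3, 3], 1)
  expect_equal(m[2, 3], 0)
  expect_equal(m[3, 2], 0)
  expect_true(all(m[img == 0] == 0))
  # constant image: no contrast anywhere
  expect_true(all(contrast_mask(matrix(0.7, 8, 8), 3, 1e-6) == 0))
  # infinite threshold: nothing passes
  expect_true(all(contrast_mask(matrix(runif(64), 8, 8), 3, Inf) == 0))
  expect_error(contrast_mask(img, window = 4), "odd")
})

test_that("mask construction reproduces the thresholding rule exactly", {
  # enumerate all salient/contrast combinations on a 3x3 grid
  combos <- expand.grid(s = 0:1, c = 0:1)
  sal <- matrix(rep(combos$s, length.out = 9), 3, 3)
  con <- matrix(rep(combos$c, length.out = 9), 3, 3)
  ms <- build_masks(sal, con)
  expect_equal(ms$m_sum, sal + con)
  expect_equal(ms$m_ir, (sal + con > 0) * 1)     # 1 iff the sum is positive
  expect_equal(ms$m_ir + ms$m_vi, matrix(1, 3, 3))
  # salient and contrast both set -> sum 2 -> still mask 1
  both <- build_masks(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_true(all(both$m_sum == 2) && all(both$m_ir == 1))
  # nothing set -> complement covers everything
  none <- build_masks(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(all(none$m_ir == 0) && all(none$m_vi == 1))
  # fully salient dominates regardless of contrast
  allsal <- build_masks(matrix(1, 2, 2), matrix(0, 2, 2))
  expect_true(all(allsal$m_ir == 1) && all(allsal$m_vi == 0))
  expect_error(build_masks(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("intensity loss vanishes at the mask-composited minimizer", {
  set.seed(1)
  i_ir <- matrix(runif(36), 6); i_vi <- matrix(runif(36), 6)
  masks <- build_masks(matrix(rbinom(36, 1, 0.4), 6),
                       matrix(rbinom(36, 1, 0.3), 6))
  i_f <- masks$m_ir * i_ir + masks$m_vi * i_vi
  expect_equal(intensity_loss(i_f, i_ir, i_vi, masks), 0)
  # constant deviation under a full infrared mask equals the constant
  full <- build_masks(matrix(1, 6, 6), matrix(0, 6, 6))
  expect_equal(intensity_loss(i_ir + 0.3, i_ir, i_vi, full), 0.3,
               tolerance = 1e-12)
})

test_that("intensity loss matches the per-pixel summation oracle", {
  set.seed(2)
  for (rep in 1:20) {
    i_f <- matrix(runif(16), 4); i_ir <- matrix(runif(16), 4)
    i_vi <- matrix(runif(16), 4)
    masks <- build_masks(matrix(rbinom(16, 1, 0.5), 4),
                         matrix(rbinom(16, 1, 0.5), 4))
    expect_equal(intensity_loss(i_f, i_ir, i_vi, masks),
                 intensity_loss_oracle(i_f, i_ir, i_vi, masks$m_ir,
                                       masks$m_vi),
                 tolerance = 1e-12)
  }
})

test_that("intensity loss is 1-Lipschitz in the fused image", {
  set.seed(8)
  i_ir <- matrix(runif(64), 8); i_vi <- matrix(runif(64), 8)
  masks <- build_masks(matrix(rbinom(64, 1, 0.5), 8), matrix(0, 8, 8))
  f1 <- matrix(runif(64), 8); f2 <- matrix(runif(64), 8)
  dl <- abs(intensity_loss(f1, i_ir, i_vi, masks) -
            intensity_loss(f2, i_ir, i_vi, masks))
  expect_lte(dl, sum(abs(f1 - f2)) / 64 + 1e-12)
})

test_that("Sobel magnitude has its closed-form responses", {
  expect_lt(max(sobel_gradient(matrix(0.4, 6, 6))), 1e-12)
  ramp <- matrix(rep(0:7, each = 8), 8, 8)      # img(i, j) = j - 1, unit steps
  g <- sobel_gradient(ramp)
  expect_true(all(abs(g[2:7, 2:7] - 8) < 1e-12))  # interior: |Gx| = 8, Gy = 0
  # transposition swaps the two kernel responses, magnitude is unchanged
  set.seed(3)
  x <- matrix(runif(49), 7)
  expect_equal(sobel_gradient(t(x)), t(sobel_gradient(x)), tolerance = 1e-12)
  expect_equal(sobel_gradient(x), sobel_naive(x), tolerance = 1e-12)
})

test_that("texture loss vanishes on identical or flat inputs", {
  set.seed(4)
  x <- matrix(runif(25), 5)
  expect_equal(texture_loss(x, x, x), 0)
  k <- matrix(0.3, 5, 5)
  expect_equal(texture_loss(k, k * 0 + 0.9, k * 0 + 0.1), 0)
  for (rep in 1:10) {
    a <- matrix(runif(25), 5); b <- matrix(runif(25), 5); f <- matrix(runif(25), 5)
    expect_equal(texture_loss(f, a, b), texture_loss_oracle(f, a, b),
                 tolerance = 1e-12)
  }
})

test_that("total loss arithmetic and variants follow their definitions", {
  set.seed(5)
  i_ir <- matrix(runif(36), 6); i_vi <- matrix(runif(36), 6)
  masks <- build_masks(matrix(rbinom(36, 1, 0.4), 6), matrix(0, 6, 6))
  # construct a fused image with known l_int and verify lambda weighting
  lv <- total_loss(matrix(runif(36), 6), i_ir, i_vi, masks, lambda = 5)
  expect_equal(lv$l_total, lv$l_text + 5 * lv$l_int, tolerance = 1e-12)
  # variant max: zero intensity term at the element-wise maximum
  fmax <- pmax(i_ir, i_vi)
  lmax <- total_loss(fmax, i_ir, i_vi, lambda = 5, variant = "max")
  expect_equal(lmax$l_int, 0)
  # variant pixel: everything equal -> total zero
  lpix <- total_loss(i_ir, i_ir, i_ir, lambda = 5, variant = "pixel")
  expect_equal(lpix$l_total, 0)
  # no_texture drops the texture term from the total
  lnt <- total_loss(matrix(runif(36), 6), i_ir, i_vi, masks, lambda = 5,
                    variant = "no_texture")
  expect_equal(lnt$l_total, 5 * lnt$l_int, tolerance = 1e-12)
  expect_error(total_loss(i_ir, i_ir, i_vi, lambda = 0), "lambda")
})

test_that("the differentiable loss graph agrees with the array losses", {
  ns <- asNamespace("mmfuse")
  set.seed(6)
  i_f <- matrix(runif(64), 8); i_ir <- matrix(runif(64), 8)
  i_vi <- matrix(runif(64), 8)
  masks <- build_masks(matrix(rbinom(64, 1, 0.4), 8),
                       contrast_mask(i_ir, 3, 0.02))
  for (variant in c("mask", "pixel", "max", "no_texture")) {
    cfg <- fusion_config(profile = "desk", loss_variant = variant)
    tp <- ns$ad_tape()
    lo <- ns$g_total_loss(tp, ns$ad_const(tp, ns$as3d(i_f)), i_ir, i_vi,
                          masks, cfg)
    expect_equal(ns$ad_value(tp, lo$total),
                 total_loss(i_f, i_ir, i_vi, masks, lambda = cfg$lambda,
                            variant = variant)$l_total,
                 tolerance = 1e-10)
  }
})
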