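test_that("image gradients use central/one-sided differences", {
  expect_equal(image_gradients(matrix(0.5, 5, 5)),
               list(gx = matrix(0, 5, 5), gy = matrix(0, 5, 5)))
  # vertical linear ramp: gy constant, gx zero
  H <- 6
  ramp <- matrix(rep((0:(H - 1)) / (H - 1), 4), H, 4)
  g <- image_gradients(ramp)
  expect_equal(g$gy, matrix(1 / (H - 1), H, 4))
  expect_equal(g$gx, matrix(0, H, 4))
  # hand-computed central difference at a step
  m <- rbind(rep(0, 3), rep(0, 3), rep(1, 3))
  expect_equal(image_gradients(m)$gy[2, ], rep(0.5, 3))
})

test_that("normalise01 maps ranges linearly and constants to zero", {
  expect_equal(normalise01(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(normalise01(rep(4, 5)), rep(0, 5))
  set.seed(13)
  for (i in 1:10) {
    m <- matrix(rnorm(24), 4, 6)
    n <- normalise01(m)
    expect_equal(min(n), 0)
    expect_equal(max(n), 1)
  }
})

test_that("cost maps are low on a frontier of the requested polarity", {
  img <- two_band_image(12, 10, 6)     # dark over bright, step at row 6
  cm <- build_cost_map(img, "dark_to_bright")
  expect_s3_class(cm, "oct_costmap")
  expect_equal(range(cm$values), c(0, 1))
  expect_equal(which.min(rowMeans(cm$values)) - 1, 6)
  # flipped polarity: clamping removes the transition entirely
  cm2 <- build_cost_map(img, "bright_to_dark")
  expect_false(which.min(rowMeans(cm2$values)) - 1 == 6)
})

test_that("a constant image yields a degenerate all-zero cost map", {
  cm <- build_cost_map(matrix(0.5, 6, 6), "dark_to_bright")
  expect_true(cm$degenerate)
  expect_equal(cm$values, matrix(0, 6, 6))
})

test_that("each polarity finds its own transition on a two-step image", {
  # dark band, bright band, dark band, with mixed pixels at the transitions
  img <- matrix(0.1, 18, 8)
  img[7, ] <- 0.5; img[8:12, ] <- 0.9; img[13, ] <- 0.5
  d2b <- build_cost_map(img, "dark_to_bright")
  b2d <- build_cost_map(img, "bright_to_dark")
  expect_equal(which.min(rowMeans(d2b$values)) - 1, 6)
  expect_equal(which.min(rowMeans(b2d$values)) - 1, 12)
})

test_that("larger lambda deepens the frontier's relative cost advantage", {
  img <- two_band_image(12, 10, 6)
  # normalized cost at the gradient shoulder (half the peak gv) shrinks as
  # lambda grows: the frontier stands out more sharply from the background
  prev <- Inf
  for (lam in c(1, 5, 10, 50)) {
    cm <- build_cost_map(img, "dark_to_bright", lambda = lam)
    shoulder <- mean(cm$values[6, ])
    expect_equal(mean(cm$values[7, ]), 0)  # the peak row is always minimal
    expect_lte(shoulder, prev + 1e-12)
    prev <- shoulder
  }
})
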