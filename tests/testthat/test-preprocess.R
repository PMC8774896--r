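test_that("tv_denoise leaves constants and smooth=0 inputs untouched", {
  m <- matrix(0.4, 10, 12)
  expect_equal(tv_denoise(m, 0.5), m)
  noisy <- matrix(runif(120), 10, 12)
  expect_identical(tv_denoise(noisy, 0), noisy)
})

test_that("tv_denoise reduces total variation of a noisy step image", {
  set.seed(5)
  img <- two_band_image(24, 24, 12)
  img <- pmin(pmax(img + matrix(rnorm(576, 0, 0.08), 24, 24), 0), 1)
  out <- tv_denoise(img, 0.1)
  expect_lt(tv2d(out), tv2d(img))
  expect_true(all(out >= 0 & out <= 1))
  # the band structure survives: means of the two halves stay well apart
  expect_gt(mean(out[13:24, ]) - mean(out[1:12, ]), 0.5)
})

test_that("adaptive binarisation follows the local-median rule exactly", {
  # constant image: median - pixel = 0 <= C everywhere
  expect_equal(adaptive_binarise(matrix(0.3, 6, 6),
                                 list(ws = 3, C = 0.01)),
               matrix(1, 6, 6))
  # 5x5 with a dark centre: only the centre drops below its local median
  m <- matrix(0.5, 5, 5); m[3, 3] <- 0
  mask <- adaptive_binarise(m, list(ws = 3, C = 0.01))
  expected <- matrix(1, 5, 5); expected[3, 3] <- 0
  expect_equal(mask, expected)
})

test_that("adaptive binarisation matches the naive median oracle", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(49), 7, 7)
    C <- 0.05
    med <- naive_median_filter(m, 3)
    expected <- (med - m <= C) * 1
    expect_equal(adaptive_binarise(m, list(ws = 3, C = C)), expected)
  }
})

test_that("binarisation is invariant under a global intensity shift", {
  set.seed(31)
  m <- matrix(runif(64, 0.1, 0.6), 8, 8)
  base <- adaptive_binarise(m, list(ws = 3, C = 0.02))
  shifted <- adaptive_binarise(m + 0.3, list(ws = 3, C = 0.02))
  expect_equal(shifted, base)
})

test_that("even windows are forced odd and oversized windows rejected", {
  m <- matrix(runif(100), 10, 10)
  expect_equal(adaptive_binarise(m, list(ws = 4, C = 0.01)),
               adaptive_binarise(m, list(ws = 5, C = 0.01)))
  expect_error(adaptive_binarise(m, list(ws = 25, C = 0.01)),
               "exceeds both", class = "oct_validation_error")
})

test_that("enhance_isos handles the constant-image sign cases", {
  m <- matrix(0.5, 6, 6)
  r0 <- enhance_isos(m, list(ws = 3, enh = 0, smooth = 0))
  expect_equal(r0$mask, matrix(1, 6, 6))  # sIM = 0 -> kept
  expect_equal(r0$enhanced, m)
  r1 <- enhance_isos(m, list(ws = 3, enh = 0.2, smooth = 0))
  expect_equal(r1$mask, matrix(1, 6, 6))  # sIM = -enh < 0 -> kept
})

test_that("a full-window mean keeps only the brighter band", {
  img <- two_band_image(8, 6, 4, top = 0.1, bottom = 0.9)
  r <- enhance_isos(img, list(ws = 8, enh = 0, smooth = 0))
  # the half-mixed transition pixel sits exactly at its local mean, so the
  # threshold-at-zero rule keeps it together with the bright band
  expect_equal(r$mask, (img >= 0.5) * 1)
  expect_equal(r$enhanced, img * (img >= 0.5))
})

test_that("enhancement matches the naive mean-filter oracle", {
  set.seed(41)
  m <- matrix(runif(63), 7, 9)
  enh <- 0.05
  sIM <- naive_mean_filter(m, 5) - m - enh
  expected <- (sIM <= 0) * 1
  r <- enhance_isos(m, list(ws = 5, enh = enh, smooth = 0))
  expect_equal(r$mask, expected)
  expect_equal(r$enhanced, m * expected)
})

test_that("the enhancement mask keeps the IS-OS neighbourhood on phantoms", {
  spec <- default_healthy_spec(256, 300, seed = 2); spec$speckle_k <- Inf
  ph <- generate_phantom(spec)
  r <- enhance_isos(ph$image)  # default parameters
  W <- spec$width
  hit <- 0; tot <- 0
  for (c in seq_len(W)) {
    rows <- round(ph$truth$B7[c]) + (-1:1)
    rows <- rows[rows >= 0 & rows <= spec$height - 1]
    hit <- hit + sum(r$mask[rows + 1, c]); tot <- tot + length(rows)
  }
  expect_gte(hit / tot, 0.95)
})
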