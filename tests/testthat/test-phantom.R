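flat_spec <- function(W = 24, H = 60, ...) {
  phantom_spec(
    width = W, height = H,
    depths = c(10, 15, 20, 25, 30, 36, 40, 44, 48),
    band_intensities = c(0.03, 0.52, 0.38, 0.26, 0.38, 0.10, 0.18, 0.95,
                         0.80, 0.32),
    curve_amp = 0, dip_amp = 0, speckle_k = Inf, blur_sigma = 0, ...)
}

test_that("a flat noise-free spec renders exact horizontal bands", {
  ph <- generate_phantom(flat_spec())
  expect_true(all(apply(ph$image, 1, function(r) length(unique(r)) == 1)))
  for (l in oct_layers) expect_length(unique(ph$truth[[l]]), 1)
  # with integer boundaries, the pixel AT the boundary row mixes the two
  # bands half-and-half (sub-pixel rendering); the step across it matches the
  # band-intensity difference exactly
  v <- ph$spec$band_intensities
  for (i in 1:9) {
    b <- ph$truth[[oct_layers[i]]][1]          # 0-based boundary row
    expect_equal(ph$image[b + 2, 1] - ph$image[b, 1], v[i + 1] - v[i])
    expect_equal(ph$image[b + 1, 1], (v[i] + v[i + 1]) / 2)
  }
})

test_that("generation is deterministic for a fixed seed", {
  spec <- default_healthy_spec(64, 128, seed = 7)
  expect_identical(generate_phantom(spec), generate_phantom(spec))
})

test_that("ground-truth ordering holds across random specs", {
  for (s in 1:8) {
    ph <- generate_phantom(default_healthy_spec(96, 160, seed = s))
    tm <- do.call(rbind, ph$truth[oct_layers])
    expect_true(all(apply(tm, 2, function(col) all(diff(col) >= 0))))
    expect_true(all(tm >= 0 & tm <= ph$spec$height - 1))
    expect_true(all(ph$image >= 0 & ph$image <= 1))
  }
})

test_that("a drusen lifts B8/B9 by exactly its height at its centre", {
  base <- flat_spec(W = 64, H = 120)
  base$depths <- c(10, 20, 30, 40, 50, 60, 70, 90, 100)  # room for the bump
  ph0 <- generate_phantom(base)
  spec <- base
  spec$drusen <- list(list(center = 32, width = 40, height = 12))
  phd <- generate_phantom(spec)
  lift <- ph0$truth$B9 - phd$truth$B9
  expect_equal(max(lift), 12)
  expect_equal(which.max(lift) - 1, 32)  # 0-based centre column
  expect_equal(ph0$truth$B8 - phd$truth$B8, lift)
  expect_equal(phd$truth$B7, ph0$truth$B7)  # anchor untouched
})

test_that("crossing bands are rejected with the offending columns", {
  spec <- flat_spec()
  spec$drusen <- list(list(center = 12, width = 20, height = 10))  # gap is 4
  err <- expect_error(generate_phantom(spec), "cross",
                      class = "oct_validation_error")
  expect_match(conditionMessage(err), "12")
})

test_that("fluid pockets darken and push B4/B5 apart", {
  base <- flat_spec(W = 64, H = 120)
  base$depths <- c(10, 20, 30, 45, 60, 80, 90, 100, 110)
  spec <- base
  spec$fluid <- list(list(center = 32, rx = 12, ry = 8, factor = 0.3))
  ph0 <- generate_phantom(base)
  phf <- generate_phantom(spec)
  expect_lt(phf$truth$B4[33], ph0$truth$B4[33])
  expect_gt(phf$truth$B5[33], ph0$truth$B5[33])
  # compare a pixel that lies in the same (ONL) band in both phantoms and
  # inside the darkened ellipse
  r <- ceiling(phf$truth$B5[33]) + 2
  expect_gt(r, phf$truth$B5[33]); expect_lt(r, phf$truth$B6[33])
  expect_lt(phf$image[r + 1, 33], ph0$image[r + 1, 33])
})

test_that("the default healthy spec encodes the expected contrast ordering", {
  spec <- default_healthy_spec(512, 496, seed = 0)
  expect_length(spec$depths, 9)
  expect_true(all(diff(spec$depths) > 0))
  expect_true(all(spec$depths >= 0 & spec$depths <= 495))
  v <- spec$band_intensities
  expect_true(all(v[1] < v[-1]))             # vitreous is the darkest
  expect_equal(which.min(v[2:10]), 5)        # ONL darkest retinal band
  steps <- abs(diff(v))
  expect_equal(which.max(steps), 7)          # IS-OS is the strongest step
  # and that step is dark-to-bright, matching the anchor stage's polarity
  expect_gt(v[8], v[7])
})

test_that("write_phantom emits image, truth and spec files", {
  d <- withr::local_tempdir()
  ph <- generate_phantom(default_healthy_spec(64, 128, seed = 3))
  write_phantom(ph, d)
  expect_true(all(file.exists(file.path(d, c("phantom.png", "truth.csv",
                                             "spec.json")))))
  tb <- read_boundaries(file.path(d, "truth.csv"))
  expect_equal(unique(tb$layer), oct_layers)
  expect_equal(nrow(tb), 9 * 64)
})
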