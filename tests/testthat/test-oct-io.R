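test_that("images rescale by the maximum representable value on load", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 4, 4), f)  # all pixels 255 in the 8-bit file
  expect_equal(load_image(f), matrix(1, 4, 4))

  png::writePNG(matrix(0, 4, 4), f)
  expect_equal(load_image(f), matrix(0, 4, 4))

  ft <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(c(1, 32768 / 65535), 2, 4), ft, bits.per.sample = 16L)
  img <- load_image(ft)
  expect_equal(img[1, 1], 1)
  expect_equal(img[2, 1], 32768 / 65535)
})

test_that("RGB rasters are averaged to grayscale", {
  f <- withr::local_tempfile(fileext = ".png")
  arr <- array(0, c(3, 4, 3))
  arr[, , 1] <- 0.9; arr[, , 2] <- 0.3; arr[, , 3] <- 0.3
  png::writePNG(arr, f)
  img <- load_image(f)
  expect_equal(img, matrix(0.5, 3, 4), tolerance = 1 / 255)
})

test_that("loading is idempotent after re-saving at the same bit depth", {
  f <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(48), 6, 8), f)
  img <- load_image(f)
  save_image(img, f2)
  expect_identical(load_image(f2), img)
})

test_that("unreadable and oversized inputs raise typed errors", {
  expect_error(load_image(file.path(tempdir(), "missing.png")),
               class = "oct_io_error")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("not an image", f)
  expect_error(load_image(f), class = "oct_io_error")
})

test_that("boundary CSV uses the stable dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_boundaries(list(B7 = c(10, 10)), f)
  expect_identical(readLines(f), c("layer,column,row", "B7,0,10.000",
                                   "B7,1,10.000"))
  write_boundaries(list(), f)
  expect_identical(readLines(f), "layer,column,row")
})

test_that("write/read round trip is the identity on valid boundary maps", {
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(11)
  for (i in 1:10) {
    W <- sample(2:40, 1)
    layers <- sample(oct_layers, sample(1:9, 1))
    bmap <- stats::setNames(
      lapply(layers, function(l) round(runif(W, 0, 300), 3)), layers)
    write_boundaries(bmap, f)
    tb <- read_boundaries(f)
    expect_identical(split(tb$row, tb$layer),
                     bmap[order(names(bmap))])
  }
})

test_that("malformed boundary files are rejected with named problems", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("layer,column,row", "B7,0,10", "B7,2,11"), f)
  expect_error(read_boundaries(f), "non-contiguous",
               class = "oct_validation_error")
  writeLines(c("layer,column,row", "B10,0,10"), f)
  expect_error(read_boundaries(f), "B10", class = "oct_validation_error")
  writeLines(c("layer,column,row", "B1,0,10", "B2,0,5", "B2,1,6"), f)
  expect_error(read_boundaries(f), "differing",
               class = "oct_validation_error")
  expect_error(write_boundaries(list(B1 = c(1, 2), B2 = c(1, 2, 3)),
                                f), "share one width",
               class = "oct_validation_error")
})

test_that("stage config JSON round-trips and rejects unknown keys", {
  f <- withr::local_tempfile(fileext = ".json")
  cfgs <- default_stage_configs()
  cfgs$B3$band_up <- 30
  write_stage_configs(cfgs, f)
  expect_equal(read_stage_configs(f)$B3$band_up, 30)
  writeLines('{"B3": {"bandwidth": 7}}', f)
  expect_error(read_stage_configs(f), "unknown config key",
               class = "oct_validation_error")
  writeLines('{"B3": {"lambda": -1}}', f)
  expect_error(read_stage_configs(f), "lambda",
               class = "oct_validation_error")
})
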