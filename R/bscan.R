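# B-scan images: plain numeric matrices, intensities in [0, 1], row 1 at the
# top (vitreous side). All public coordinates are 0-based: row 0 is the first
# pixel row, matching the on-disk CSV dialect.

validate_bscan <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_validation(sprintf("`%s` must be a numeric matrix", arg))
  }
  if (nrow(image) < 2L || ncol(image) < 2L) {
    abort_validation(sprintf(
      "`%s` must be at least 2x2 (got %dx%d)", arg, nrow(image), ncol(image)))
  }
  if (anyNA(image) || !all(is.finite(image))) {
    abort_validation(sprintf("`%s` contains non-finite values", arg))
  }
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 1) {
    abort_validation(sprintf(
      "`%s` intensities must lie in [0, 1] (found range [%g, %g])",
      arg, rng[1], rng[2]))
  }
  invisible(image)
}

#' Load an OCT B-scan image
#'
#' Reads a grayscale (or RGB, averaged to gray) PNG or TIFF raster and returns
#' it as a numeric matrix with intensities rescaled to \[0, 1\] by the maximum
#' representable value of the file's bit depth (255 for 8-bit, 65535 for
#' 16-bit).
#'
#' @param path Path to a PNG or TIFF file.
#' @return A numeric H x W matrix in \[0, 1\]; rows are depth (top of the scan
#'   first), columns are lateral position.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' img <- load_image(f)
#' range(img)
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_io(sprintf("cannot read image: file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      abort_io(sprintf("unsupported image format '.%s' (PNG/TIFF only): %s",
                       ext, path))
    ),
    error = function(e) {
      if (inherits(e, "oct_io_error")) rlang::cnd_signal(e)
      abort_io(sprintf("failed to read image %s: %s", path,
                       conditionMessage(e)))
    }
  )
  if (length(dim(arr)) == 3L) {
    # RGB(A) or gray+alpha: average the colour channels, drop alpha.
    nc <- dim(arr)[3]
    ch <- if (nc >= 3L) 1:3 else 1L
    arr <- apply(arr[, , ch, drop = FALSE], c(1, 2), mean)
  }
  if (is.null(dim(arr)) || any(dim(arr) == 0L)) {
    abort_validation(sprintf("zero-sized image: %s", path))
  }
  arr <- pmin(pmax(arr, 0), 1)
  validate_bscan(arr, "loaded image")
  arr
}

#' Write a B-scan image to disk
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param path Output path; the extension selects PNG (8-bit) or TIFF (16-bit).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  validate_bscan(image)
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      png = png::writePNG(image, path),
      tif = ,
      tiff = tiff::writeTIFF(image, path, bits.per.sample = 16L),
      abort_io(sprintf("unsupported image format '.%s' (PNG/TIFF only)", ext))
    )
    TRUE
  }, error = function(e) {
    if (inherits(e, "oct_io_error")) rlang::cnd_signal(e)
    abort_io(sprintf("failed to write image %s: %s", path,
                     conditionMessage(e)))
  })
  invisible(path)
}
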