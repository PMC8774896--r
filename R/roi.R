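# Regions of interest: binary masks anchored to previously found boundaries,
# restricting each subsequent boundary search so it cannot re-detect an
# already-segmented frontier. Rows are 0-based; boundary positions are rounded
# half-up to integer rows before the strict row comparisons, and the boundary
# row itself is excluded at offset 0.

check_shape <- function(shape) {
  if (!is.numeric(shape) || length(shape) != 2L || any(shape < 1)) {
    abort_validation("`shape` must be c(H, W) with positive entries")
  }
  as.integer(shape)
}

roi_rows <- function(boundary, shape, arg = "boundary") {
  shape <- check_shape(shape)
  validate_boundary_rows(boundary, width = shape[2], arg = arg)
  round_half_up(boundary)
}

# mask[r, c] == 1 exactly when lo[c] <= r <= hi[c] (0-based rows).
mask_row_range <- function(lo, hi, shape) {
  H <- shape[1]; W <- shape[2]
  r0 <- seq.int(0L, H - 1L)
  (outer(r0, lo, ">=") & outer(r0, hi, "<=")) * 1
}

check_columns_nonempty <- function(mask, context = NULL) {
  empty <- which(colSums(mask) == 0) - 1L
  if (length(empty) > 0L) abort_broken_roi(empty, context)
  invisible(mask)
}

#' Keep the region strictly below a boundary
#'
#' `mask[r, c] = 1` exactly for pixels whose row exceeds
#' `boundary(c) + offset` (0-based rows increasing toward the choroid).
#'
#' @param boundary Numeric vector of row positions, one per column.
#' @param offset Non-negative offset in pixels.
#' @param shape `c(H, W)` of the image.
#' @return 0/1 matrix of shape `shape`.
#' @examples
#' keep_below(rep(5, 4), 0, c(10, 4))[6:7, ]
#' @export
keep_below <- function(boundary, offset, shape) {
  check_number(offset, "offset", min = 0)
  b <- roi_rows(boundary, shape, "boundary")
  mask_row_range(b + offset + 1, rep(shape[1] - 1, length(b)), check_shape(shape))
}

#' Keep the region strictly above a boundary
#'
#' Mirror of [keep_below()]: `mask[r, c] = 1` exactly for pixels whose row
#' lies above `boundary(c) - offset`.
#'
#' @inheritParams keep_below
#' @return 0/1 matrix of shape `shape`.
#' @export
keep_above <- function(boundary, offset, shape) {
  check_number(offset, "offset", min = 0)
  b <- roi_rows(boundary, shape, "boundary")
  mask_row_range(rep(0, length(b)), b - offset - 1, check_shape(shape))
}

#' Band between two boundaries
#'
#' Elementwise product of [keep_below()] on the upper boundary and
#' [keep_above()] on the lower one. Raises a broken-ROI error (naming the
#' columns) if any column ends up empty, and a validation error (naming the
#' columns) if the boundaries cross.
#'
#' @param upper,lower Numeric row vectors with `upper <= lower` columnwise.
#' @param pad_up,pad_dn Non-negative pads excluded next to each boundary.
#' @param shape `c(H, W)`.
#' @return 0/1 matrix.
#' @export
band_between <- function(upper, lower, pad_up, pad_dn, shape) {
  shape <- check_shape(shape)
  validate_boundary_rows(upper, width = shape[2], arg = "upper")
  validate_boundary_rows(lower, width = shape[2], arg = "lower")
  crossing <- which(upper > lower) - 1L
  if (length(crossing) > 0L) {
    abort_validation(sprintf(
      "`upper` crosses `lower` at column(s) %s",
      paste(crossing, collapse = ", ")))
  }
  m <- keep_below(upper, pad_up, shape) * keep_above(lower, pad_dn, shape)
  check_columns_nonempty(m)
}

#' Fixed-width band parallel to a boundary
#'
#' A band of exactly `width` rows adjacent to the boundary on the given side
#' (the boundary row itself excluded), clipped at the image borders. A column
#' whose band is fully clipped raises a broken-ROI error.
#'
#' @param boundary Numeric row vector.
#' @param direction `"above"` or `"below"`.
#' @param width Band width in pixels (>= 1).
#' @param shape `c(H, W)`.
#' @return 0/1 matrix.
#' @examples
#' m <- band_parallel(rep(50, 4), "above", 20, c(64, 4))
#' range(which(m[, 1] == 1) - 1)  # rows 30..49
#' @export
band_parallel <- function(boundary, direction, width, shape) {
  if (!direction %in% c("above", "below")) {
    abort_validation('`direction` must be "above" or "below"')
  }
  check_number(width, "width", min = 1)
  shape <- check_shape(shape)
  b <- roi_rows(boundary, shape)
  m <- if (direction == "above") {
    mask_row_range(b - width, b - 1, shape)
  } else {
    mask_row_range(b + 1, b + width, shape)
  }
  check_columns_nonempty(m)
}

# Band at signed offsets lo..hi relative to a boundary (lo <= hi; negative =
# above). Used by the pipeline for the "5-60 px below B7" style regions.
band_offset <- function(boundary, lo, hi, shape) {
  shape <- check_shape(shape)
  b <- roi_rows(boundary, shape)
  if (hi < lo) abort_validation("`hi` must be >= `lo`")
  m <- mask_row_range(b + lo, b + hi, shape)
  check_columns_nonempty(m)
}

#' Export a region mask as an 8-bit PNG (0/255)
#'
#' Supports the human-review workflow: masks can be previewed alongside the
#' scan before a stage is re-run with adjusted band parameters.
#'
#' @param mask 0/1 matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    abort_validation("`mask` must be a 0/1 matrix")
  }
  png::writePNG(mask, path)
  invisible(path)
}
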