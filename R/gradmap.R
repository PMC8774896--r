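# Cost maps: per-pixel traversal costs derived from directional gradients.
# A frontier of the requested polarity (dark-to-bright or bright-to-dark,
# reading down the scan) gets LOW cost, so the minimum-cost left-to-right path
# rides along it.

#' First-order image gradients
#'
#' Central differences in the interior, one-sided differences at the first and
#' last row/column (the same scheme as MATLAB's and numpy's `gradient`).
#'
#' @param image Numeric matrix (at least 2x2).
#' @return List with `gx` (derivative along columns, lateral) and `gy`
#'   (derivative along rows; positive where intensity increases downward).
#' @export
image_gradients <- function(image) {
  if (!is.matrix(image) || nrow(image) < 2L || ncol(image) < 2L) {
    abort_validation("`image` must be a numeric matrix of size >= 2x2")
  }
  H <- nrow(image); W <- ncol(image)
  gy <- matrix(0, H, W)
  gy[1, ] <- image[2, ] - image[1, ]
  gy[H, ] <- image[H, ] - image[H - 1L, ]
  if (H > 2L) {
    gy[2:(H - 1L), ] <- (image[3:H, , drop = FALSE] -
                           image[1:(H - 2L), , drop = FALSE]) / 2
  }
  gx <- matrix(0, H, W)
  gx[, 1] <- image[, 2] - image[, 1]
  gx[, W] <- image[, W] - image[, W - 1L]
  if (W > 2L) {
    gx[, 2:(W - 1L)] <- (image[, 3:W, drop = FALSE] -
                           image[, 1:(W - 2L), drop = FALSE]) / 2
  }
  list(gx = gx, gy = gy)
}

#' Rescale to \[0, 1\]
#'
#' Linear min-max normalisation: `(m - min) / (max - min)`. A constant input
#' maps to all zeros (the stated degenerate-case convention).
#'
#' @param m Numeric matrix or vector with finite values.
#' @return Object of the same shape with range \[0, 1\] (or all zeros).
#' @export
normalise01 <- function(m) {
  if (!is.numeric(m) || anyNA(m) || !all(is.finite(m))) {
    abort_validation("`m` must be finite numeric")
  }
  rng <- range(m)
  if (rng[2] == rng[1]) {
    m[] <- 0
    return(m)
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Build a polarity-specific traversal cost map
#'
#' After optional TV denoising, the signed vertical gradient is flipped for
#' `bright_to_dark` searches and clamped at zero, so only intensity transitions
#' of the requested polarity score. With `gv` the normalised clamped vertical
#' gradient and `gh` the normalised horizontal gradient magnitude, the cost is
#' \deqn{W(x) = \exp(-\lambda\,(1 - gh)\,gv)}
#' renormalised to \[0, 1\]: pixels on a strong vertical transition of the
#' requested polarity with little lateral variation have the lowest cost.
#' Larger `lambda` sharpens the contrast between frontier and background.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param polarity `"dark_to_bright"` or `"bright_to_dark"` (reading down the
#'   scan, vitreous to choroid).
#' @param lambda Positive exponential weight (default 10).
#' @param smooth TV denoise strength applied before differentiation.
#' @return An `oct_costmap`: list with `values` (H x W matrix in \[0, 1\]),
#'   `polarity`, `lambda`. A constant input yields a degenerate all-zero map
#'   (flagged in the `degenerate` field).
#' @examples
#' img <- rbind(matrix(0.1, 4, 6), matrix(0.9, 4, 6))
#' cm <- build_cost_map(img, "dark_to_bright")
#' which.min(rowMeans(cm$values))
#' @export
build_cost_map <- function(image, polarity, lambda = 10, smooth = 0) {
  validate_bscan(image)
  if (!is.character(polarity) || length(polarity) != 1L ||
      !polarity %in% polarities) {
    abort_validation(sprintf("`polarity` must be one of %s",
                             paste(polarities, collapse = ", ")))
  }
  check_number(lambda, "lambda", min = 0, strict = TRUE)
  sm <- tv_denoise(image, smooth)
  g <- image_gradients(sm)
  sv <- if (polarity == "bright_to_dark") -g$gy else g$gy
  sv[sv < 0] <- 0
  gv <- normalise01(sv)
  gh <- normalise01(abs(g$gx))
  raw <- exp(-lambda * (1 - gh) * gv)
  degenerate <- diff(range(raw)) == 0
  structure(
    list(values = normalise01(raw), polarity = polarity, lambda = lambda,
         degenerate = degenerate),
    class = "oct_costmap"
  )
}

as_cost_matrix <- function(cost, arg = "cost") {
  if (inherits(cost, "oct_costmap")) return(cost$values)
  if (is.matrix(cost) && is.numeric(cost)) {
    if (anyNA(cost) || any(cost < 0) || any(cost > 1)) {
      abort_validation(sprintf("`%s` values must be finite in [0, 1]", arg))
    }
    return(cost)
  }
  abort_validation(sprintf(
    "`%s` must be an oct_costmap or a numeric matrix in [0, 1]", arg))
}

#' @export
print.oct_costmap <- function(x, ...) {
  cat(sprintf("<oct_costmap> %dx%d, polarity=%s, lambda=%g%s\n",
              nrow(x$values), ncol(x$values), x$polarity, x$lambda,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}
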