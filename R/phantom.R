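# Synthetic B-scan phantoms: layered images with known 9-boundary ground
# truth, multiplicative gamma speckle, and optional drusen / fluid pathology.
# The generator is the package's test substrate: every pipeline claim is
# validated against phantoms, since clinical datasets ship with no ground
# truth at desk scale.

#' Construct a phantom specification
#'
#' @param width,height Image size in pixels (`W >= 64`, `H >= 128` for the
#'   default bands to fit).
#' @param depths Nine strictly increasing base row offsets (0-based pixels),
#'   vitreous side first.
#' @param band_intensities Ten intensities in \[0, 1\]: vitreous, the eight
#'   bands between consecutive boundaries, and the choroid below B9.
#' @param curve_amp,curve_wavelength,curve_phase Smooth undulation applied to
#'   all boundaries in parallel (pixels / pixels / radians).
#' @param dip_amp Foveal dip amplitude (pixels), pushing the inner boundaries
#'   down toward the photoreceptors near `dip_center`.
#' @param dip_center,dip_sigma Lateral centre and Gaussian width of the dip.
#' @param dip_weights Per-boundary dip attenuation (1 at the ILM, 0 for the
#'   outer retina).
#' @param speckle_k Gamma shape of the multiplicative speckle (mean 1,
#'   variance 1/k); `Inf` disables speckle.
#' @param blur_sigma Gaussian blur of the band image (pixels); 0 disables.
#' @param drusen List of `list(center, width, height)` bumps lifting B8/B9
#'   toward the vitreous.
#' @param fluid List of `list(center, rx, ry, factor)` darkened ellipses
#'   between B4 and B6, locally pushing B4 and B5 apart.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An `oct_phantom_spec` list.
#' @export
phantom_spec <- function(width, height, depths, band_intensities,
                         curve_amp = 0, curve_wavelength = 400,
                         curve_phase = 0,
                         dip_amp = 0, dip_center = width / 2,
                         dip_sigma = width / 8,
                         dip_weights = c(1, 0.7, 0.55, 0.4, 0.25, 0.08, 0, 0, 0),
                         speckle_k = Inf, blur_sigma = 0.7,
                         drusen = list(), fluid = list(), seed = 0L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               depths = as.numeric(depths),
               band_intensities = as.numeric(band_intensities),
               curve_amp = curve_amp, curve_wavelength = curve_wavelength,
               curve_phase = curve_phase,
               dip_amp = dip_amp, dip_center = dip_center,
               dip_sigma = dip_sigma, dip_weights = as.numeric(dip_weights),
               speckle_k = speckle_k, blur_sigma = blur_sigma,
               drusen = drusen, fluid = fluid, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "oct_phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (spec$width < 2L || spec$height < 2L) {
    abort_validation("phantom width and height must be >= 2")
  }
  if (length(spec$depths) != 9L || any(diff(spec$depths) <= 0)) {
    abort_validation("`depths` must be 9 strictly increasing row offsets")
  }
  if (any(spec$depths < 0) || any(spec$depths > spec$height - 1)) {
    abort_validation("`depths` must lie within [0, H-1]")
  }
  if (length(spec$band_intensities) != 10L ||
      any(spec$band_intensities < 0) || any(spec$band_intensities > 1)) {
    abort_validation("`band_intensities` must be 10 values in [0, 1]")
  }
  check_number(spec$speckle_k, "speckle_k", min = 0, strict = TRUE,
               allow_inf = TRUE)
  check_number(spec$blur_sigma, "blur_sigma", min = 0)
  if (length(spec$dip_weights) != 9L) {
    abort_validation("`dip_weights` must have 9 entries")
  }
  for (d in spec$drusen) {
    if (!all(c("center", "width", "height") %in% names(d))) {
      abort_validation("each drusen needs center, width, height")
    }
  }
  for (f in spec$fluid) {
    if (!all(c("center", "rx", "ry", "factor") %in% names(f))) {
      abort_validation("each fluid pocket needs center, rx, ry, factor")
    }
  }
  invisible(spec)
}

#' Default healthy-retina phantom specification
#'
#' Band contrasts mimic a healthy macular scan: the vitreous is near-black,
#' the outer nuclear layer (between B5 and B6) is the darkest retinal band,
#' and the photoreceptor outer-segment band below B7 together with the RPE
#' band below B8 are the brightest — which makes the IS-OS junction (B7) the
#' highest-contrast dark-to-bright frontier of the scan, the anchor assumption
#' of the pipeline. The seed jitters the curvature phase/amplitude, the foveal
#' dip and the base depths slightly so different seeds give genuinely
#' different geometry, and drives the speckle.
#'
#' @param width,height Image size in pixels (`width >= 64`, `height >= 128`).
#' @param seed Integer seed.
#' @return An `oct_phantom_spec`.
#' @examples
#' spec <- default_healthy_spec(128, 256, seed = 1)
#' diff(spec$depths) > 0
#' @export
default_healthy_spec <- function(width = 512, height = 496, seed = 0L) {
  if (width < 64L || height < 128L) {
    abort_validation("default_healthy_spec needs width >= 64 and height >= 128")
  }
  frac <- c(0.300, 0.340, 0.373, 0.403, 0.433, 0.494, 0.524, 0.544, 0.575)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  # jitter is kept well below the smallest inter-boundary gap (which scales
  # with height), so the depths stay strictly increasing
  jitter <- runif(9, -1, 1) * min(1, height / 496)
  depths <- frac * height + jitter
  phantom_spec(
    width = width, height = height, depths = depths,
    band_intensities = c(0.03, 0.52, 0.38, 0.26, 0.38, 0.10, 0.18,
                         0.95, 0.80, 0.32),
    curve_amp = 8 * (height / 496) * runif(1, 0.7, 1.3),
    curve_wavelength = 0.9 * width,
    curve_phase = runif(1, 0, 2 * pi),
    dip_amp = 30 * (height / 496) * runif(1, 0.8, 1.2),
    dip_center = width / 2, dip_sigma = width / 8,
    speckle_k = 50, blur_sigma = 0.7, seed = seed
  )
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Raised-cosine bump equal to `height` at `center`, 0 beyond width/2.
cosine_bump <- function(x, center, width, height) {
  u <- (x - center) / (width / 2)
  b <- ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
  height * b
}

phantom_truth_curves <- function(spec) {
  W <- spec$width
  x <- seq.int(0L, W - 1L)
  undulation <- spec$curve_amp *
    sin(2 * pi * x / spec$curve_wavelength + spec$curve_phase)
  dip <- spec$dip_amp * exp(-((x - spec$dip_center)^2) /
                              (2 * spec$dip_sigma^2))
  truth <- lapply(seq_len(9L), function(i) {
    spec$depths[i] + undulation + spec$dip_weights[i] * dip
  })
  names(truth) <- oct_layers
  for (d in spec$drusen) {
    bump <- cosine_bump(x, d$center, d$width, d$height)
    truth$B8 <- truth$B8 - bump
    truth$B9 <- truth$B9 - bump
  }
  for (f in spec$fluid) {
    bump <- sqrt(pmax(0, 1 - ((x - f$center) / f$rx)^2))
    truth$B4 <- truth$B4 - 0.4 * f$ry * bump
    truth$B5 <- truth$B5 + 0.4 * f$ry * bump
  }
  truth
}

# separable Gaussian blur, reflect padding
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  blur1d <- function(m) {
    n <- nrow(m)
    padded <- m[reflect_index(seq.int(1L - r, n + r), n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[(i):(i + n - 1L), , drop = FALSE]
    }
    out
  }
  t(blur1d(t(blur1d(m))))
}

#' Generate a synthetic B-scan with ground truth
#'
#' Builds the nine boundary curves (base depths + smooth undulation + foveal
#' dip, then drusen elevation of B8/B9 and fluid displacement of B4/B5),
#' renders piecewise-constant bands with sub-pixel coverage at each frontier,
#' darkens fluid ellipses, blurs with a small Gaussian kernel, multiplies by
#' gamma-distributed speckle (mean 1, shape `speckle_k`), and clips to
#' \[0, 1\]. Deterministic for a fixed seed; no global RNG state leaks.
#'
#' @param spec An `oct_phantom_spec`, e.g. from [default_healthy_spec()].
#' @return An `oct_phantom`: list with `image` (H x W matrix), `truth` (named
#'   list of 0-based row vectors, non-decreasing from B1 to B9 per column),
#'   and `spec`.
#' @examples
#' ph <- generate_phantom(default_healthy_spec(64, 128, seed = 0))
#' dim(ph$image)
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  H <- spec$height; W <- spec$width
  truth <- phantom_truth_curves(spec)
  tm <- do.call(rbind, truth)  # 9 x W
  bad <- which(apply(tm, 2, function(col) any(diff(col) < 0.5)) |
                 tm[1, ] < 0 | tm[9, ] > H - 1) - 1L
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "phantom bands cross or leave the image at column(s) %s",
      paste(bad, collapse = ", ")))
  }

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(spec$seed)

  v <- spec$band_intensities
  r0half <- seq.int(0L, H - 1L) + 0.5
  img <- matrix(v[1], H, W)
  for (i in seq_len(9L)) {
    # fraction of each pixel lying below boundary i (sub-pixel coverage)
    fracs <- pmin(pmax(outer(r0half, tm[i, ], "-"), 0), 1)
    img <- img + (v[i + 1] - v[i]) * fracs
  }

  if (length(spec$fluid) > 0L) {
    x <- matrix(seq.int(0L, W - 1L), H, W, byrow = TRUE)
    y <- matrix(seq.int(0L, H - 1L), H, W)
    for (f in spec$fluid) {
      cy <- (truth$B4 + truth$B6) / 2
      cym <- matrix(cy, H, W, byrow = TRUE)
      inside <- ((x - f$center) / f$rx)^2 + ((y - cym) / f$ry)^2 <= 1
      img[inside] <- img[inside] * f$factor
    }
  }

  img <- gaussian_blur(img, spec$blur_sigma)
  if (is.finite(spec$speckle_k)) {
    k <- spec$speckle_k
    img <- img * matrix(stats::rgamma(H * W, shape = k, rate = k), H, W)
  }
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = img, truth = truth, spec = spec),
            class = "oct_phantom")
}

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("<oct_phantom> %dx%d, speckle_k=%s, %d drusen, %d fluid, seed=%d\n",
              x$spec$height, x$spec$width, format(x$spec$speckle_k),
              length(x$spec$drusen), length(x$spec$fluid), x$spec$seed))
  invisible(x)
}

#' Write a phantom's image, ground truth and spec to a directory
#'
#' Writes `phantom.png` (8-bit grayscale), `truth.csv` (the boundary CSV
#' dialect) and `spec.json`.
#'
#' @param phantom An `oct_phantom`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!inherits(phantom, "oct_phantom")) {
    abort_validation("`phantom` must be an oct_phantom")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_image(phantom$image, file.path(dir, "phantom.png"))
  write_boundaries(phantom$truth, file.path(dir, "truth.csv"))
  spec <- phantom$spec
  class(spec) <- NULL
  jsonlite::write_json(spec, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
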