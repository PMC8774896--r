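# Visual review of segmentations: ggplot2 overlays for interactive sessions
# and flat PNG overlays for the CLI's human-review workflow.

layer_palette <- function() {
  stats::setNames(grDevices::hcl.colors(9, "Zissou 1"), oct_layers)
}

image_raster_tbl <- function(image) {
  tibble::tibble(
    column = rep(seq.int(0L, ncol(image) - 1L), each = nrow(image)),
    row = rep(seq.int(0L, nrow(image) - 1L), times = ncol(image)),
    intensity = as.vector(image)
  )
}

boundary_overlay_plot <- function(image, tb, title) {
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = image_raster_tbl(image),
                         ggplot2::aes(x = .data$column, y = .data$row,
                                      fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::geom_line(data = tb,
                       ggplot2::aes(x = .data$column, y = .data$row,
                                    colour = .data$layer),
                       linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = layer_palette()) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "column (px)", y = "row (px, depth)",
                  colour = "frontier") +
    ggplot2::theme_minimal()
}

#' Plot a segmentation over its B-scan
#'
#' @param object An `oct_segmentation`.
#' @param ... Unused.
#' @return A ggplot object: the scan as a grayscale raster with the nine
#'   boundaries coloured per layer.
#' @export
autoplot.oct_segmentation <- function(object, ...) {
  boundary_overlay_plot(object$image, tidy(object), "Retinal layer segmentation")
}

#' @rdname autoplot.oct_segmentation
#' @param object An `oct_phantom`.
#' @export
autoplot.oct_phantom <- function(object, ...) {
  boundary_overlay_plot(object$image, tidy(object),
                        "Synthetic B-scan phantom (ground truth)")
}

#' Per-layer error bars for a metrics report
#'
#' @param object An `oct_metrics` report from [evaluate()].
#' @param ... Unused.
#' @return A ggplot object with SE and AE means and +-1 standard deviation per
#'   layer.
#' @export
autoplot.oct_metrics <- function(object, ...) {
  d <- tidy(object)
  long <- dplyr::bind_rows(
    tibble::tibble(layer = d$layer, metric = "signed error",
                   mean = d$se_mean, std = d$se_std),
    tibble::tibble(layer = d$layer, metric = "absolute error",
                   mean = d$ae_mean, std = d$ae_std))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$layer, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$std,
                                        ymax = .data$mean + .data$std),
                           width = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "pixels") +
    ggplot2::theme_minimal()
}

#' Write a flat PNG overlay of boundaries on a scan
#'
#' Draws each boundary (rounded to pixel rows) in a distinct colour on top of
#' the grayscale image — the non-interactive counterpart of
#' [autoplot.oct_segmentation()], written next to the CLI's other outputs for
#' human review.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param boundaries Named list / tibble / `oct_segmentation`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, boundaries, path) {
  validate_bscan(image)
  bmap <- as_boundary_list(boundaries)
  H <- nrow(image); W <- ncol(image)
  rgbarr <- array(rep(image, 3L), dim = c(H, W, 3L))
  cols <- grDevices::col2rgb(layer_palette()) / 255
  for (l in names(bmap)) {
    r <- pmin(pmax(round_half_up(bmap[[l]]), 0), H - 1L) + 1L
    idx <- cbind(r, seq_len(W))
    for (ch in 1:3) {
      plane <- rgbarr[, , ch]
      plane[idx] <- cols[ch, l]
      rgbarr[, , ch] <- plane
    }
  }
  png::writePNG(rgbarr, path)
  invisible(path)
}
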