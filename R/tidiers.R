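# broom-style tidiers and ggplot2 autoplot methods for the package's result
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a segmentation result
#'
#' @param x An `oct_segmentation`.
#' @param ... Unused.
#' @return A tibble with columns `layer`, `column` (0-based), `row`.
#' @export
tidy.oct_segmentation <- function(x, ...) boundary_tbl(x$boundaries)

#' @rdname tidy.oct_segmentation
#' @export
tidy.oct_phantom <- function(x, ...) boundary_tbl(x$truth)

#' Tidy a metrics report
#'
#' @param x An `oct_metrics` report.
#' @param ... Unused.
#' @return The per-layer rows (without the `Total` aggregate) as a plain
#'   tibble.
#' @export
tidy.oct_metrics <- function(x, ...) {
  out <- tibble::as_tibble(x)[x$layer != "Total", ]
  class(out) <- setdiff(class(out), "oct_metrics")
  out
}

#' One-row summary of a segmentation result
#'
#' @param x An `oct_segmentation`.
#' @param ... Unused.
#' @return A tibble with image size, IS-OS check verdict/score, and the count
#'   of ordering-adjusted columns.
#' @export
glance.oct_segmentation <- function(x, ...) {
  tibble::tibble(
    height = nrow(x$image), width = ncol(x$image),
    n_layers = length(x$boundaries),
    isos_passed = x$isos_check$passed,
    isos_score = x$isos_check$score,
    isos_tv = x$isos_check$tv,
    n_adjusted_columns = sum(lengths(lapply(x$adjustments, `[[`, "columns"))),
    n_overridden = length(x$overrides)
  )
}

#' @rdname glance.oct_segmentation
#' @export
glance.oct_phantom <- function(x, ...) {
  tibble::tibble(height = x$spec$height, width = x$spec$width,
                 speckle_k = x$spec$speckle_k,
                 n_drusen = length(x$spec$drusen),
                 n_fluid = length(x$spec$fluid), seed = x$spec$seed)
}

#' Aggregate row of a metrics report
#'
#' @param x An `oct_metrics` report.
#' @param ... Unused.
#' @return The aggregate `Total` row as a one-row tibble.
#' @export
glance.oct_metrics <- function(x, ...) {
  out <- tibble::as_tibble(x)[x$layer == "Total",
                              c("se_mean", "se_std", "ae_mean", "ae_std", "n")]
  class(out) <- setdiff(class(out), "oct_metrics")
  out
}
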