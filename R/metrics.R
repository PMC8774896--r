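# Evaluation: signed error and mean absolute error between automatic and
# reference boundaries, in pixels, with per-layer and aggregate summaries.
# Sign convention: positive SE means the automatic boundary sits at larger
# row indices (deeper, toward the choroid) than the reference.

check_pair <- function(auto, ref) {
  if (!is.numeric(auto) || !is.numeric(ref)) {
    abort_validation("boundaries must be numeric vectors")
  }
  if (length(auto) != length(ref)) {
    abort_validation(sprintf(
      "boundary length mismatch: %d vs %d", length(auto), length(ref)))
  }
  invisible(NULL)
}

#' Signed error between two boundaries
#'
#' \eqn{SE = \frac{1}{n}\sum_j (auto_j - ref_j)}: positive when the automatic
#' boundary lies below (deeper than) the reference, negative when above.
#'
#' @param auto,ref Numeric row vectors of equal length.
#' @return A single number (pixels).
#' @examples
#' signed_error(c(2, 4, 6), c(1, 2, 3))  # 2
#' @export
signed_error <- function(auto, ref) {
  check_pair(auto, ref)
  mean(auto - ref)
}

#' Mean absolute error between two boundaries
#'
#' \eqn{MAE = \frac{1}{n}\sum_j |auto_j - ref_j|}.
#'
#' @inheritParams signed_error
#' @return A single number (pixels).
#' @export
mean_absolute_error <- function(auto, ref) {
  check_pair(auto, ref)
  mean(abs(auto - ref))
}

pop_sd <- function(x) {
  if (length(x) <= 1L) return(0)
  sqrt(mean((x - mean(x))^2))
}

#' Evaluate segmentations against reference boundaries
#'
#' For each image, the per-layer signed error (SE) and absolute error (AE)
#' are computed; across images each layer is summarized by its mean and
#' population standard deviation. The aggregate `Total` row is the unweighted
#' mean of the per-layer statistics.
#'
#' @param results A segmentation (or boundary set) or a list of them: each may
#'   be an `oct_segmentation`, a named list of row vectors, or a tidy
#'   layer/column/row data frame.
#' @param truths A reference boundary set, or a list paired with `results`.
#'   Every layer present in a result must be present in its reference.
#' @return An `oct_metrics` tibble with columns `layer`, `se_mean`, `se_std`,
#'   `ae_mean`, `ae_std`, `n` (compared columns), including the `Total` row;
#'   attribute `n_images` holds the number of image pairs.
#' @examples
#' a <- list(B1 = c(5, 5), B7 = c(9, 9))
#' b <- list(B1 = c(4, 6), B7 = c(9, 9))
#' evaluate(a, b)
#' @export
evaluate <- function(results, truths) {
  is_single <- function(x) inherits(x, c("oct_segmentation", "oct_phantom")) ||
    is.data.frame(x) || (is.list(x) && !is.null(names(x)) &&
                           all(names(x) %in% oct_layers))
  if (is_single(results)) results <- list(results)
  if (is_single(truths)) truths <- list(truths)
  if (length(results) != length(truths) || length(results) == 0L) {
    abort_validation("`results` and `truths` must be non-empty paired lists")
  }
  results <- lapply(results, as_boundary_list, arg = "results")
  truths <- lapply(truths, as_boundary_list, arg = "truths")

  layers <- sort(unique(unlist(lapply(results, names))))
  per_image <- lapply(seq_along(results), function(i) {
    auto <- results[[i]]; ref <- truths[[i]]
    missing <- setdiff(names(auto), names(ref))
    if (length(missing) > 0L) {
      abort_validation(sprintf(
        "image %d: reference lacks layer(s) %s", i,
        paste(missing, collapse = ", ")))
    }
    rows <- lapply(names(auto), function(l) {
      tibble::tibble(image = i, layer = l,
                     se = signed_error(auto[[l]], ref[[l]]),
                     ae = mean_absolute_error(auto[[l]], ref[[l]]),
                     n = length(auto[[l]]))
    })
    dplyr::bind_rows(rows)
  })
  d <- dplyr::bind_rows(per_image)

  per_layer <- d |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(se_mean = mean(.data$se), se_std = pop_sd(.data$se),
                     ae_mean = mean(.data$ae), ae_std = pop_sd(.data$ae),
                     n = sum(.data$n), .groups = "drop")
  total <- tibble::tibble(layer = "Total",
                          se_mean = mean(per_layer$se_mean),
                          se_std = mean(per_layer$se_std),
                          ae_mean = mean(per_layer$ae_mean),
                          ae_std = mean(per_layer$ae_std),
                          n = sum(per_layer$n))
  out <- dplyr::bind_rows(per_layer, total)
  attr(out, "n_images") <- length(results)
  class(out) <- c("oct_metrics", class(out))
  out
}

#' Write a metrics report as CSV
#'
#' Columns `layer,se_mean,se_std,ae_mean,ae_std,n`; a header comment records
#' the sign convention (positive SE = automatic boundary deeper than the
#' reference).
#'
#' @param report An `oct_metrics` tibble from [evaluate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  if (!inherits(report, "oct_metrics")) {
    abort_validation("`report` must come from evaluate()")
  }
  lines <- c(
    "# signed error in pixels; positive = automatic boundary deeper (larger row) than reference",
    "layer,se_mean,se_std,ae_mean,ae_std,n",
    sprintf("%s,%.4f,%.4f,%.4f,%.4f,%d", report$layer,
            report$se_mean, report$se_std, report$ae_mean, report$ae_std,
            report$n))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
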