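# Boundaries: one row position per image column for a named layer frontier.
# Internally a boundary is a numeric vector of 0-based row positions (length
# W); a boundary set is a named list keyed by layer label. The tidy user-facing
# form is a tibble with columns layer, column (0-based), row.

validate_boundary_rows <- function(rows, width = NULL, height = NULL,
                                   arg = "boundary") {
  if (!is.numeric(rows) || length(rows) < 1L || anyNA(rows) ||
      !all(is.finite(rows))) {
    abort_validation(sprintf("`%s` must be a finite numeric vector", arg))
  }
  if (!is.null(width) && length(rows) != width) {
    abort_validation(sprintf(
      "`%s` has length %d but the image has %d columns",
      arg, length(rows), width))
  }
  if (any(rows < 0) || (!is.null(height) && any(rows > height - 1))) {
    abort_validation(sprintf("`%s` has row values outside [0, H-1]", arg))
  }
  invisible(rows)
}

check_layer_labels <- function(labels) {
  bad <- setdiff(labels, oct_layers)
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "unknown layer label(s): %s (expected %s)",
      paste(unique(bad), collapse = ", "), paste(range(oct_layers), collapse = "..")))
  }
  invisible(labels)
}

# Coerce a boundary set given as a named list, a tidy tibble/data.frame, or an
# oct_segmentation object into the internal named-list form.
as_boundary_list <- function(x, arg = "boundaries") {
  if (inherits(x, "oct_segmentation")) return(x$boundaries)
  if (inherits(x, "oct_phantom")) return(x$truth)
  if (is.data.frame(x)) {
    need <- c("layer", "column", "row")
    if (!all(need %in% names(x))) {
      abort_validation(sprintf(
        "`%s` data frame must have columns layer, column, row", arg))
    }
    check_layer_labels(unique(x$layer))
    out <- lapply(split(x, x$layer), function(d) {
      d <- d[order(d$column), , drop = FALSE]
      cols <- d$column
      if (anyDuplicated(cols) || !identical(as.integer(cols),
                                            seq.int(0L, length(cols) - 1L))) {
        abort_validation(sprintf(
          "layer %s has missing, duplicated or non-contiguous columns",
          d$layer[1]))
      }
      as.numeric(d$row)
    })
    return(out[order(names(out))])
  }
  if (is.list(x)) {
    if (length(x) > 0L) {
      check_layer_labels(names(x))
      lapply(x, validate_boundary_rows)
    }
    return(x)
  }
  abort_validation(sprintf(
    "`%s` must be a named list, a layer/column/row data frame, or a segmentation result", arg))
}

boundary_tbl <- function(bmap) {
  if (length(bmap) == 0L) {
    return(tibble::tibble(layer = character(0), column = integer(0),
                          row = numeric(0)))
  }
  dplyr::bind_rows(lapply(names(bmap)[order(names(bmap))], function(l) {
    tibble::tibble(layer = l,
                   column = seq.int(0L, length(bmap[[l]]) - 1L),
                   row = as.numeric(bmap[[l]]))
  }))
}

#' Write layer boundaries to CSV
#'
#' Serializes a boundary set as CSV with header `layer,column,row`, rows sorted
#' by (layer, column), 0-based column indices, row positions with 3 decimal
#' places, UTF-8 and LF line endings. The file round-trips losslessly through
#' [read_boundaries()] for row values already at 3-decimal precision.
#'
#' @param boundaries A named list of per-layer row vectors (`B1`..`B9`), a tidy
#'   tibble with columns `layer`, `column`, `row`, or an `oct_segmentation`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_boundaries(list(B7 = c(10, 10)), f)
#' readLines(f)
#' @export
write_boundaries <- function(boundaries, path) {
  bmap <- as_boundary_list(boundaries)
  if (length(bmap) > 0L) {
    widths <- lengths(bmap)
    if (length(unique(widths)) != 1L) {
      abort_validation(sprintf(
        "all boundaries must share one width (got %s)",
        paste(unique(widths), collapse = ", ")))
    }
  }
  tb <- boundary_tbl(bmap)
  lines <- c("layer,column,row",
             sprintf("%s,%d,%.3f", tb$layer, tb$column, tb$row))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort_io(sprintf(
                    "cannot write boundaries to %s: %s", path,
                    conditionMessage(e))))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read layer boundaries from CSV
#'
#' Reads the CSV dialect produced by [write_boundaries()] and returns a tidy
#' tibble. Each layer must carry a contiguous 0-based column range; unknown
#' layer labels are rejected.
#'
#' @param path CSV path.
#' @return A tibble with columns `layer`, `column`, `row`.
#' @export
read_boundaries <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("boundary file not found: %s", path))
  }
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) abort_io(sprintf(
                  "failed to read boundary CSV %s: %s", path,
                  conditionMessage(e))))
  if (!all(c("layer", "column", "row") %in% names(d))) {
    abort_validation(sprintf(
      "%s: boundary CSV must have header layer,column,row", path))
  }
  bmap <- as_boundary_list(d)
  if (length(bmap) > 1L && length(unique(lengths(bmap))) != 1L) {
    abort_validation(sprintf(
      "%s: layers have differing column counts", path))
  }
  boundary_tbl(bmap)
}
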