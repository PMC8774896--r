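# The nine-boundary segmentation pipeline. The IS-OS junction (B7) is found
# first on the enhanced scan; each remaining frontier is then searched inside
# a region of interest anchored to earlier boundaries, with a polarity- and
# lambda-specific cost map. A final columnwise monotone projection enforces
# the anatomical ordering B1 <= ... <= B9, logging every adjusted column.

#' Segment the IS-OS junction (B7)
#'
#' Enhances the scan with [enhance_isos()], builds a dark-to-bright cost map
#' on the enhanced image, and extracts the minimum-cost path over the full
#' image width.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param cfg Stage configuration (the `B7` entry of
#'   [default_stage_configs()] by default).
#' @return Numeric vector of 0-based row positions (length W).
#' @export
segment_isos <- function(image, cfg = default_stage_configs()$B7) {
  segment_isos_full(image, cfg)$boundary
}

segment_isos_full <- function(image, cfg) {
  validate_bscan(image)
  validate_stage_config(cfg, "B7")
  enh <- enhance_isos(image, cfg)
  cm <- build_cost_map(enh$enhanced, cfg$polarity %||% "dark_to_bright",
                       lambda = cfg$lambda %||% 10,
                       smooth = cfg$smooth %||% 0)
  b7 <- get_seg_boundary(cm)
  list(boundary = b7, costmap = cm, enhanced = enh$enhanced, mask = enh$mask)
}

#' Validity check of an IS-OS segmentation
#'
#' Scores the candidate boundary by its mean prominence `g = 1 - cost` along
#' the path and by its smoothness (total variation of the row positions). The
#' check records a verdict for human review; it never blocks — the caller (or
#' the ophthalmologist) decides what to do with a failing B7.
#'
#' @param image The scan the boundary belongs to.
#' @param b7 Numeric vector of 0-based rows (length W).
#' @param cost The `oct_costmap` the boundary was extracted from.
#' @param min_score Prominence threshold (default 0.6).
#' @param max_tv_frac Maximum total variation, as a fraction of W (default
#'   0.5).
#' @return List with `passed` (logical), `score` (mean prominence; 0 for a
#'   degenerate cost map), and `tv` (total variation in pixels).
#' @export
check_isos <- function(image, b7, cost, min_score = 0.6, max_tv_frac = 0.5) {
  validate_bscan(image)
  W <- ncol(image)
  validate_boundary_rows(b7, width = W, height = nrow(image), arg = "b7")
  values <- as_cost_matrix(cost)
  degenerate <- isTRUE(cost$degenerate) || diff(range(values)) == 0
  if (degenerate) {
    score <- 0
  } else {
    r <- pmin(pmax(round_half_up(b7), 0), nrow(image) - 1L)
    score <- mean(1 - values[cbind(r + 1L, seq_len(W))])
  }
  tv <- sum(abs(diff(b7)))
  list(passed = score >= min_score && tv <= max_tv_frac * W,
       score = score, tv = tv)
}

# Region of interest for each stage, built from the boundaries found so far.
roi_for_stage <- function(layer, cfg, bmap, shape) {
  need <- stage_deps[[layer]]
  missing <- setdiff(need, names(bmap))
  if (length(missing) > 0L) {
    abort_validation(sprintf("stage %s needs boundary %s first",
                             layer, paste(missing, collapse = ", ")))
  }
  switch(layer,
    B7 = NULL,  # full-image search
    B9 = band_offset(bmap$B7, cfg$band_lo %||% 5, cfg$band_hi %||% 60, shape),
    B8 = band_between(bmap$B7, bmap$B9, cfg$pad_up %||% 1, cfg$pad_dn %||% 1,
                      shape),
    B6 = band_offset(bmap$B7, -(cfg$band_up %||% 25),
                     -(cfg$margin %||% 3) - 1, shape),
    B1 = {
      m <- keep_above(bmap$B6, cfg$margin %||% 2, shape)
      check_columns_nonempty(m)
    },
    B4 = band_between(bmap$B1, bmap$B6, cfg$pad_up %||% 1, cfg$pad_dn %||% 1,
                      shape),
    B5 = band_between(bmap$B4, bmap$B6, cfg$pad_up %||% 1, cfg$pad_dn %||% 1,
                      shape),
    B3 = band_offset(bmap$B4, -(cfg$band_up %||% 20), -1, shape),
    B2 = band_between(bmap$B1, bmap$B3, cfg$pad_up %||% 1, cfg$pad_dn %||% 1,
                      shape),
    abort_validation(sprintf("unknown stage %s", layer))
  )
}

# Which parameter of a stage to enlarge when its ROI breaks.
roi_hint <- function(layer) {
  switch(layer,
    B9 = "widen B9.band_lo..band_hi",
    B6 = "increase B6.band_up or decrease B6.margin",
    B3 = "increase B3.band_up",
    B1 = "decrease B1.margin",
    sprintf("decrease %s.pad_up/pad_dn", layer))
}

run_stage <- function(layer, image, cfg, bmap, cache) {
  shape <- dim(image)
  mask <- tryCatch(
    roi_for_stage(layer, cfg, bmap, shape),
    oct_broken_roi = function(e) {
      abort_validation(sprintf("stage %s: %s; try to %s", layer,
                               conditionMessage(e), roi_hint(layer)),
                       class = "oct_broken_roi")
    })
  key <- paste(cfg$polarity, cfg$lambda, cfg$smooth, sep = "|")
  if (is.null(cache[[key]])) {
    cache[[key]] <- build_cost_map(image, cfg$polarity,
                                   lambda = cfg$lambda %||% 10,
                                   smooth = cfg$smooth %||% 0)
  }
  get_seg_boundary(cache[[key]], mask)
}

# Columnwise monotone projection: clip each boundary to lie at or below the
# one above it, top-down. Returns the projected matrix and the adjustment log.
enforce_ordering <- function(bmat, H) {
  adjustments <- list()
  bmat <- pmin(pmax(bmat, 0), H - 1)
  for (i in 2:nrow(bmat)) {
    viol <- which(bmat[i, ] < bmat[i - 1L, ])
    if (length(viol) > 0L) {
      adjustments[[length(adjustments) + 1L]] <- list(
        pair = c(rownames(bmat)[i - 1L], rownames(bmat)[i]),
        columns = viol - 1L)
      bmat[i, viol] <- bmat[i - 1L, viol]
    }
  }
  list(bmat = bmat, adjustments = adjustments)
}

#' Segment all nine retinal layer boundaries
#'
#' Runs the stages in the fixed order B7, B9, B8, B6, B1, B4, B5, B3, B2.
#' Every stage builds its region of interest from earlier boundaries, its
#' polarity-specific cost map, and extracts the minimum-cost path. A manual
#' override for a layer replaces the computed boundary *before* any
#' downstream stage runs, so corrections propagate. After all stages, the
#' anatomical ordering B1 <= ... <= B9 is enforced columnwise by monotone
#' projection, with every adjustment logged. The whole pipeline is
#' deterministic: identical image, configs and overrides give identical
#' results.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param configs Named list of per-stage configurations; missing entries fall
#'   back to [default_stage_configs()].
#' @param overrides Optional boundary set (named list or tidy tibble) whose
#'   layers replace the corresponding computed boundaries.
#' @return An `oct_segmentation`: boundaries (named list of 0-based row
#'   vectors), the configs used, the IS-OS validity check, the ordering
#'   adjustments, a per-stage provenance log, and the input image.
#' @examples
#' \donttest{
#' ph <- generate_phantom(default_healthy_spec(128, 256, seed = 0))
#' seg <- segment_all(ph$image)
#' tidy(seg)
#' }
#' @export
segment_all <- function(image, configs = NULL, overrides = NULL) {
  validate_bscan(image)
  configs <- normalize_stage_configs(configs)
  ov <- if (is.null(overrides)) list() else as_boundary_list(overrides,
                                                             "overrides")
  for (l in names(ov)) {
    validate_boundary_rows(ov[[l]], width = ncol(image), height = nrow(image),
                           arg = paste0("overrides$", l))
  }

  cache <- new.env(parent = emptyenv())
  bmap <- list()
  provenance <- list()
  isos <- NULL
  for (layer in stage_order) {
    cfg <- configs[[layer]]
    overridden <- layer %in% names(ov)
    if (layer == "B7") {
      full <- segment_isos_full(image, cfg)
      computed <- full$boundary
      b <- if (overridden) ov[[layer]] else computed
      isos <- check_isos(image, b, full$costmap)
    } else {
      b <- if (overridden) ov[[layer]] else run_stage(layer, image, cfg,
                                                      bmap, cache)
    }
    bmap[[layer]] <- as.numeric(b)
    provenance[[length(provenance) + 1L]] <- c(
      list(stage = layer, overridden = overridden), cfg)
  }

  bmat <- do.call(rbind, bmap[oct_layers])
  proj <- enforce_ordering(bmat, nrow(image))
  boundaries <- stats::setNames(
    lapply(seq_len(9L), function(i) unname(proj$bmat[i, ])), oct_layers)

  structure(
    list(boundaries = boundaries,
         raw_boundaries = bmap,
         configs = configs,
         overrides = ov,
         isos_check = isos,
         adjustments = proj$adjustments,
         provenance = provenance,
         image = image),
    class = "oct_segmentation"
  )
}

# Transitive closure of the stage dependency graph, in stage order.
downstream_stages <- function(layer) {
  affected <- layer
  for (l in stage_order) {
    if (l %in% affected) next
    if (any(stage_deps[[l]] %in% affected)) affected <- c(affected, l)
  }
  intersect(stage_order, affected)
}

#' Re-run one stage (and everything downstream) with new parameters
#'
#' Recomputes the named stage and all stages whose regions of interest depend
#' on it, directly or transitively, in the pipeline order; boundaries upstream
#' of the named stage are left untouched. This is the command-line
#' counterpart of interactive parameter fine-tuning: inspect, adjust a band
#' width, re-run.
#'
#' @param result An `oct_segmentation` from [segment_all()].
#' @param image The image the result was computed on.
#' @param layer Stage to re-run (`"B1"`..`"B9"`).
#' @param new_cfg Named list of configuration keys to change for that stage.
#' @return A new `oct_segmentation`.
#' @export
rerun_stage <- function(result, image, layer, new_cfg = list()) {
  if (!inherits(result, "oct_segmentation")) {
    abort_validation("`result` must be an oct_segmentation")
  }
  validate_bscan(image)
  check_layer_labels(layer)
  configs <- result$configs
  configs[[layer]] <- utils::modifyList(configs[[layer]], new_cfg)
  validate_stage_config(configs[[layer]], layer)

  affected <- downstream_stages(layer)
  upstream <- setdiff(stage_order, affected)
  missing <- setdiff(unlist(stage_deps[affected]), c(affected,
                                                     names(result$raw_boundaries)))
  if (length(missing) > 0L) {
    abort_validation(sprintf("result lacks upstream boundary %s",
                             paste(missing, collapse = ", ")))
  }

  cache <- new.env(parent = emptyenv())
  bmap <- result$raw_boundaries[upstream]
  ov <- result$overrides
  isos <- result$isos_check
  provenance <- result$provenance
  for (st in stage_order) {
    if (!st %in% affected) next
    cfg <- configs[[st]]
    overridden <- st %in% names(ov)
    if (st == "B7") {
      full <- segment_isos_full(image, cfg)
      b <- if (overridden) ov[[st]] else full$boundary
      isos <- check_isos(image, b, full$costmap)
    } else {
      b <- if (overridden) ov[[st]] else run_stage(st, image, cfg, bmap, cache)
    }
    bmap[[st]] <- as.numeric(b)
    provenance[[length(provenance) + 1L]] <- c(
      list(stage = st, overridden = overridden, rerun = TRUE), cfg)
  }

  bmat <- do.call(rbind, bmap[oct_layers])
  proj <- enforce_ordering(bmat, nrow(image))
  structure(
    list(boundaries = stats::setNames(
           lapply(seq_len(9L), function(i) unname(proj$bmat[i, ])), oct_layers),
         raw_boundaries = bmap,
         configs = configs,
         overrides = ov,
         isos_check = isos,
         adjustments = proj$adjustments,
         provenance = provenance,
         image = image),
    class = "oct_segmentation"
  )
}

#' @export
print.oct_segmentation <- function(x, ...) {
  W <- length(x$boundaries[[1]])
  cat(sprintf("<oct_segmentation> %d boundaries over %d columns\n",
              length(x$boundaries), W))
  cat(sprintf("  IS-OS check: %s (prominence %.3f, TV %.1f px)\n",
              if (x$isos_check$passed) "passed" else "FAILED",
              x$isos_check$score, x$isos_check$tv))
  n_adj <- sum(lengths(lapply(x$adjustments, `[[`, "columns")))
  cat(sprintf("  ordering adjustments: %d column(s) across %d pair(s)\n",
              n_adj, length(x$adjustments)))
  invisible(x)
}
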