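# Per-stage configuration: each of the nine boundary searches carries its own
# transition polarity, exponential weight lambda, denoise strength, and the
# band parameters that anchor its region of interest to earlier boundaries.

config_keys <- c("polarity", "lambda", "smooth", "ws", "enh",
                 "band_lo", "band_hi", "band_up", "margin",
                 "pad_up", "pad_dn")

polarities <- c("dark_to_bright", "bright_to_dark")

validate_stage_config <- function(cfg, layer) {
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown) > 0L) {
    abort_validation(sprintf("unknown config key(s) for %s: %s",
                             layer, paste(unknown, collapse = ", ")))
  }
  if (!is.null(cfg$polarity) && !cfg$polarity %in% polarities) {
    abort_validation(sprintf(
      "%s: polarity must be one of %s", layer,
      paste(polarities, collapse = ", ")))
  }
  if (!is.null(cfg$lambda)) check_number(cfg$lambda, paste0(layer, ".lambda"),
                                         min = 0, strict = TRUE)
  if (!is.null(cfg$smooth)) check_number(cfg$smooth, paste0(layer, ".smooth"),
                                         min = 0)
  if (!is.null(cfg$ws)) check_number(cfg$ws, paste0(layer, ".ws"), min = 1)
  if (!is.null(cfg$enh)) check_number(cfg$enh, paste0(layer, ".enh"))
  for (k in c("band_lo", "band_hi", "band_up")) {
    if (!is.null(cfg[[k]])) check_number(cfg[[k]], paste0(layer, ".", k),
                                         min = 1)
  }
  for (k in c("margin", "pad_up", "pad_dn")) {
    if (!is.null(cfg[[k]])) check_number(cfg[[k]], paste0(layer, ".", k),
                                         min = 0)
  }
  if (!is.null(cfg$band_lo) && !is.null(cfg$band_hi) &&
      cfg$band_hi <= cfg$band_lo) {
    abort_validation(sprintf("%s: band_hi must exceed band_lo", layer))
  }
  invisible(cfg)
}

#' Default per-stage segmentation parameters
#'
#' One configuration per layer, keyed `B1`..`B9`. Each holds the transition
#' polarity of the frontier (which sign of the vertical intensity gradient the
#' cost map rewards), the exponential weight `lambda`, the total-variation
#' denoise strength `smooth`, and the region-of-interest geometry in pixels:
#'
#' * `B7` (IS-OS): full-image search on the enhanced scan; `ws` is the mean
#'   filter window and `enh` the enhancement offset of [enhance_isos()].
#' * `B9`: band `band_lo`..`band_hi` below B7.
#' * `B8`: between B7 and B9 with `pad_up`/`pad_dn` exclusion pads.
#' * `B6`: band of `band_up` rows above B7, keeping `margin` rows clear of the
#'   bright IS-OS shoulder.
#' * `B1`: everything above B6 minus `margin` rows.
#' * `B4`, `B5`, `B2`: bands between already-found neighbours.
#' * `B3`: band of `band_up` rows above B4.
#'
#' Polarity defaults follow retinal reflectivity: the outer nuclear layer is
#' the darkest band, so the frontier above it (B5) is bright-to-dark and the
#' one below it (B6) dark-to-bright.
#'
#' @return Named list of stage configuration lists.
#' @export
default_stage_configs <- function() {
  cfgs <- list(
    B7 = list(polarity = "dark_to_bright", lambda = 10, smooth = 0.08,
              ws = 101, enh = 0.30),
    B9 = list(polarity = "bright_to_dark", lambda = 10, smooth = 0.05,
              band_lo = 5, band_hi = 60),
    B8 = list(polarity = "bright_to_dark", lambda = 10, smooth = 0.05,
              pad_up = 1, pad_dn = 1),
    B6 = list(polarity = "dark_to_bright", lambda = 10, smooth = 0.05,
              band_up = 25, margin = 3),
    B1 = list(polarity = "dark_to_bright", lambda = 10, smooth = 0.05,
              margin = 2),
    B4 = list(polarity = "dark_to_bright", lambda = 10, smooth = 0.05,
              pad_up = 1, pad_dn = 1),
    B5 = list(polarity = "bright_to_dark", lambda = 10, smooth = 0.05,
              pad_up = 1, pad_dn = 1),
    B3 = list(polarity = "bright_to_dark", lambda = 10, smooth = 0.05,
              band_up = 20),
    B2 = list(polarity = "bright_to_dark", lambda = 10, smooth = 0.05,
              pad_up = 1, pad_dn = 1)
  )
  for (l in names(cfgs)) validate_stage_config(cfgs[[l]], l)
  cfgs
}

normalize_stage_configs <- function(configs) {
  if (is.null(configs)) return(default_stage_configs())
  if (!is.list(configs)) {
    abort_validation("`configs` must be a named list keyed B1..B9")
  }
  check_layer_labels(names(configs))
  base <- default_stage_configs()
  for (l in names(configs)) {
    validate_stage_config(configs[[l]], l)
    base[[l]] <- utils::modifyList(base[[l]], configs[[l]])
    validate_stage_config(base[[l]], l)
  }
  base
}

#' Read / write stage configurations as JSON
#'
#' The on-disk format is a single JSON object keyed `B1`..`B9`; each entry
#' holds the keys described in [default_stage_configs()]. Missing layers or
#' keys fall back to the defaults; unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return `read_stage_configs()` returns the fully resolved named list;
#'   `write_stage_configs()` returns `path` invisibly.
#' @export
read_stage_configs <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort_io(sprintf(
                    "failed to parse config JSON %s: %s", path,
                    conditionMessage(e))))
  normalize_stage_configs(lapply(raw, as.list))
}

#' @rdname read_stage_configs
#' @param configs Named list of stage configurations.
#' @export
write_stage_configs <- function(configs, path) {
  configs <- normalize_stage_configs(configs)
  jsonlite::write_json(configs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# Apply dotted-key overrides like "B3.band_up=30" to a config set.
apply_config_sets <- function(configs, sets) {
  for (s in sets) {
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort_validation(sprintf("--set expects layer.key=value, got '%s'", s))
    }
    lk <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    if (length(lk) != 2L) {
      abort_validation(sprintf("--set key must be layer.key, got '%s'", kv[1]))
    }
    check_layer_labels(lk[1])
    val <- if (lk[2] == "polarity") kv[2] else suppressWarnings(as.numeric(kv[2]))
    if (!is.character(val) && is.na(val)) {
      abort_validation(sprintf("--set %s: value '%s' is not numeric",
                               kv[1], kv[2]))
    }
    configs[[lk[1]]][[lk[2]]] <- val
    validate_stage_config(configs[[lk[1]]], lk[1])
  }
  configs
}
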