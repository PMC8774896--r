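# Condition helpers ---------------------------------------------------------

# Validation problems (bad parameters, malformed files, violated invariants).
abort_validation <- function(message, ..., class = character(0)) {
  rlang::abort(message, class = c(class, "oct_validation_error"), ...)
}

# I/O problems (unreadable or unwritable files).
abort_io <- function(message, ...) {
  rlang::abort(message, class = "oct_io_error", ...)
}

# A region of interest that leaves some image column with no admissible pixel.
abort_broken_roi <- function(columns, context = NULL) {
  cols <- paste(columns, collapse = ", ")
  msg <- sprintf("broken ROI: no admissible pixel in column(s) %s", cols)
  if (!is.null(context)) msg <- paste0(msg, " (", context, ")")
  abort_validation(msg, class = "oct_broken_roi", columns = columns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scalar checks --------------------------------------------------------------

check_number <- function(x, name, min = -Inf, strict = FALSE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    abort_validation(sprintf("`%s` must be a single finite number", name))
  }
  if (strict && x <= min) {
    abort_validation(sprintf("`%s` must be > %g (got %g)", name, min, x))
  }
  if (!strict && x < min) {
    abort_validation(sprintf("`%s` must be >= %g (got %g)", name, min, x))
  }
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

# Reflective (symmetric, edge-repeating) index folding for border padding.
# Maps any integer position, including ones beyond several mirror periods,
# into 1..n.
reflect_index <- function(pos, n) {
  if (n == 1L) return(rep(1L, length(pos)))
  t <- (pos - 1L) %% (2L * n)
  ifelse(t < n, t + 1L, 2L * n - t)
}

pad_reflect <- function(m, pr, pc = pr) {
  ri <- reflect_index(seq.int(1L - pr, nrow(m) + pr), nrow(m))
  ci <- reflect_index(seq.int(1L - pc, ncol(m) + pc), ncol(m))
  m[ri, ci, drop = FALSE]
}
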