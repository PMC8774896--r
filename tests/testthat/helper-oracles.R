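# Independent oracles used to pin expected values: naive loop implementations
# of the window filters and an exhaustive minimum-cost path search. These
# deliberately share no code with the package internals they check.

reflect_fold <- function(pos, n) {
  t <- (pos - 1L) %% (2L * n)
  ifelse(t < n, t + 1L, 2L * n - t)
}

naive_window_filter <- function(m, ws, fun) {
  ws <- if (ws %% 2 == 0) ws + 1L else as.integer(ws)
  p <- (ws - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      rr <- reflect_fold((r - p):(r + p), H)
      cc <- reflect_fold((c - p):(c + p), W)
      out[r, c] <- fun(m[rr, cc])
    }
  }
  out
}

naive_median_filter <- function(m, ws) naive_window_filter(m, ws, median)
naive_mean_filter <- function(m, ws) naive_window_filter(m, ws, mean)

tv2d <- function(m) {
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}

# Exhaustive minimum source-to-sink path cost over the pixel graph semantics:
# 8-connected admissible pixels with edge weight (2 - g(a) - g(b)) + eps,
# eps-weight pad columns at both sides tied to a virtual source and sink.
# Depth-first over all simple paths with cost pruning.
brute_force_min_cost <- function(values, mask = NULL, eps = 1e-5) {
  H <- nrow(values); W <- ncol(values)
  if (is.null(mask)) mask <- matrix(1, H, W)
  g <- 1 - values
  # node ids: real pixel (r,c) -> (c-1)*H + r ; pads and terminals after
  nid <- function(r, c) (c - 1L) * H + r
  n_real <- H * W
  left <- n_real + seq_len(H); right <- n_real + H + seq_len(H)
  src <- n_real + 2L * H + 1L; snk <- src + 1L
  adj <- vector("list", snk)
  add <- function(a, b, w) {
    adj[[a]][[length(adj[[a]]) + 1L]] <<- c(b, w)
    adj[[b]][[length(adj[[b]]) + 1L]] <<- c(a, w)
  }
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (mask[r, c] == 0) next
    for (dr in -1:1) for (dc in 0:1) {
      if (dc == 0 && dr <= 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > H || c2 > W) next
      if (mask[r2, c2] == 0) next
      add(nid(r, c), nid(r2, c2), 2 - g[r, c] - g[r2, c2] + eps)
    }
  }
  for (r in seq_len(H)) {
    if (r < H) {
      add(left[r], left[r + 1L], eps)
      add(right[r], right[r + 1L], eps)
    }
    for (dr in -1:1) {
      r2 <- r + dr
      if (r2 < 1 || r2 > H) next
      if (mask[r2, 1] != 0) add(left[r], nid(r2, 1L), 1 - g[r2, 1] + eps)
      if (mask[r2, W] != 0) add(right[r], nid(r2, W), 1 - g[r2, W] + eps)
    }
    add(src, left[r], eps)
    add(snk, right[r], eps)
  }
  best <- Inf
  visited <- rep(FALSE, snk)
  dfs <- function(node, cost) {
    if (cost >= best) return(invisible(NULL))
    if (node == snk) {
      best <<- cost
      return(invisible(NULL))
    }
    visited[node] <<- TRUE
    for (e in adj[[node]]) {
      if (!visited[e[1]]) dfs(e[1], cost + e[2])
    }
    visited[node] <<- FALSE
    invisible(NULL)
  }
  dfs(src, 0)
  best
}

# Small two-band fixture: dark band over bright band. The pixel at 0-based
# row `step_row` mixes the two bands half-and-half (sub-pixel rendering), so
# the discrete vertical gradient peaks uniquely at that row.
two_band_image <- function(H, W, step_row, top = 0.1, bottom = 0.9) {
  img <- matrix(top, H, W)
  img[step_row + 1, ] <- (top + bottom) / 2
  img[(step_row + 2):H, ] <- bottom
  img
}

layer_mae <- function(seg, truth, layer) {
  mean_absolute_error(seg$boundaries[[layer]], truth[[layer]])
}
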