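# Minimum-cost boundary extraction. The cost map becomes an 8-connected pixel
# graph flanked by two low-cost pad columns tied to a virtual source and sink;
# Dijkstra's shortest path from source to sink then traces the sought frontier
# and is collapsed to one row value per column.

GRAPH_EPS <- 1e-5

#' Build the weighted pixel graph for a cost map
#'
#' Every admissible pixel (mask 1) is a node connected to its 8 neighbours.
#' With `g = 1 - cost` (prominence, high on the sought frontier), the edge
#' weight between pixels a and b is `(2 - g(a) - g(b)) + eps` with
#' `eps = 1e-5`, so edges riding a prominent frontier cost almost nothing
#' while `eps > 0` preserves Dijkstra's optimality precondition. One pad
#' column is added at each side, fully vertically connected at weight `eps`
#' and linked to a virtual source (left) and sink (right), letting the path
#' enter and leave at any row for free.
#'
#' @param cost An `oct_costmap` from [build_cost_map()], or a numeric matrix
#'   in \[0, 1\].
#' @param mask Optional 0/1 matrix restricting the admissible pixels; every
#'   column must keep at least one admissible pixel.
#' @return An `oct_pixelgraph`: list with the igraph object, the admissible
#'   pixel index, dimensions, and the source/sink node ids.
#' @export
build_graph <- function(cost, mask = NULL) {
  values <- as_cost_matrix(cost)
  H <- nrow(values); W <- ncol(values)
  if (is.null(mask)) {
    adm <- matrix(TRUE, H, W)
  } else {
    if (!is.matrix(mask) || !all(dim(mask) == c(H, W))) {
      abort_validation("`mask` must match the cost map's shape")
    }
    adm <- mask != 0
  }
  empty <- which(colSums(adm) == 0L) - 1L
  if (length(empty) > 0L) abort_broken_roi(empty)

  g <- 1 - values
  n <- sum(adm)
  id <- matrix(NA_integer_, H, W)
  id[adm] <- seq_len(n)
  gnode <- g[adm]

  from <- integer(0); to <- integer(0)
  # 8-connectivity via 4 undirected offsets: down, right, down-right, up-right
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(H, H - dr)
    c1 <- max(1L, 1L - dc):min(W, W - dc)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    from <- c(from, a[keep]); to <- c(to, b[keep])
  }
  w <- (2 - gnode[from] - gnode[to]) + GRAPH_EPS

  # pad columns: ids n+1..n+H (left), n+H+1..n+2H (right); then source, sink
  left <- n + seq_len(H); right <- n + H + seq_len(H)
  source <- n + 2L * H + 1L; sink <- n + 2L * H + 2L
  pad_edges <- function(pad_ids, col) {
    pf <- integer(0); pt <- integer(0); pw <- numeric(0)
    if (H > 1L) {  # vertical chain inside the pad column
      pf <- pad_ids[-H]; pt <- pad_ids[-1L]; pw <- rep(GRAPH_EPS, H - 1L)
    }
    for (dr in -1L:1L) {  # 8-neighbour links into the adjacent real column
      rr <- seq_len(H); r2 <- rr + dr
      ok <- r2 >= 1L & r2 <= H
      b <- id[cbind(r2[ok], col)]
      keep <- !is.na(b)
      pf <- c(pf, pad_ids[rr[ok]][keep]); pt <- c(pt, b[keep])
      pw <- c(pw, 1 - gnode[b[keep]] + GRAPH_EPS)
    }
    list(from = pf, to = pt, w = pw)
  }
  le <- pad_edges(left, 1L)
  re <- pad_edges(right, W)
  from <- c(from, le$from, re$from, rep(source, H), rep(sink, H))
  to <- c(to, le$to, re$to, left, right)
  w <- c(w, le$w, re$w, rep(GRAPH_EPS, 2L * H))

  graph <- igraph::make_graph(rbind(from, to), n = sink, directed = FALSE)
  igraph::E(graph)$weight <- w
  structure(
    list(graph = graph, id = id, n_real = n, H = H, W = W,
         source = source, sink = sink, left = left, right = right),
    class = "oct_pixelgraph"
  )
}

#' Extract a boundary as the minimum-cost left-to-right path
#'
#' Runs Dijkstra's algorithm from the virtual source to the sink of the pixel
#' graph built by [build_graph()]. The optimal path visits at least one pixel
#' in every real column; vertical runs within a column are averaged to a
#' single row value, so the returned boundary is a total function of column.
#' The result is deterministic for a fixed input.
#'
#' @inheritParams build_graph
#' @return Numeric vector of length W with 0-based row positions, with
#'   attribute `path_cost` (total weight of the optimal path).
#' @examples
#' cost <- matrix(1, 8, 6); cost[4, ] <- 0
#' get_seg_boundary(cost)  # rides row 3 (0-based)
#' @export
get_seg_boundary <- function(cost, mask = NULL) {
  pg <- build_graph(cost, mask)
  sp <- igraph::shortest_paths(pg$graph, from = pg$source, to = pg$sink,
                               weights = igraph::E(pg$graph)$weight,
                               output = "both", algorithm = "dijkstra")
  nodes <- as.integer(sp$vpath[[1]])
  path_cost <- sum(igraph::E(pg$graph)$weight[as.integer(sp$epath[[1]])])
  real <- nodes[nodes <= pg$n_real]
  pos <- arrayInd(match(real, pg$id), dim(pg$id))
  rows0 <- pos[, 1] - 1; cols <- pos[, 2]
  boundary <- as.numeric(tapply(rows0, factor(cols, levels = seq_len(pg$W)),
                                mean))
  if (anyNA(boundary)) {
    # cannot happen for a connected source-sink path; guard regardless
    abort_validation("optimal path skipped an image column")
  }
  attr(boundary, "path_cost") <- path_cost
  boundary
}
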