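# Tubular nerve-fiber tracing: hysteresis detection, skeletonisation, graph
# building with per-node radii from the distance transform, tile-and-merge
# support for large images.

# Zhang-Suen binary thinning, vectorised over the whole mask.
zhang_suen <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, -1, 0);  p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);   p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);   p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1);  p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- 0
      for (i in 1:8) a <- a + (seqs[[i]] == 0) * (seqs[[i + 1]] == 1)
      if (step == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# hysteresis threshold: components of (x > low) containing a pixel > high
hysteresis <- function(x, low, high) {
  lowm <- x > low
  if (!any(lowm)) return(lowm)
  lab <- EBImage::bwlabel(lowm)
  keep <- sort(unique(lab[x > high]))
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nrow(x), ncol(x))
}

# decompose an undirected graph (edge tibble) into maximal junction-free
# paths; returns list of integer node-id vectors
.graph_segments <- function(n_nodes, edges) {
  if (nrow(edges) == 0L) return(list())
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  ekey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  visited <- new.env(hash = TRUE, parent = emptyenv())
  segs <- list()
  walk <- function(u, v) {
    path <- c(u, v)
    assign(ekey(u, v), TRUE, envir = visited)
    prev <- u; cur <- v
    while (deg[cur] == 2L) {
      nxt <- setdiff(adj[[cur]], prev)
      if (length(nxt) == 0L) break
      nxt <- nxt[1L]
      if (!is.null(visited[[ekey(cur, nxt)]])) break
      assign(ekey(cur, nxt), TRUE, envir = visited)
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }
  starts <- which(deg != 2L & deg > 0L)
  for (u in starts) for (v in adj[[u]]) {
    if (is.null(visited[[ekey(u, v)]])) segs[[length(segs) + 1L]] <- walk(u, v)
  }
  # pure cycles: every node degree 2
  remaining <- which(deg == 2L)
  for (u in remaining) for (v in adj[[u]]) {
    if (is.null(visited[[ekey(u, v)]])) segs[[length(segs) + 1L]] <- walk(u, v)
  }
  segs
}

# construct a fiber_graph from node/edge tables
fiber_graph <- function(nodes, edges, pixel_pitch) {
  stopifnot(all(c("node", "x", "y", "radius_um") %in% names(nodes)))
  if (nrow(edges)) {
    self <- edges$from == edges$to
    edges <- edges[!self, , drop = FALSE]
    key <- paste0(pmin(edges$from, edges$to), "_", pmax(edges$from, edges$to))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  structure(list(nodes = tibble::as_tibble(nodes),
                 edges = tibble::as_tibble(edges),
                 pixel_pitch = pixel_pitch),
            class = "fiber_graph")
}

#' @export
print.fiber_graph <- function(x, ...) {
  segs <- fiber_segments(x)
  cat(sprintf("<fiber_graph> %d nodes, %d edges, %d segments, total %.1f um\n",
              nrow(x$nodes), nrow(x$edges), nrow(segs), sum(segs$length_um)))
  invisible(x)
}

#' Segment table of a traced fiber graph
#'
#' Decomposes the graph into maximal junction-free paths and summarises each:
#' length (um, sum of node-to-node distances), mean diameter (um, from
#' per-node radii), and size-bin assignment.
#'
#' @param graph a `fiber_graph` (see [trace_fibers()]).
#' @return tibble with columns `segment`, `n_nodes`, `length_um`,
#'   `mean_diameter_um`, `bin`, and a list-column `path` of node ids.
#' @export
fiber_segments <- function(graph) {
  stopifnot(inherits(graph, "fiber_graph"))
  nodes <- graph$nodes
  id_map <- integer(max(nodes$node, 0L))
  id_map[nodes$node] <- seq_len(nrow(nodes))
  e <- graph$edges
  if (nrow(nodes) == 0L || nrow(e) == 0L) {
    return(tibble::tibble(segment = integer(0), n_nodes = integer(0),
                          length_um = numeric(0), mean_diameter_um = numeric(0),
                          bin = assign_bin(numeric(0)), path = list()))
  }
  el <- tibble::tibble(from = id_map[e$from], to = id_map[e$to])
  segs <- .graph_segments(nrow(nodes), el)
  pitch <- graph$pixel_pitch
  rows <- lapply(seq_along(segs), function(i) {
    p <- segs[[i]]
    xs <- nodes$x[p]; ys <- nodes$y[p]
    len <- sum(sqrt(diff(xs)^2 + diff(ys)^2)) * pitch
    dia <- mean(2 * nodes$radius_um[p])
    tibble::tibble(segment = i, n_nodes = length(p), length_um = len,
                   mean_diameter_um = dia, path = list(nodes$node[p]))
  })
  out <- dplyr::bind_rows(rows)
  out$bin <- assign_bin(out$mean_diameter_um)
  out[, c("segment", "n_nodes", "length_um", "mean_diameter_um", "bin", "path")]
}

# trace a single tile (full image); origin gives the (x, y) offset in px
.trace_single <- function(img, pitch, detect_sigma_px, low, high,
                          min_peak = 0.25) {
  mx <- max(img)
  if (!is.finite(mx) || mx < min_peak) {
    return(list(nodes = tibble::tibble(node = integer(0), x = numeric(0),
                                       y = numeric(0), radius_um = numeric(0)),
                edges = tibble::tibble(from = integer(0), to = integer(0))))
  }
  sm <- smooth2d(pmax(img, 0), detect_sigma_px)
  sm <- sm / max(sm)
  mask <- hysteresis(sm, low, high)
  if (!any(mask)) {
    return(list(nodes = tibble::tibble(node = integer(0), x = numeric(0),
                                       y = numeric(0), radius_um = numeric(0)),
                edges = tibble::tibble(from = integer(0), to = integer(0))))
  }
  skel <- zhang_suen(mask)
  # radius from the half-maximum contour: for Gaussian-profile tubes the 0.5
  # level reproduces the FWHM diameter (the hysteresis mask is wider)
  dist_px <- EBImage::distmap((sm > high & mask) * 1)
  ids <- which(skel)
  h <- nrow(img)
  ys <- ((ids - 1L) %% h) + 1L
  xs <- ((ids - 1L) %/% h) + 1L
  radius_um <- pmax(dist_px[ids] - 0.5, 0.25) * pitch
  nodes <- tibble::tibble(node = seq_along(ids), x = as.numeric(xs),
                          y = as.numeric(ys), radius_um = radius_um)
  # 8-neighbour edges between skeleton pixels
  lin_id <- integer(h * ncol(img)); lin_id[ids] <- seq_along(ids)
  at <- function(y2, x2) {
    ok <- y2 >= 1 & y2 <= h & x2 >= 1 & x2 <= ncol(img)
    out <- integer(length(y2))
    out[ok] <- lin_id[(x2[ok] - 1L) * h + y2[ok]]
    out
  }
  ef <- integer(0); et <- integer(0)
  for (k in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb <- at(ys + k[1], xs + k[2])
    hit <- nb > 0L
    if (all(k != 0)) {
      # drop diagonal shortcuts where an orthogonal 2-path exists (they
      # create spurious triangles and junctions in the skeleton graph)
      tri <- at(ys, xs + k[2]) > 0L | at(ys + k[1], xs) > 0L
      hit <- hit & !tri
    }
    ef <- c(ef, seq_along(ids)[hit]); et <- c(et, nb[hit])
  }
  edges <- tibble::tibble(from = ef, to = et)
  list(nodes = nodes, edges = edges)
}

#' Trace tubular fibers in an intensity image
#'
#' Detection by hysteresis thresholding of a lightly Gaussian-smoothed,
#' max-normalised image (the half-maximum contour of a Gaussian-profile tube
#' reproduces its FWHM diameter); skeletonisation by Zhang-Suen thinning;
#' per-node radius from the Euclidean distance transform at the centerline
#' (with half-pixel edge correction); segments are maximal junction-free
#' paths.  Large images can be traced in overlapping tiles that are merged
#' by matching endpoints across tile seams (nearest endpoint within 2 px).
#'
#' @param image numeric matrix or intensity [map_matrix].
#' @param pixel_pitch micrometres per pixel (taken from a [map_matrix]).
#' @param tile_px tile size in px (`Inf` traces in one piece).
#' @param overlap_px seam overlap, at least twice the largest ridge scale in
#'   px.
#' @param ridge_scales_um fiber scales (um) the detector should respond to;
#'   sets the detection smoothing.
#' @param low,high hysteresis thresholds on the max-normalised image.
#' @param spur_um terminal spurs shorter than this (thinning artifacts at
#'   junctions) are pruned.
#' @param min_peak tiles whose peak intensity falls below this (on the
#'   normalised tube-amplitude scale) are treated as background and yield
#'   no trace, so blank images return an empty graph.
#' @return a `fiber_graph`: tibbles `nodes` (`node`, `x`, `y`, `radius_um`)
#'   and `edges` (`from`, `to`), plus `pixel_pitch`.
#' @export
trace_fibers <- function(image, pixel_pitch = 0.4, tile_px = Inf,
                         overlap_px = 24, ridge_scales_um = c(1.2, 3, 5),
                         low = 0.3, high = 0.5, spur_um = 4,
                         min_peak = 0.25) {
  if (inherits(image, "map_matrix")) {
    pixel_pitch <- image$pixel_pitch
    image <- image$values
  }
  stopifnot(is.matrix(image))
  min_scale_px <- min(ridge_scales_um) / pixel_pitch
  if (is.finite(tile_px) && overlap_px < 2 * max(ridge_scales_um) / pixel_pitch)
    stopf("overlap_px must be at least twice the largest ridge scale")
  detect_sigma <- max(0.4, 0.2 * min_scale_px)

  h <- nrow(image); w <- ncol(image)
  if (!is.finite(tile_px) || (h <= tile_px && w <= tile_px)) {
    tr <- .trace_single(image, pixel_pitch, detect_sigma, low, high, min_peak)
    g <- fiber_graph(tr$nodes, tr$edges, pixel_pitch)
    return(prune_spurs(g, spur_um))
  }

  starts_y <- seq(1L, h, by = tile_px)
  starts_x <- seq(1L, w, by = tile_px)
  all_nodes <- list(); all_edges <- list(); offset <- 0L
  for (sy in starts_y) for (sx in starts_x) {
    y0 <- max(1L, sy - overlap_px); y1 <- min(h, sy + tile_px - 1L + overlap_px)
    x0 <- max(1L, sx - overlap_px); x1 <- min(w, sx + tile_px - 1L + overlap_px)
    tr <- .trace_single(image[y0:y1, x0:x1, drop = FALSE], pixel_pitch,
                        detect_sigma, low, high, min_peak)
    if (nrow(tr$nodes) == 0L) next
    tr$nodes$x <- tr$nodes$x + x0 - 1L
    tr$nodes$y <- tr$nodes$y + y0 - 1L
    # keep only nodes in this tile's core region
    core <- tr$nodes$x >= sx & tr$nodes$x <= min(w, sx + tile_px - 1L) &
      tr$nodes$y >= sy & tr$nodes$y <= min(h, sy + tile_px - 1L)
    keep_ids <- tr$nodes$node[core]
    remap <- integer(max(tr$nodes$node))
    remap[keep_ids] <- offset + seq_along(keep_ids)
    nodes <- tr$nodes[core, , drop = FALSE]
    nodes$node <- remap[keep_ids]
    e <- tr$edges[tr$edges$from %in% keep_ids & tr$edges$to %in% keep_ids, ,
                  drop = FALSE]
    if (nrow(e)) { e$from <- remap[e$from]; e$to <- remap[e$to] }
    all_nodes[[length(all_nodes) + 1L]] <- nodes
    all_edges[[length(all_edges) + 1L]] <- e
    offset <- offset + length(keep_ids)
  }
  nodes <- dplyr::bind_rows(all_nodes)
  edges <- dplyr::bind_rows(all_edges)
  if (nrow(nodes) == 0L)
    return(fiber_graph(tibble::tibble(node = integer(0), x = numeric(0),
                                      y = numeric(0), radius_um = numeric(0)),
                       tibble::tibble(from = integer(0), to = integer(0)),
                       pixel_pitch))
  # stitch across seams: connect endpoint-like nodes within 2 px
  g0 <- fiber_graph(nodes, edges, pixel_pitch)
  deg <- node_degrees(g0)
  open_n <- nodes[deg[as.character(nodes$node)] <= 1L | is.na(deg[as.character(nodes$node)]), ]
  if (nrow(open_n) > 1L) {
    add_f <- integer(0); add_t <- integer(0)
    for (i in seq_len(nrow(open_n))) {
      dx <- open_n$x - open_n$x[i]; dy <- open_n$y - open_n$y[i]
      d2 <- dx^2 + dy^2
      near <- which(d2 > 0 & d2 <= 4)
      for (j in near) {
        add_f <- c(add_f, open_n$node[i]); add_t <- c(add_t, open_n$node[j])
      }
    }
    if (length(add_f))
      edges <- dplyr::bind_rows(edges, tibble::tibble(from = add_f, to = add_t))
  }
  prune_spurs(fiber_graph(nodes, edges, pixel_pitch), spur_um)
}

# named vector of node degrees
node_degrees <- function(graph) {
  tab <- table(c(graph$edges$from, graph$edges$to))
  deg <- stats::setNames(rep(0L, nrow(graph$nodes)),
                         as.character(graph$nodes$node))
  deg[names(tab)] <- as.integer(tab)
  deg
}

# remove terminal spurs (short dangling segments at junctions)
prune_spurs <- function(graph, spur_um) {
  if (nrow(graph$edges) == 0L || spur_um <= 0) return(graph)
  repeat {
    segs <- fiber_segments(graph)
    if (nrow(segs) == 0L) return(graph)
    deg <- node_degrees(graph)
    drop_nodes <- integer(0)
    for (i in seq_len(nrow(segs))) {
      p <- segs$path[[i]]
      d1 <- deg[as.character(p[1])]; d2 <- deg[as.character(p[length(p)])]
      # spur: one free end, other end a junction, short
      if (segs$length_um[i] < spur_um && xor(d1 <= 1, d2 <= 1)) {
        interior <- if (d1 <= 1) p[-length(p)] else p[-1]
        drop_nodes <- c(drop_nodes, interior)
      }
    }
    if (length(drop_nodes) == 0L) return(graph)
    graph <- drop_graph_nodes(graph, unique(drop_nodes))
  }
}

# remove the listed node ids (and incident edges)
drop_graph_nodes <- function(graph, node_ids) {
  nodes <- graph$nodes[!graph$nodes$node %in% node_ids, , drop = FALSE]
  edges <- graph$edges[!(graph$edges$from %in% node_ids |
                           graph$edges$to %in% node_ids), , drop = FALSE]
  fiber_graph(nodes, edges, graph$pixel_pitch)
}
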