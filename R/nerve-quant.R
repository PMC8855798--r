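# Nerve-fiber quantification: post-filters for spurious junctions and
# below-floor diameters, size-binned length accounting, and the prevalence
# index.

# axial tangent (radians in [0, pi)) of a segment path near one end
.end_tangent <- function(nodes, path, at_start, k = 4L) {
  p <- if (at_start) path[seq_len(min(k, length(path)))] else
    rev(path)[seq_len(min(k, length(path)))]
  i <- match(p, nodes$node)
  dx <- nodes$x[i[length(i)]] - nodes$x[i[1]]
  dy <- nodes$y[i[length(i)]] - nodes$y[i[1]]
  fold_axial(atan2(dy, dx))
}

#' Filter a traced fiber graph
#'
#' Applies the two standard post-filters for automated nerve tracing:
#' drops nodes whose estimated diameter falls below the detection floor
#' (default 1.2 um, excluding background-staining artifacts), and removes
#' spurious junction bridges between near-parallel fibers - short
#' junction-to-junction connections (length <= `junction_gap_um`) joining
#' two fibers whose local tangents differ axially by less than
#' `parallel_angle_deg`.  Idempotent on clean graphs; genuine crossings at
#' steep angles are kept.
#'
#' @param graph a `fiber_graph`.
#' @param min_diameter_um diameter floor in micrometres.
#' @param parallel_angle_deg parallel-fiber angle threshold, degrees.
#' @param junction_gap_um maximum bridge length, micrometres.
#' @return a filtered `fiber_graph`.
#' @export
filter_graph <- function(graph, min_diameter_um = 1.2,
                         parallel_angle_deg = 20, junction_gap_um = 10) {
  stopifnot(inherits(graph, "fiber_graph"))
  if (min_diameter_um < 0 || parallel_angle_deg <= 0 || junction_gap_um <= 0)
    stopf("thresholds must be positive")
  small <- graph$nodes$node[2 * graph$nodes$radius_um < min_diameter_um]
  if (length(small)) graph <- drop_graph_nodes(graph, small)
  if (nrow(graph$edges) == 0L) return(graph)

  segs <- fiber_segments(graph)
  deg <- node_degrees(graph)
  nodes <- graph$nodes
  drop_edges <- list()
  for (i in seq_len(nrow(segs))) {
    p <- segs$path[[i]]
    u <- p[1]; v <- p[length(p)]
    if (deg[as.character(u)] < 3L || deg[as.character(v)] < 3L) next
    if (segs$length_um[i] > junction_gap_um) next
    # tangents of the through-going fibers at each junction: longest other
    # incident segment
    tan_at <- function(j, self) {
      inc <- which(vapply(segs$path, function(q)
        (q[1] == j || q[length(q)] == j), logical(1)))
      inc <- setdiff(inc, self)
      if (length(inc) == 0L) return(NA_real_)
      best <- inc[which.max(segs$length_um[inc])]
      q <- segs$path[[best]]
      .end_tangent(nodes, q, at_start = (q[1] == j))
    }
    t1 <- tan_at(u, i); t2 <- tan_at(v, i)
    if (is.na(t1) || is.na(t2)) next
    d <- abs(t1 - t2)
    d <- min(d, pi - d) * 180 / pi
    if (d < parallel_angle_deg) {
      pr <- cbind(p[-length(p)], p[-1])
      drop_edges[[length(drop_edges) + 1L]] <- pr
    }
  }
  if (length(drop_edges)) {
    de <- do.call(rbind, drop_edges)
    key <- paste0(pmin(de[, 1], de[, 2]), "_", pmax(de[, 1], de[, 2]))
    ekey <- paste0(pmin(graph$edges$from, graph$edges$to), "_",
                   pmax(graph$edges$from, graph$edges$to))
    graph <- fiber_graph(graph$nodes,
                         graph$edges[!ekey %in% key, , drop = FALSE],
                         graph$pixel_pitch)
  }
  graph
}

#' Size-binned fiber length in a region
#'
#' Assigns each segment to a diameter bin by its mean diameter and
#' accumulates length per bin; with an ROI mask, segments are clipped at the
#' ROI boundary (edge midpoints decide membership).  Segments wider than the
#' top bin are excluded with a warning.
#'
#' @param graph a `fiber_graph`.
#' @param bins bin table from [size_bins()].
#' @param roi_mask optional logical matrix in image pixels.
#' @return tibble with columns `bin` and `length_um` (all bins present).
#' @export
bin_lengths <- function(graph, bins = size_bins(), roi_mask = NULL) {
  stopifnot(inherits(graph, "fiber_graph"))
  segs <- fiber_segments(graph)
  if (any(segs$mean_diameter_um > max(bins$hi_um))) {
    warnf("%d segment(s) wider than %g um excluded",
          sum(segs$mean_diameter_um > max(bins$hi_um)), max(bins$hi_um))
  }
  out <- tibble::tibble(bin = bins$bin, length_um = 0)
  nodes <- graph$nodes
  for (i in seq_len(nrow(segs))) {
    b <- segs$bin[i]
    if (is.na(b)) next
    p <- segs$path[[i]]
    idx <- match(p, nodes$node)
    xs <- nodes$x[idx]; ys <- nodes$y[idx]
    step <- sqrt(diff(xs)^2 + diff(ys)^2) * graph$pixel_pitch
    if (!is.null(roi_mask)) {
      mx <- round((xs[-1] + xs[-length(xs)]) / 2)
      my <- round((ys[-1] + ys[-length(ys)]) / 2)
      ok <- mx >= 1 & mx <= ncol(roi_mask) & my >= 1 & my <= nrow(roi_mask)
      inroi <- rep(FALSE, length(step))
      inroi[ok] <- roi_mask[cbind(my[ok], mx[ok])]
      step <- step[inroi]
    }
    out$length_um[out$bin == b] <- out$length_um[out$bin == b] + sum(step)
  }
  out
}

#' Regional fiber-size prevalence index
#'
#' For each diameter bin, the proportion of that size class in the ROI
#' divided by its proportion in the whole heart:
#' `(L_roi,bin / sum(L_roi)) / (L_whole,bin / sum(L_whole))`.  A value of 1
#' means the ROI mirrors the whole-heart composition; values above 1 mean
#' local enrichment (e.g. small-fiber sprouting at an infarct border zone).
#'
#' @param roi_bin_lengths,whole_bin_lengths tibbles from [bin_lengths()].
#' @return tibble with columns `bin`, `prevalence` (NA when the ROI has zero
#'   total length; bins absent from the whole heart error).
#' @export
prevalence_index <- function(roi_bin_lengths, whole_bin_lengths) {
  stopifnot(all(c("bin", "length_um") %in% names(roi_bin_lengths)),
            all(c("bin", "length_um") %in% names(whole_bin_lengths)))
  j <- dplyr::inner_join(roi_bin_lengths, whole_bin_lengths,
                         by = "bin", suffix = c("_roi", "_whole"))
  tot_roi <- sum(j$length_um_roi)
  tot_whole <- sum(j$length_um_whole)
  if (any(j$length_um_whole <= 0))
    stopf("whole-heart totals must be positive for every bin")
  if (tot_roi <= 0) {
    warnf("ROI has zero total fiber length; prevalence undefined")
    return(tibble::tibble(bin = j$bin, prevalence = NA_real_))
  }
  tibble::tibble(bin = j$bin,
                 prevalence = (j$length_um_roi / tot_roi) /
                   (j$length_um_whole / tot_whole))
}
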