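# Plain-text and TIFF interchange.  Coordinate convention in all exported
# files: pixel centers, 0-based, x rightward, y downward (stated in file
# headers where the format allows comments).

#' Read/write a scalar map as CSV
#'
#' Row-major numeric CSV, `NaN` marking invalid pixels; no header row.
#'
#' @param map a [map_matrix].
#' @param path file path.
#' @param units,pixel_pitch metadata applied on read.
#' @return `write_map_csv` returns `path` invisibly; `read_map_csv` a
#'   [map_matrix].
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "map_matrix"))
  vals <- map$values
  vals[!map$valid_mask] <- NaN
  utils::write.table(vals, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NaN")
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path, units = "ms", pixel_pitch = 55) {
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                      na.strings = c("NaN", "NA")))
  dimnames(vals) <- NULL
  map_matrix(vals, units, pixel_pitch, valid_mask = is.finite(vals))
}

#' Read/write a scalar map as 32-bit float TIFF
#'
#' Invalid pixels are written as 0 (the TIFF writer does not preserve NaN);
#' use [write_map_csv()] when the validity mask must survive the round trip.
#'
#' @inheritParams write_map_csv
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "map_matrix"))
  vals <- map$values
  vals[!map$valid_mask] <- 0
  tiff::writeTIFF(vals, path, bits.per.sample = 32, reduce = TRUE)
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path, units = "ms", pixel_pitch = 55) {
  vals <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(vals)) == 3L) vals <- vals[, , 1]
  map_matrix(vals, units, pixel_pitch, valid_mask = is.finite(vals))
}

#' Write/read a voltage movie as multi-page TIFF
#'
#' One page per frame, 32-bit float.
#' @param movie a [voltage_movie].
#' @param path file path.
#' @param sampling_rate,pixel_pitch metadata applied on read.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "voltage_movie"))
  d <- dim(movie$frames)
  pages <- lapply(seq_len(d[1]), function(t) matrix(movie$frames[t, , ], d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = TRUE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, sampling_rate = 1.03, pixel_pitch = 55) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    frames[t, , ] <- p
  }
  voltage_movie(frames, sampling_rate, pixel_pitch = pixel_pitch)
}

#' Read/write paired fiducial points as CSV
#'
#' Columns `x_optical, y_optical, x_structural, y_structural, label`;
#' coordinates in pixels, 0-based in the file, converted to R's 1-based
#' convention on read.
#'
#' @param fiducials tibble of fiducial pairs.
#' @param path file path.
#' @export
write_fiducials_csv <- function(fiducials, path) {
  out <- fiducials
  for (col in c("x_optical", "y_optical", "x_structural", "y_structural"))
    out[[col]] <- out[[col]] - 1
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducials_csv
#' @export
read_fiducials_csv <- function(path) {
  f <- tibble::as_tibble(utils::read.csv(path))
  for (col in c("x_optical", "y_optical", "x_structural", "y_structural"))
    f[[col]] <- f[[col]] + 1
  f
}

#' Read/write a homography as JSON
#'
#' Nine numbers, row-major, plus the normalisation convention.
#' @param h a `cm_homography` or 3x3 matrix.
#' @param path file path.
#' @export
write_homography_json <- function(h, path) {
  H <- if (inherits(h, "cm_homography")) h$H else h
  jsonlite::write_json(list(
    H_row_major = as.vector(t(H)),
    direction = "structural_to_optical",
    normalization = "frobenius_norm_1_H33_nonneg",
    coordinates = "pixel centers, 0-based, x rightward, y downward"
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_homography_json
#' @export
read_homography_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  matrix(j$H_row_major, 3, 3, byrow = TRUE)
}

#' Write/read traced fiber morphology as SWC
#'
#' Standard SWC (`id type x y z radius parent`, whitespace-separated, `#`
#' comments).  Coordinates and radii are written in micrometres; the type
#' field carries the size-bin label (1 small, 2 medium, 3 large, 0 unbinned).
#' Graph cycles are broken by a spanning forest on write.
#'
#' @param graph a `fiber_graph`.
#' @param path file path.
#' @param pixel_pitch micrometres per pixel assumed on read.
#' @export
write_swc <- function(graph, path) {
  stopifnot(inherits(graph, "fiber_graph"))
  nodes <- graph$nodes
  pitch <- graph$pixel_pitch
  segs <- fiber_segments(graph)
  type <- stats::setNames(rep(0L, nrow(nodes)), as.character(nodes$node))
  for (i in seq_len(nrow(segs))) {
    b <- as.integer(segs$bin[i])
    if (!is.na(b)) type[as.character(segs$path[[i]])] <- b
  }
  parent <- stats::setNames(rep(-1L, nrow(nodes)), as.character(nodes$node))
  if (nrow(graph$edges)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(graph$edges$from),
                 to = as.character(graph$edges$to)),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes$node)))
    comps <- igraph::components(g)
    for (ci in seq_len(comps$no)) {
      members <- igraph::V(g)[comps$membership == ci]
      root <- members[1]
      bfs <- igraph::bfs(g, root = root, unreachable = FALSE, father = TRUE)
      f <- bfs$father
      ok <- !is.na(f) & comps$membership == ci
      parent[names(igraph::V(g))[ok]] <-
        as.integer(names(igraph::V(g))[as.integer(f[ok])])
    }
  }
  lines <- c(
    "# SWC traced fiber morphology",
    "# coordinates in micrometres; pixel centers, 0-based grid, x rightward, y downward",
    "# type: 1 small, 2 medium, 3 large, 0 unbinned",
    sprintf("%d %d %.4f %.4f 0 %.4f %d",
            nodes$node, as.integer(type[as.character(nodes$node)]),
            (nodes$x - 1) * pitch, (nodes$y - 1) * pitch,
            nodes$radius_um, as.integer(parent[as.character(nodes$node)]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path, pixel_pitch = 1) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  nodes <- tibble::tibble(node = as.integer(tab$id),
                          x = tab$x / pixel_pitch + 1,
                          y = tab$y / pixel_pitch + 1,
                          radius_um = tab$radius)
  has_parent <- tab$parent > 0
  edges <- tibble::tibble(from = as.integer(tab$id[has_parent]),
                          to = as.integer(tab$parent[has_parent]))
  fiber_graph(nodes, edges, pixel_pitch)
}
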