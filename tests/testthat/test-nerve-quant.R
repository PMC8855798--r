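# Tracing, junction filtering, size binning, prevalence.

test_that("a single rendered tube is traced with correct length and diameter", {
  ni <- make_nerve_image(tube_spec(1, 5, 30, 105, 30, 4),
                         background_sd = 0.02, seed = 1,
                         width_um = 115, height_um = 60)
  g <- trace_fibers(ni$image)
  segs <- fiber_segments(g)
  expect_equal(nrow(segs), 1)
  expect_lt(abs(segs$length_um - 100), 5)
  expect_lt(abs(segs$mean_diameter_um - 4), 0.8)
})

test_that("parallel tubes stay separate; blank images give empty graphs", {
  s2 <- dplyr::bind_rows(tube_spec(1, 5, 20, 105, 20, 3.6),
                         tube_spec(2, 5, 30, 105, 30, 3.6))
  n2 <- make_nerve_image(s2, background_sd = 0.02, seed = 1,
                         width_um = 115, height_um = 50)
  g <- trace_fibers(n2$image)
  segs <- fiber_segments(g)
  expect_equal(nrow(segs), 2)
  # no edge connects the two tubes: each segment is one tube's length
  expect_true(all(abs(segs$length_um - 100) < 5))

  blank <- make_nerve_image(NULL, background_sd = 0.02, seed = 2)
  g0 <- trace_fibers(blank$image)
  expect_equal(nrow(g0$nodes), 0)
  expect_equal(nrow(fiber_segments(g0)), 0)
})

test_that("tile-and-merge tracing matches single-tile tracing", {
  set.seed(11)
  specs <- dplyr::bind_rows(lapply(1:6, function(i) {
    tube_spec(i, runif(1, 5, 40), runif(1, 5, 110),
              runif(1, 80, 115), runif(1, 5, 110), runif(1, 2, 6))
  }))
  ni <- make_nerve_image(specs, background_sd = 0.02, seed = 3,
                         width_um = 120, height_um = 120)
  g1 <- trace_fibers(ni$image)
  g2 <- trace_fibers(ni$image, tile_px = 160, overlap_px = 30)
  t1 <- sum(fiber_segments(g1)$length_um)
  t2 <- sum(fiber_segments(g2)$length_um)
  expect_lt(abs(t2 - t1) / t1, 0.02)
  # translation invariance: padding shifts node coordinates identically
  img <- ni$image$values
  pad <- matrix(0, nrow(img) + 20, ncol(img) + 20)
  pad[21:(20 + nrow(img)), 21:(20 + ncol(img))] <- img
  g3 <- trace_fibers(map_matrix(pad, "intensity", ni$image$pixel_pitch))
  expect_equal(sort(g3$nodes$x), sort(g1$nodes$x + 20), tolerance = 1e-9)
  expect_equal(sort(g3$nodes$y), sort(g1$nodes$y + 20), tolerance = 1e-9)
})

test_that("the junction filter removes parallel bridges and keeps crossings", {
  g <- two_fiber_graph(bridge = TRUE)          # ~5 degrees apart
  expect_equal(nrow(fiber_segments(g)), 5)
  gf <- filter_graph(g)
  expect_equal(nrow(fiber_segments(gf)), 2)
  key <- paste(gf$edges$from, gf$edges$to)
  expect_false("11 32" %in% key)
  # idempotent on the already-clean graph
  gf2 <- filter_graph(gf)
  expect_identical(fiber_segments(gf2)$length_um, fiber_segments(gf)$length_um)

  # X-crossing at ~80 degrees: junction is kept
  a <- 40 * pi / 180
  nx1 <- tibble::tibble(node = 1:21, x = (-10:10) * cos(a) + 15,
                        y = (-10:10) * sin(a) + 15, radius_um = 1.5)
  nx2 <- tibble::tibble(node = 22:42, x = (-10:10) * cos(-a) + 15,
                        y = (-10:10) * sin(-a) + 15, radius_um = 1.5)
  ex <- tibble::tibble(from = c(1:20, 22:41), to = c(2:21, 23:42))
  ex <- dplyr::bind_rows(ex, tibble::tibble(from = 11, to = 32))
  gx <- cardiomapr:::fiber_graph(dplyr::bind_rows(nx1, nx2), ex, 1)
  gxf <- filter_graph(gx)
  expect_equal(nrow(gxf$edges), nrow(gx$edges))

  # diameter floor drops thin nodes
  gt <- two_fiber_graph(bridge = FALSE, radius_um = 0.4)
  expect_equal(nrow(filter_graph(gt)$nodes), 0)
})

test_that("length conservation: filtering never increases total length", {
  ni <- make_nerve_image(dplyr::bind_rows(
    tube_spec(1, 5, 20, 105, 22, 2),
    tube_spec(2, 5, 26, 105, 24, 2.4)), background_sd = 0.02, seed = 5,
    width_um = 115, height_um = 45)
  g <- trace_fibers(ni$image)
  gf <- filter_graph(g)
  expect_lte(sum(fiber_segments(gf)$length_um),
             sum(fiber_segments(g)$length_um) + 1e-9)
})

test_that("binning follows the half-open rule and partitions total length", {
  mk_seg <- function(node0, d_um, y) {
    tibble::tibble(node = node0 + 0:10, x = as.numeric(0:10) * 5, y = y,
                   radius_um = d_um / 2)
  }
  nodes <- dplyr::bind_rows(mk_seg(1, 2, 5), mk_seg(20, 3, 15), mk_seg(40, 5, 25))
  edges <- tibble::tibble(from = c(1:10, 20:29, 40:49),
                          to = c(2:11, 21:30, 41:50))
  g <- cardiomapr:::fiber_graph(nodes, edges, 1)
  bl <- bin_lengths(g)
  expect_equal(bl$length_um[bl$bin == "small"], 50)   # 2 um
  expect_equal(bl$length_um[bl$bin == "medium"], 50)  # exactly 3 um -> medium
  expect_equal(bl$length_um[bl$bin == "large"], 50)   # exactly 5 um -> large
  expect_equal(sum(bl$length_um), sum(fiber_segments(g)$length_um))

  # over-wide segments are excluded with a warning
  fat <- cardiomapr:::fiber_graph(mk_seg(1, 150, 5),
                                  tibble::tibble(from = 1:10, to = 2:11), 1)
  expect_warning(blf <- bin_lengths(fat), "excluded")
  expect_equal(sum(blf$length_um), 0)

  # ROI clipping: only edges with midpoints inside the mask count
  roi <- matrix(FALSE, 40, 60); roi[, 1:26] <- TRUE
  blr <- bin_lengths(g, roi_mask = roi)
  expect_equal(sum(blr$length_um), 75)   # half of each 50 um segment
})

test_that("prevalence index reproduces its algebraic identities", {
  whole <- tibble::tibble(bin = size_bins()$bin, length_um = c(20, 30, 50))
  expect_true(all(prevalence_index(whole, whole)$prevalence == 1))
  roi <- tibble::tibble(bin = size_bins()$bin, length_um = c(40, 20, 40))
  pr <- prevalence_index(roi, whole)
  expect_equal(pr$prevalence[pr$bin == "small"], 0.4 / 0.2)
  # ROI with only small fibers, whole-heart small fraction 0.25
  whole2 <- tibble::tibble(bin = size_bins()$bin, length_um = c(25, 35, 40))
  only_small <- tibble::tibble(bin = size_bins()$bin, length_um = c(10, 0, 0))
  pr2 <- prevalence_index(only_small, whole2)
  expect_equal(pr2$prevalence, c(4, 0, 0))
  # prevalence weighted by whole-heart proportions sums to 1
  w <- whole2$length_um / sum(whole2$length_um)
  expect_equal(sum(pr2$prevalence * w), 1, tolerance = 1e-12)
  # zero-length ROI -> NA with warning
  expect_warning(
    pr3 <- prevalence_index(tibble::tibble(bin = size_bins()$bin,
                                           length_um = c(0, 0, 0)), whole),
    "undefined")
  expect_true(all(is.na(pr3$prevalence)))
  expect_error(prevalence_index(roi, tibble::tibble(bin = size_bins()$bin,
                                                    length_um = c(0, 1, 1))),
               "positive")
})

test_that("end-to-end per-bin recovery is within 10% of rendered truth", {
  set.seed(8)
  specs <- dplyr::bind_rows(
    tube_spec(1, 5, 10, 115, 14, 2),
    tube_spec(2, 5, 28, 115, 24, 2.5),
    tube_spec(3, 5, 42, 115, 44, 4),
    tube_spec(4, 5, 58, 115, 60, 3.6),
    tube_spec(5, 5, 74, 115, 70, 6.5),
    tube_spec(6, 5, 90, 115, 94, 8))
  ni <- make_nerve_image(specs, background_sd = 0.02, seed = 6,
                         width_um = 120, height_um = 100)
  g <- filter_graph(trace_fibers(ni$image))
  bl <- bin_lengths(g)
  j <- dplyr::inner_join(bl, ni$truth, by = "bin",
                         suffix = c("_traced", "_true"))
  expect_true(all(abs(j$length_um_traced - j$length_um_true) /
                    j$length_um_true < 0.10))
})

test_that("SWC round trip preserves geometry, radii and lengths", {
  g <- two_fiber_graph(bridge = FALSE)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(g, path)
  g2 <- read_swc(path, pixel_pitch = 1)
  expect_equal(sort(g2$nodes$x), sort(g$nodes$x), tolerance = 1e-6)
  expect_equal(sort(g2$nodes$radius_um), sort(g$nodes$radius_um),
               tolerance = 1e-6)
  s1 <- fiber_segments(g); s2 <- fiber_segments(g2)
  expect_equal(sort(s1$length_um), sort(s2$length_um), tolerance = 1e-6)
})
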