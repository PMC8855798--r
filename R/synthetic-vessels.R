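#' Synthesise a vascular fiducial scene in two frames
#'
#' Generates a branching curvilinear vessel tree in the optical frame,
#' renders it, and renders its image under the known homography
#' `homography_true` (structural frame), returning the paired branch-point
#' fiducial coordinates with independent Gaussian jitter per frame.  Vessel
#' branch points play the role of venous-bifurcation fiducial anchors.
#'
#' @param phantom a [make_phantom()] object (sets the canvas and tissue).
#' @param homography_true 3x3 matrix mapping structural to optical
#'   coordinates (must be invertible).
#' @param n_points number of branch-point fiducials (4-10).
#' @param jitter_sd Gaussian jitter SD (px) added to each fiducial,
#'   independently in each frame.
#' @param seed integer seed.
#' @return list with `optical` and `structural` intensity [map_matrix]
#'   images, and `fiducials`: a tibble with columns `x_optical, y_optical,
#'   x_structural, y_structural, label`.
#' @export
make_vessel_tree <- function(phantom, homography_true = diag(3),
                             n_points = 8, jitter_sd = 0, seed = 1) {
  stopifnot(inherits(phantom, "heart_phantom"))
  if (n_points < 4) stopf("need at least 4 branch points for registration")
  if (n_points > 10) stopf("at most 10 branch points supported")
  H <- homography_true
  if (abs(det(H)) < 1e-12) stopf("homography_true must be invertible")
  w <- phantom$width; h <- phantom$height

  res <- with_seed(seed, {
    # trunk down the midline; primary branches peel off at staggered heights
    # and bifurcate again partway along -- those secondary bifurcations,
    # spread over the tissue, are the fiducial anchors
    trunk_x <- w * (0.5 + 0.06 * sin(seq(0, 2 * pi, length.out = 40)))
    trunk_y <- seq(0.12 * h, 0.88 * h, length.out = 40)
    branch_t <- seq(0.15, 0.9, length.out = n_points) +
      stats::runif(n_points, -0.02, 0.02)
    side <- rep(c(-1, 1), length.out = n_points)
    segs <- list(cbind(trunk_x, trunk_y))
    fid <- matrix(NA_real_, n_points, 2)
    for (i in seq_len(n_points)) {
      ti <- branch_t[i]
      bx <- stats::approx(seq(0, 1, length.out = 40), trunk_x, ti)$y
      by <- stats::approx(seq(0, 1, length.out = 40), trunk_y, ti)$y
      reach <- stats::runif(1, 0.22, 0.38) * w * side[i]
      mx <- bx + reach
      my <- by + stats::runif(1, -0.08, 0.08) * h
      bt <- seq(0, 1, length.out = 20)
      segs[[length(segs) + 1L]] <- cbind(bx + (mx - bx) * bt +
                                           2 * sin(3 * pi * bt),
                                         by + (my - by) * bt)
      # two sub-branches from the secondary bifurcation at (mx, my)
      for (sgn in c(-1, 1)) {
        ex <- mx + 0.08 * w * side[i]
        ey <- my + sgn * stats::runif(1, 0.05, 0.12) * h
        segs[[length(segs) + 1L]] <- cbind(mx + (ex - mx) * bt,
                                           my + (ey - my) * bt)
      }
      fid[i, ] <- c(mx, my)
    }
    list(segs = segs, fid = fid)
  })

  render <- function(segs, w, h) {
    img <- matrix(0, h, w)
    pts <- do.call(rbind, lapply(segs, function(s) {
      # densify to sub-pixel spacing
      n <- nrow(s)
      d <- cumsum(c(0, sqrt(rowSums(diff(s)^2))))
      tt <- seq(0, d[n], by = 0.5)
      cbind(stats::approx(d, s[, 1], tt)$y, stats::approx(d, s[, 2], tt)$y)
    }))
    for (dy in -1:1) for (dx in -1:1) {
      xi <- round(pts[, 1]) + dx; yi <- round(pts[, 2]) + dy
      ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
      img[cbind(yi[ok], xi[ok])] <- 1
    }
    img
  }

  opt_img <- render(res$segs, w, h)
  Hi <- solve(H)                                  # optical -> structural
  segs_str <- lapply(res$segs, function(s) project_points(Hi, s))
  str_img <- render(segs_str, w, h)
  fid_str <- project_points(Hi, res$fid)

  jit <- function(m, sub_seed) {
    if (jitter_sd == 0) return(m)
    with_seed(seed + sub_seed, m + matrix(stats::rnorm(length(m), 0, jitter_sd),
                                          nrow(m), ncol(m)))
  }
  fo <- jit(res$fid, 101L); fs <- jit(fid_str, 202L)
  fiducials <- tibble::tibble(
    x_optical = fo[, 1], y_optical = fo[, 2],
    x_structural = fs[, 1], y_structural = fs[, 2],
    label = paste0("venous bifurcation ", seq_len(n_points))
  )
  list(
    optical = map_matrix(opt_img, "intensity", phantom$pixel_pitch),
    structural = map_matrix(str_img, "intensity", phantom$pixel_pitch),
    fiducials = fiducials,
    homography_true = H
  )
}
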