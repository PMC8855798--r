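# Fiducial-based registration between the optical (functional) and
# structural (cleared-tissue) frames.  The canonical direction is
# structural -> optical: structure is brought onto the frame that hosts the
# functional data.

#' Apply a homography to point coordinates
#'
#' @param H 3x3 matrix.
#' @param pts n x 2 matrix (or data frame) of `(x, y)` coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
project_points <- function(H, pts) {
  pts <- as.matrix(pts)
  ph <- cbind(pts[, 1], pts[, 2], 1) %*% t(H)
  cbind(ph[, 1] / ph[, 3], ph[, 2] / ph[, 3])
}

# Hartley normalisation: translate centroid to origin, scale mean distance
# to sqrt(2); returns the 3x3 similarity transform.
.hartley <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- sqrt(2) / max(mean(d), .Machine$double.eps)
  matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
}

# plain DLT on >= 4 correspondences (src -> dst), Hartley-normalised
.dlt <- function(src, dst) {
  Ts <- .hartley(src); Td <- .hartley(dst)
  s <- project_points(Ts, src); d <- project_points(Td, dst)
  n <- nrow(s)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  H / sqrt(sum(H^2)) * sign(H[3, 3] + (H[3, 3] == 0))
}

# geometric refinement of the DLT solution: minimise summed squared
# reprojection error over the 9 entries (scale fixed by renormalisation)
.refine_geometric <- function(H, src, dst) {
  fn <- function(hv) {
    Hc <- matrix(hv, 3, 3)
    p <- project_points(Hc, src)
    sum((p - dst)^2)
  }
  res <- tryCatch(stats::optim(as.vector(H), fn, method = "BFGS",
                               control = list(reltol = 1e-14, maxit = 500)),
                  error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value)) return(H)
  Hr <- matrix(res$par, 3, 3)
  if (abs(det(Hr)) < 1e-12) return(H)
  Hr / sqrt(sum(Hr^2)) * sign(Hr[3, 3] + (Hr[3, 3] == 0))
}

.collinear <- function(pts, tol = 1e-8) {
  if (nrow(pts) < 3) return(TRUE)
  c0 <- sweep(as.matrix(pts), 2, colMeans(pts))
  sv <- svd(c0)$d
  sv[2] / max(sv[1], .Machine$double.eps) < tol
}

#' Fit a perspective warp (homography) to paired fiducial points
#'
#' Normalised direct linear transform (Hartley-normalised coordinates,
#' smallest-singular-vector solution) mapping structural to optical
#' coordinates from >= 4 paired fiducial points (5-10 vascular branch
#' points, sutures or scars are typical), followed by geometric refinement
#' (minimising summed squared reprojection error) when the system is
#' overdetermined.  Optional robust mode runs a
#' consensus search over random minimal 4-point subsets (inlier threshold
#' `inlier_px`) and refits on the inliers.
#'
#' @param fiducials tibble/data frame with columns `x_optical`, `y_optical`,
#'   `x_structural`, `y_structural` (see [make_vessel_tree()]), or a list
#'   with `$fiducials`.
#' @param robust logical; use the consensus search.
#' @param inlier_px inlier reprojection threshold in px (robust mode).
#' @param n_trials number of minimal subsets to try (robust mode).
#' @param seed seed for the subset draw.
#' @return object of class `cm_homography`: list with `H` (3x3, Frobenius
#'   norm 1, `H[3,3] >= 0`), `residuals` tibble (per-point euclidean
#'   reprojection error, px, and inlier flag), `rmse` (per-coordinate RMS
#'   residual over the inliers, px), `n`.
#' @export
fit_homography <- function(fiducials, robust = FALSE, inlier_px = 3,
                           n_trials = 200, seed = 1) {
  if (is.list(fiducials) && !is.data.frame(fiducials) &&
      !is.null(fiducials$fiducials)) fiducials <- fiducials$fiducials
  need <- c("x_optical", "y_optical", "x_structural", "y_structural")
  stopifnot(all(need %in% names(fiducials)))
  src <- cbind(fiducials$x_structural, fiducials$y_structural)
  dst <- cbind(fiducials$x_optical, fiducials$y_optical)
  n <- nrow(src)
  if (n < 4) stopf("need at least 4 fiducial pairs, got %d", n)
  if (anyDuplicated(round(dst, 9)) || anyDuplicated(round(src, 9)))
    stopf("duplicate fiducial points")
  if (.collinear(src) || .collinear(dst))
    stopf("degenerate configuration: fiducials are collinear")

  inliers <- rep(TRUE, n)
  if (robust && n > 4) {
    best <- -1L
    best_err <- Inf
    with_seed(seed, {
      for (t in seq_len(n_trials)) {
        pick <- sample.int(n, 4L)
        if (.collinear(src[pick, , drop = FALSE]) ||
            .collinear(dst[pick, , drop = FALSE])) next
        Ht <- tryCatch(.dlt(src[pick, , drop = FALSE], dst[pick, , drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(Ht)) next
        err <- sqrt(rowSums((project_points(Ht, src) - dst)^2))
        inl <- err < inlier_px
        score <- sum(inl)
        merr <- stats::median(err[inl])
        if (score > best || (score == best && merr < best_err)) {
          best <- score; best_err <- merr; inliers <- inl
        }
      }
    })
    if (sum(inliers) < 4) stopf("robust fit found fewer than 4 inliers")
  }
  H <- .dlt(src[inliers, , drop = FALSE], dst[inliers, , drop = FALSE])
  if (abs(det(H)) < 1e-12) stopf("fitted homography is singular")
  if (sum(inliers) > 4)
    H <- .refine_geometric(H, src[inliers, , drop = FALSE],
                           dst[inliers, , drop = FALSE])
  err <- sqrt(rowSums((project_points(H, src) - dst)^2))
  res <- tibble::tibble(
    point = seq_len(n), residual_px = err, inlier = inliers,
    label = fiducials[["label"]] %||% rep(NA_character_, n)
  )
  structure(list(H = H, residuals = res,
                 rmse = sqrt(sum(err[inliers]^2) / (2 * sum(inliers))), n = n),
            class = "cm_homography")
}

#' @export
print.cm_homography <- function(x, ...) {
  cat(sprintf("<cm_homography> structural -> optical, %d points, RMSE %.4g px\n",
              x$n, x$rmse))
  print(signif(x$H, 6))
  invisible(x)
}

# Jacobian d(optical)/d(structural) of the projective map at points (x, y)
.homography_jacobian <- function(H, x, y) {
  den <- H[3, 1] * x + H[3, 2] * y + H[3, 3]
  nx <- H[1, 1] * x + H[1, 2] * y + H[1, 3]
  ny <- H[2, 1] * x + H[2, 2] * y + H[2, 3]
  j11 <- (H[1, 1] * den - nx * H[3, 1]) / den^2
  j12 <- (H[1, 2] * den - nx * H[3, 2]) / den^2
  j21 <- (H[2, 1] * den - ny * H[3, 1]) / den^2
  j22 <- (H[2, 2] * den - ny * H[3, 2]) / den^2
  list(j11 = j11, j12 = j12, j21 = j21, j22 = j22)
}

#' Warp a map or orientation field into the optical frame
#'
#' Inverse-warps values onto the target (optical) grid: each optical pixel is
#' pulled back through `H^-1` to structural coordinates and interpolated
#' there (bilinear for scalar maps, nearest-neighbour for masks/labels).
#' Orientation fields are transformed covariantly: the axis direction is
#' rotated by the local Jacobian of the structural-to-optical map, not
#' copied, then re-folded to `[0, pi)`.
#'
#' @param x a [map_matrix] or [orientation_field] in the structural frame.
#' @param H 3x3 homography (structural -> optical) or a `cm_homography`.
#' @param target_shape `c(height, width)` of the output grid; defaults to
#'   the input shape.
#' @param interpolation `"bilinear"` or `"nearest"` (scalar maps only;
#'   orientation uses nearest sampling of the angle plus Jacobian rotation).
#' @return warped object of the same class.
#' @export
warp_map <- function(x, H, target_shape = NULL,
                     interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(H, "cm_homography")) H <- H$H
  if (abs(det(H)) < 1e-12) stopf("homography must be invertible")
  Hi <- solve(H)
  is_orient <- inherits(x, "orientation_field")
  vals <- if (is_orient) x$theta else x$values
  target_shape <- target_shape %||% dim(vals)
  ht <- target_shape[1]; wt <- target_shape[2]
  gx <- rep(seq_len(wt), each = ht)
  gy <- rep(seq_len(ht), times = wt)
  srcp <- project_points(Hi, cbind(gx, gy))
  sx <- srcp[, 1]; sy <- srcp[, 2]
  mask_src <- x$valid_mask * 1
  m_out <- nearest_sample(mask_src, sx, sy, fill = 0) >= 0.5
  if (is_orient) {
    th <- nearest_sample(x$theta, sx, sy)
    co <- nearest_sample(x$coherence, sx, sy)
    J <- .homography_jacobian(H, sx, sy)
    vx <- cos(th); vy <- sin(th)
    wx <- J$j11 * vx + J$j12 * vy
    wy <- J$j21 * vx + J$j22 * vy
    th_new <- fold_axial(atan2(wy, wx))
    ok <- m_out & is.finite(th_new)
    theta <- matrix(NA_real_, ht, wt); theta[ok] <- th_new[ok]
    coh <- matrix(NA_real_, ht, wt); coh[ok] <- co[ok]
    return(orientation_field(theta, coh, matrix(ok, ht, wt), x$pixel_pitch))
  }
  v <- if (interpolation == "bilinear") bilinear_sample(vals, sx, sy)
  else nearest_sample(vals, sx, sy)
  ok <- m_out & is.finite(v)
  out <- matrix(NA_real_, ht, wt); out[ok] <- v[ok]
  map_matrix(out, x$units, x$pixel_pitch, valid_mask = matrix(ok, ht, wt))
}

#' Outer-shell projection of a structural volume
#'
#' Cleared-heart structural data are only comparable with epicardial optical
#' maps over the outer tissue shell.  For each (x, y) column of the stack,
#' finds the first voxel along z whose intensity exceeds `threshold` (tissue
#' surface) and max-projects the next `depth_um` of voxels; columns with no
#' tissue are invalid.
#'
#' @param stack 3D numeric array `[y, x, z]`.
#' @param depth_um shell thickness in micrometres (default 100).
#' @param z_step_um z sampling step in micrometres (default 8.29).
#' @param threshold absolute intensity threshold defining tissue.
#' @param pixel_pitch xy pitch in micrometres per pixel.
#' @return a [map_matrix] (intensity).
#' @export
shell_projection <- function(stack, depth_um = 100, z_step_um = 8.29,
                             threshold = 0.1, pixel_pitch = 1.661) {
  stopifnot(length(dim(stack)) == 3L)
  nz <- dim(stack)[3]
  n_sh <- ceiling(depth_um / z_step_um)
  h <- dim(stack)[1]; w <- dim(stack)[2]
  out <- matrix(NA_real_, h, w)
  above <- stack > threshold
  first <- apply(above, c(1, 2), function(col) {
    i <- which(col)[1L]
    if (is.na(i)) NA_integer_ else i
  })
  has <- which(!is.na(first))
  for (lin in has) {
    i <- first[lin]
    zs <- i:min(nz, i + n_sh - 1L)
    yy <- ((lin - 1L) %% h) + 1L
    xx <- ((lin - 1L) %/% h) + 1L
    out[lin] <- max(stack[yy, xx, zs])
  }
  map_matrix(out, "intensity", pixel_pitch, valid_mask = !is.na(first))
}
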