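# Internal numeric helpers shared across modules.
#
# Image convention used throughout: matrices are indexed [row, col] = [y, x],
# y increasing downward, x rightward.  Angles are measured from the image +x
# axis toward +y (atan2(dy, dx)).  Axial (fiber) angles live in [0, pi).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fold an angle (radians) into the axial range [0, pi).
fold_axial <- function(theta) {
  out <- theta %% pi
  out[which(out >= pi)] <- 0   # guard against pi from floating point
  out
}

# Axial circular statistics via the double-angle transform.
# theta in radians, optional non-negative weights.
# Returns mean in [0, pi), sd (radians, axial scale), resultant length R.
axial_stats <- function(theta, w = NULL) {
  ok <- is.finite(theta)
  if (!is.null(w)) ok <- ok & is.finite(w) & w >= 0
  w <- if (is.null(w)) rep(1, sum(ok)) else w[ok]
  theta <- theta[ok]
  if (length(theta) == 0L) return(list(mean = NA_real_, sd = NA_real_, R = NA_real_))
  c2 <- sum(w * cos(2 * theta)) / sum(w)
  s2 <- sum(w * sin(2 * theta)) / sum(w)
  R <- sqrt(c2^2 + s2^2)
  mu <- fold_axial(atan2(s2, c2) / 2)
  sd <- if (R > 0) 0.5 * sqrt(pmax(-2 * log(R), 0)) else Inf
  list(mean = mu, sd = sd, R = R)
}

# Circular (directional, 2*pi-periodic) mean.
circ_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))

# Shift a matrix by (dy, dx), filling vacated cells.
shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy   # source rows
  xs <- seq_len(nc) - dx
  ok_y <- ys >= 1 & ys <= nr
  ok_x <- xs >= 1 & xs <= nc
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

gauss_kernel1d <- function(sigma_px, radius = NULL) {
  radius <- radius %||% max(1L, ceiling(3 * sigma_px))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian convolution by shift-and-add (zero padding).
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  acc <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) acc <- acc + k[i] * shift_mat(m, i - r - 1L, 0L)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(acc, 0L, i - r - 1L)
  out
}

# Mask-normalised Gaussian smoothing: ignores invalid pixels, renormalises
# by the smoothed mask so borders are unbiased.
smooth2d <- function(m, sigma_px, mask = NULL) {
  k <- gauss_kernel1d(sigma_px)
  if (is.null(mask)) return(conv_sep(m, k))
  mm <- m; mm[!mask] <- 0
  num <- conv_sep(mm, k)
  den <- conv_sep(mask * 1, k)
  out <- num / den
  out[den <= .Machine$double.eps] <- NA_real_
  out
}

# 3x3 Gaussian spatial filter (unit-sum kernel [1 2 1]/4 per axis).
gauss3x3 <- function(m, mask = NULL) {
  k <- c(1, 2, 1) / 4
  if (is.null(mask)) return(conv_sep(m, k))
  mm <- m; mm[!mask] <- 0
  num <- conv_sep(mm, k)
  den <- conv_sep(mask * 1, k)
  out <- num / den
  out[den <= .Machine$double.eps] <- NA_real_
  out
}

# Central-difference gradients (rows = y, cols = x).
grad2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- (shift_mat(m, 0, -1, NA) - shift_mat(m, 0, 1, NA)) / 2
  gy <- (shift_mat(m, -1, 0, NA) - shift_mat(m, 1, 0, NA)) / 2
  # one-sided at borders
  gx[, 1] <- m[, 2] - m[, 1];  gx[, nc] <- m[, nc] - m[, nc - 1]
  gy[1, ] <- m[2, ] - m[1, ];  gy[nr, ] <- m[nr, ] - m[nr - 1, ]
  list(gx = gx, gy = gy)
}

# Bilinear interpolation of matrix m at continuous (x, y) in 1-based pixel
# coordinates; returns NA outside the grid or where any contributing pixel
# is NA.
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= nc & y0 + 1 <= nr
  # clamp points that fall exactly on far edges
  edge <- x >= 1 & y >= 1 & x <= nc & y <= nr & !ok
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    i00 <- cbind(y0[ok], x0[ok]);     i01 <- cbind(y0[ok], x0[ok] + 1)
    i10 <- cbind(y0[ok] + 1, x0[ok]); i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
    out[ok] <- (1 - fy[ok]) * ((1 - fx[ok]) * m[i00] + fx[ok] * m[i01]) +
      fy[ok] * ((1 - fx[ok]) * m[i10] + fx[ok] * m[i11])
  }
  if (any(edge)) {
    out[edge] <- m[cbind(pmin(pmax(round(y[edge]), 1), nr),
                         pmin(pmax(round(x[edge]), 1), nc))]
  }
  out
}

# Nearest-neighbour sampling (used for masks and labels).
nearest_sample <- function(m, x, y, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  xi <- round(x); yi <- round(y)
  ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
  out <- rep(fill, length(x))
  out[ok] <- m[cbind(yi[ok], xi[ok])]
  out
}

# Linear interpolation of the first crossing of `level` in direction `dir`
# ("up": first i with x[i] < level <= x[i+1]; "down": x[i] >= level > x[i+1]).
# Returns fractional index (1-based) or NA.
first_crossing <- function(x, level, dir = c("up", "down"), from = 1L) {
  dir <- match.arg(dir)
  n <- length(x)
  if (from >= n) return(NA_real_)
  idx <- from:(n - 1L)
  if (dir == "up") hit <- x[idx] < level & x[idx + 1L] >= level
  else hit <- x[idx] >= level & x[idx + 1L] < level
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) return(NA_real_)
  i <- idx[which(hit)[1L]]
  frac <- (level - x[i]) / (x[i + 1L] - x[i])
  i + frac
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
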