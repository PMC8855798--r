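# Conduction analysis: local-plane-fit velocity vectors, tissue activation
# curves, and normalised tissue activation times from activation maps.

#' Conduction-velocity vector field from an activation map
#'
#' At each pixel, fits the plane `t(x, y) = a x + b y + c` by least squares
#' over the valid pixels of a centred square window.  The conduction velocity
#' vector is `(a, b) / (a^2 + b^2)` (px/ms), scaled by the pixel pitch to
#' mm/ms; its angle is the local propagation direction.  Pixels with fewer
#' than `min_valid_frac` valid neighbours, or an activation-time gradient
#' below `grad_floor` (conduction-block interfaces, where speed would be
#' unbounded), are masked invalid.
#'
#' @param activation_map a [map_matrix] in ms.
#' @param window_px odd window size >= 3 (default 7).
#' @param min_valid_frac minimum fraction of valid pixels in the window.
#' @param grad_floor gradient magnitude floor, ms/px.
#' @return a [vector_field] (angle in radians, speed in mm/ms).
#' @export
conduction_vectors <- function(activation_map, window_px = 7,
                               min_valid_frac = 0.6, grad_floor = 1e-3) {
  stopifnot(inherits(activation_map, "map_matrix"))
  if (window_px %% 2 != 1 || window_px < 3) stopf("window_px must be odd, >= 3")
  tmap <- activation_map$values
  mask <- activation_map$valid_mask & is.finite(tmap)
  if (window_px > min(dim(tmap))) stopf("window larger than map")
  h <- (window_px - 1L) %/% 2L
  tm <- tmap; tm[!mask] <- 0
  mk <- mask * 1

  z <- matrix(0, nrow(tmap), ncol(tmap))
  N <- z; Sx <- z; Sy <- z; Sxx <- z; Syy <- z; Sxy <- z
  St <- z; Stx <- z; Sty <- z
  for (dy in -h:h) for (dx in -h:h) {
    mshift <- shift_mat(mk, -dy, -dx)       # neighbour (dy,dx) rel. to centre
    tshift <- shift_mat(tm, -dy, -dx)
    N <- N + mshift
    Sx <- Sx + dx * mshift;  Sy <- Sy + dy * mshift
    Sxx <- Sxx + dx * dx * mshift; Syy <- Syy + dy * dy * mshift
    Sxy <- Sxy + dx * dy * mshift
    St <- St + tshift
    Stx <- Stx + dx * tshift; Sty <- Sty + dy * tshift
  }
  # solve the 3x3 normal equations per pixel (Cramer on the symmetric system)
  # [Sxx Sxy Sx; Sxy Syy Sy; Sx Sy N] [a b c]' = [Stx Sty St]'
  det3 <- Sxx * (Syy * N - Sy^2) - Sxy * (Sxy * N - Sy * Sx) +
    Sx * (Sxy * Sy - Syy * Sx)
  a <- (Stx * (Syy * N - Sy^2) - Sxy * (Sty * N - Sy * St) +
          Sx * (Sty * Sy - Syy * St)) / det3
  b <- (Sxx * (Sty * N - Sy * St) - Stx * (Sxy * N - Sy * Sx) +
          Sx * (Sxy * St - Sty * Sx)) / det3
  g2 <- a^2 + b^2
  ok <- mask & N >= min_valid_frac * window_px^2 & abs(det3) > 1e-9 &
    is.finite(g2) & sqrt(g2) > grad_floor
  speed <- matrix(NA_real_, nrow(tmap), ncol(tmap))
  angle <- matrix(NA_real_, nrow(tmap), ncol(tmap))
  speed[ok] <- (1 / sqrt(g2[ok])) * activation_map$pixel_pitch / 1000
  angle[ok] <- atan2(b[ok], a[ok]) %% (2 * pi)
  vector_field(angle, speed, valid_mask = ok,
               pixel_pitch = activation_map$pixel_pitch)
}

#' Tissue activation curve
#'
#' Cumulative fraction of ROI pixels activated by time t, on a uniform time
#' grid.  Isotropic conduction gives a smooth sigmoid-like rise; anisotropic
#' conduction and conduction block flatten and stage the curve.
#'
#' @param activation_map a [map_matrix] in ms.
#' @param roi_mask logical matrix; defaults to all valid pixels.
#' @param time_step grid step in ms.
#' @return tibble of class `activation_curve` with columns `time`,
#'   `fraction_activated`.
#' @export
activation_curve <- function(activation_map, roi_mask = NULL, time_step = 0.5) {
  stopifnot(inherits(activation_map, "map_matrix"))
  roi_mask <- roi_mask %||% activation_map$valid_mask
  times <- activation_map$values[roi_mask & activation_map$valid_mask]
  times <- times[is.finite(times)]
  if (length(times) == 0L) stopf("empty ROI")
  grid <- seq(floor(min(times)), max(times) + time_step, by = time_step)
  frac <- vapply(grid, function(t) mean(times <= t), numeric(1))
  out <- tibble::tibble(time = grid, fraction_activated = frac)
  class(out) <- c("activation_curve", class(out))
  out
}

#' Normalised tissue activation time of an ROI
#'
#' Spread of ROI activation times between the `lo` and `hi` quantiles,
#' optionally normalised by the square root of the ROI area so that
#' same-shaped regions of different size are comparable (units ms/mm).
#'
#' @param activation_map a [map_matrix] in ms.
#' @param roi_mask logical matrix.
#' @param lo,hi quantiles (defaults 0.10 and 0.90).
#' @param normalize `"sqrt_area"` (divide by sqrt of ROI area in mm^2) or
#'   `"none"` (raw quantile spread, ms).
#' @return a single number.
#' @export
tissue_activation_time <- function(activation_map, roi_mask, lo = 0.10,
                                   hi = 0.90,
                                   normalize = c("sqrt_area", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(activation_map, "map_matrix"))
  ok <- roi_mask & activation_map$valid_mask
  times <- activation_map$values[ok]
  times <- times[is.finite(times)]
  if (length(times) < 20L) stopf("ROI must contain at least 20 valid pixels")
  qs <- stats::quantile(times, c(lo, hi), names = FALSE, type = 7)
  spread <- qs[2] - qs[1]
  if (normalize == "none") return(spread)
  area_mm2 <- sum(ok) * (activation_map$pixel_pitch / 1000)^2
  spread / sqrt(area_mm2)
}
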