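#' Scalar map container
#'
#' A 2D scalar field (activation time, APD, intensity, similarity, ...) with a
#' validity mask and physical pixel pitch.  Matrices are indexed
#' `[row = y, col = x]` with y increasing downward.
#'
#' @param values numeric matrix.
#' @param units one of `"ms"`, `"dimensionless"`, `"intensity"`.
#' @param pixel_pitch pixel size in micrometres per pixel.
#' @param valid_mask logical matrix of the same shape; defaults to finite
#'   entries of `values`.
#' @return an object of class `map_matrix`.
#' @export
map_matrix <- function(values, units = c("ms", "dimensionless", "intensity"),
                       pixel_pitch = 55, valid_mask = NULL) {
  units <- match.arg(units)
  stopifnot(is.matrix(values))
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  stopifnot(identical(dim(values), dim(valid_mask)))
  values[!valid_mask] <- NA_real_
  structure(list(values = values, units = units,
                 valid_mask = valid_mask, pixel_pitch = pixel_pitch),
            class = "map_matrix")
}

#' @export
print.map_matrix <- function(x, ...) {
  cat(sprintf("<map_matrix> %d x %d px, %s, pitch %.3g um/px, %d valid px\n",
              nrow(x$values), ncol(x$values), x$units, x$pixel_pitch,
              sum(x$valid_mask)))
  rng <- range(x$values[x$valid_mask])
  if (any(x$valid_mask)) cat(sprintf("  range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
as_tibble.map_matrix <- function(x, ...) {
  d <- dim(x$values)
  value <- as.vector(x$values)
  valid <- as.vector(x$valid_mask)
  tibble::tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), times = d[2]),
    value = value, valid = valid
  )
}

#' Voltage movie container
#'
#' @param frames numeric 3D array `[time, y, x]` of normalised fluorescence.
#' @param sampling_rate sampling rate in kHz.
#' @param valid_mask logical y-by-x matrix.
#' @param pixel_pitch micrometres per pixel.
#' @return an object of class `voltage_movie`.
#' @export
voltage_movie <- function(frames, sampling_rate = 1.03, valid_mask = NULL,
                          pixel_pitch = 55) {
  stopifnot(length(dim(frames)) == 3L)
  if (sampling_rate <= 0) stopf("sampling_rate must be positive")
  if (dim(frames)[1] < 3L) stopf("movie needs at least 3 frames")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, dim(frames)[2], dim(frames)[3])
  structure(list(frames = frames, sampling_rate = sampling_rate,
                 valid_mask = valid_mask, pixel_pitch = pixel_pitch),
            class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<voltage_movie> %d frames of %d x %d px @ %.3g kHz (%.1f ms)\n",
              d[1], d[2], d[3], x$sampling_rate, d[1] / x$sampling_rate))
  invisible(x)
}

# time axis of a movie in ms (frame 1 at t = 0)
movie_time <- function(movie) (seq_len(dim(movie$frames)[1]) - 1L) / movie$sampling_rate

#' Axial orientation field container
#'
#' Per-pixel fiber-axis angle in `[0, pi)` (axial: theta and theta + pi are the
#' same axis), with a coherence map in `[0, 1]`.
#'
#' @param theta numeric matrix of angles in radians, `[0, pi)`.
#' @param coherence numeric matrix in `[0, 1]`.
#' @param valid_mask logical matrix.
#' @param pixel_pitch micrometres per pixel.
#' @return an object of class `orientation_field`.
#' @export
orientation_field <- function(theta, coherence = NULL, valid_mask = NULL,
                              pixel_pitch = 1.661) {
  stopifnot(is.matrix(theta))
  if (is.null(valid_mask)) valid_mask <- is.finite(theta)
  if (is.null(coherence)) coherence <- matrix(1, nrow(theta), ncol(theta))
  theta <- fold_axial(theta)
  theta[!valid_mask] <- NA_real_
  coherence[!valid_mask] <- NA_real_
  structure(list(theta = theta, coherence = coherence,
                 valid_mask = valid_mask, pixel_pitch = pixel_pitch),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %d x %d px, pitch %.3g um/px, %d valid px\n",
              nrow(x$theta), ncol(x$theta), x$pixel_pitch, sum(x$valid_mask)))
  invisible(x)
}

#' Conduction vector field container
#'
#' @param angle matrix of propagation directions in radians, `[0, 2*pi)`,
#'   measured from the image +x axis.
#' @param speed matrix of conduction speeds in mm/ms.
#' @param valid_mask logical matrix.
#' @param pixel_pitch micrometres per pixel.
#' @return an object of class `vector_field`.
#' @export
vector_field <- function(angle, speed, valid_mask = NULL, pixel_pitch = 55) {
  stopifnot(identical(dim(angle), dim(speed)))
  if (is.null(valid_mask)) valid_mask <- is.finite(angle) & is.finite(speed)
  angle <- angle %% (2 * pi)
  angle[!valid_mask] <- NA_real_
  speed[!valid_mask] <- NA_real_
  structure(list(angle = angle, speed = speed, valid_mask = valid_mask,
                 pixel_pitch = pixel_pitch),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %d x %d px, %d valid px", nrow(x$angle),
              ncol(x$angle), sum(x$valid_mask)))
  if (any(x$valid_mask))
    cat(sprintf(", median speed %.3g mm/ms", stats::median(x$speed[x$valid_mask])))
  cat("\n")
  invisible(x)
}

#' @export
as_tibble.vector_field <- function(x, ...) {
  d <- dim(x$angle)
  angle <- as.vector(x$angle)
  speed <- as.vector(x$speed)
  valid <- as.vector(x$valid_mask)
  tibble::tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), times = d[2]),
    angle = angle, speed = speed, valid = valid
  )
}

#' @export
as_tibble.orientation_field <- function(x, ...) {
  d <- dim(x$theta)
  theta <- as.vector(x$theta)
  coherence <- as.vector(x$coherence)
  valid <- as.vector(x$valid_mask)
  tibble::tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), times = d[2]),
    theta = theta, coherence = coherence, valid = valid
  )
}

#' Hypothesis-test result record
#'
#' Uniform return type for the package's statistical tests, with [tidy()] and
#' [glance()] methods.
#'
#' @param statistic numeric test statistic.
#' @param p_value p-value in (0, 1].
#' @param method character method name.
#' @param n sample size(s).
#' @param exact logical; TRUE when the p-value comes from full enumeration.
#' @param seed seed used for any permutation, or NULL.
#' @param extra named list of additional fields.
#' @return an object of class `cm_test`.
#' @export
cm_test <- function(statistic, p_value, method, n, exact = FALSE,
                    seed = NULL, extra = list()) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method,
                   n = n, exact = exact, seed = seed), extra),
            class = "cm_test")
}

#' @export
print.cm_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.6g, p = %.6g (%s), n = %s\n",
              x$method, x$statistic, x$p_value,
              if (isTRUE(x$exact)) "exact" else "approximate",
              paste(x$n, collapse = ", ")))
  invisible(x)
}
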