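# Optical-signal processing: voltage movies -> activation, APD80, delta-APD
# maps.  Conventions follow panoramic optical mapping practice: activation
# from the maximum upstroke derivative or the depolarisation midpoint, APD
# measured from the depolarisation midpoint to a fractional repolarisation
# level, flat/failed pixels masked invalid rather than raising.

# running min/max over a centred window of w samples (columns are pixels)
run_extreme <- function(m, w, which = c("min", "max")) {
  which <- match.arg(which)
  r <- (w - 1L) %/% 2L
  out <- m
  f <- if (which == "min") pmin else pmax
  for (k in seq_len(r)) {
    out <- f(out, shift_mat(m, k, 0, if (which == "min") Inf else -Inf),
             shift_mat(m, -k, 0, if (which == "min") Inf else -Inf))
  }
  out
}

#' Preprocess a voltage movie
#'
#' Applies, in order: a per-frame 3x3 Gaussian spatial filter, a per-pixel
#' morphological top-hat baseline correction (signal minus its greyscale
#' opening over a temporal window), and per-pixel Savitzky-Golay temporal
#' smoothing.  This is the standard drift-and-noise correction chain for
#' optical action potentials.
#'
#' @param movie a [voltage_movie].
#' @param spatial logical; apply the 3x3 Gaussian spatial filter.
#' @param tophat_window_ms top-hat structuring-element length, ms (must be
#'   longer than the APD to preserve the AP; default 100 ms).
#' @param sg_window SG window length in samples (odd; default 9).
#' @param sg_order SG polynomial order (default 3).
#' @return a [voltage_movie] with the same mask and sampling rate.
#' @export
preprocess <- function(movie, spatial = TRUE, tophat_window_ms = 100,
                       sg_window = 9, sg_order = 3) {
  stopifnot(inherits(movie, "voltage_movie"))
  d <- dim(movie$frames)
  nt <- d[1]
  w_th <- round(tophat_window_ms * movie$sampling_rate)
  if (w_th %% 2 == 0) w_th <- w_th + 1L
  if (w_th >= nt) stopf("top-hat window (%d samples) longer than trace (%d)",
                        w_th, nt)
  if (sg_window >= nt) stopf("SG window longer than trace")
  if (sg_window %% 2 == 0) stopf("sg_window must be odd")

  x <- movie$frames
  if (spatial) {
    for (t in seq_len(nt)) x[t, , ] <- gauss3x3(matrix(x[t, , ], d[2], d[3]))
  }
  m <- matrix(x, nt, d[2] * d[3])
  # greyscale top-hat: x - opening(x); removes slow baseline, keeps the AP
  er <- run_extreme(m, w_th, "min")
  op <- run_extreme(er, w_th, "max")
  m <- m - op
  m <- apply(m, 2, function(col) signal::sgolayfilt(col, p = sg_order,
                                                    n = sg_window))
  out <- array(m, dim = d)
  voltage_movie(out, movie$sampling_rate, movie$valid_mask, movie$pixel_pitch)
}

#' Activation time of a single optical trace
#'
#' @param trace numeric vector (one pixel's fluorescence).
#' @param time time axis in ms (same length); defaults to samples at
#'   `sampling_rate`.
#' @param method `"dvdt_max"` (time of maximum first difference; ties broken
#'   earliest) or `"midpoint"` (first linearly interpolated crossing of 50%
#'   of the min-to-max amplitude).
#' @param sampling_rate kHz, used when `time` is missing.
#' @param min_amplitude traces with min-to-max range below this are declared
#'   flat and return `NA` (invalid pixel) rather than erroring.
#' @return activation time in ms, or `NA` for a flat trace.
#' @export
activation_time <- function(trace, time = NULL, method = c("dvdt_max", "midpoint"),
                            sampling_rate = 1.03, min_amplitude = 0) {
  method <- match.arg(method)
  time <- time %||% ((seq_along(trace) - 1L) / sampling_rate)
  rng <- range(trace, na.rm = TRUE)
  if (!all(is.finite(rng)) || diff(rng) <= min_amplitude) return(NA_real_)
  if (method == "dvdt_max") {
    dv <- diff(trace) / diff(time)
    # earliest tie, robust to floating-point noise among equal slopes
    tol <- 1e-9 * max(abs(dv), na.rm = TRUE)
    i <- which(dv >= max(dv, na.rm = TRUE) - tol)[1L]
    return((time[i] + time[i + 1L]) / 2)
  }
  level <- rng[1] + 0.5 * diff(rng)
  ci <- first_crossing(trace, level, "up")
  if (is.na(ci)) return(NA_real_)
  i <- floor(ci)
  time[i] + (ci - i) * (time[i + 1L] - time[i])
}

#' Action potential duration of a single optical trace
#'
#' Time from activation (depolarisation midpoint by default) to the first
#' subsequent interpolated crossing of `(1 - level)` of the min-to-max
#' amplitude; `level = 0.8` gives APD80.
#'
#' @inheritParams activation_time
#' @param level repolarisation fraction in (0, 1).
#' @param anchor activation reference: `"midpoint"` or `"dvdt_max"`.
#' @return APD in ms, or `NA` when flat or when repolarisation is not reached
#'   before the end of the trace.
#' @export
apd <- function(trace, time = NULL, level = 0.8,
                anchor = c("midpoint", "dvdt_max"),
                sampling_rate = 1.03, min_amplitude = 0) {
  anchor <- match.arg(anchor)
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  time <- time %||% ((seq_along(trace) - 1L) / sampling_rate)
  t_act <- activation_time(trace, time, method = anchor,
                           min_amplitude = min_amplitude)
  if (is.na(t_act)) return(NA_real_)
  rng <- range(trace, na.rm = TRUE)
  thr <- rng[1] + (1 - level) * diff(rng)
  i0 <- max(1L, which(time >= t_act)[1L])
  ci <- first_crossing(trace, thr, "down", from = i0)
  if (is.na(ci)) return(NA_real_)
  i <- floor(ci)
  t_cross <- time[i] + (ci - i) * (time[i + 1L] - time[i])
  t_cross - t_act
}

# shared per-pixel map driver
.pixel_map <- function(movie, fun, rel_amplitude = 0.05) {
  d <- dim(movie$frames)
  m <- matrix(movie$frames, d[1], d[2] * d[3])
  tgrid <- movie_time(movie)
  rngs <- apply(m, 2, function(col) diff(range(col)))
  min_amp <- rel_amplitude * max(rngs, na.rm = TRUE)
  vals <- rep(NA_real_, ncol(m))
  todo <- which(as.vector(movie$valid_mask) & rngs > min_amp)
  for (j in todo) vals[j] <- fun(m[, j], tgrid)
  matrix(vals, d[2], d[3])
}

#' Activation map from a voltage movie
#'
#' Per-pixel [activation_time()]; pixels that are flat (min-to-max range
#' below `rel_amplitude` of the movie-wide maximum range) or outside the
#' movie's validity mask are invalid.  The relative amplitude criterion makes
#' the map invariant to global gain.
#'
#' @param movie a [voltage_movie].
#' @param method passed to [activation_time()].
#' @param rel_amplitude relative flatness threshold.
#' @return a [map_matrix] in ms.
#' @export
activation_map <- function(movie, method = c("dvdt_max", "midpoint"),
                           rel_amplitude = 0.05) {
  method <- match.arg(method)
  vals <- .pixel_map(movie, function(tr, tt)
    activation_time(tr, tt, method = method), rel_amplitude)
  map_matrix(vals, "ms", movie$pixel_pitch)
}

#' APD map from a voltage movie
#'
#' Per-pixel [apd()]; invalid-pixel policy as in [activation_map()].
#'
#' @inheritParams activation_map
#' @param level repolarisation fraction (0.8 for APD80).
#' @param anchor activation reference for the APD interval.
#' @return a [map_matrix] in ms.
#' @export
apd_map <- function(movie, level = 0.8, anchor = c("midpoint", "dvdt_max"),
                    rel_amplitude = 0.05) {
  anchor <- match.arg(anchor)
  vals <- .pixel_map(movie, function(tr, tt)
    apd(tr, tt, level = level, anchor = anchor), rel_amplitude)
  map_matrix(vals, "ms", movie$pixel_pitch)
}

#' Average time-aligned beats of a movie
#'
#' Extracts a fixed-length window after each listed beat onset and averages
#' them per pixel; beats must share a cycle length so the windows align.
#'
#' @param movie a [voltage_movie].
#' @param beat_times onset times (ms) of each beat window.
#' @param n_beats minimum number of beats required (default 4).
#' @param window_ms window length; defaults to the shortest inter-beat
#'   interval.
#' @return a [voltage_movie] holding the averaged beat.
#' @export
beat_average <- function(movie, beat_times, n_beats = 4, window_ms = NULL) {
  stopifnot(inherits(movie, "voltage_movie"))
  if (length(beat_times) < n_beats)
    stopf("need at least %d beats, got %d", n_beats, length(beat_times))
  window_ms <- window_ms %||% min(diff(sort(beat_times)))
  nw <- floor(window_ms * movie$sampling_rate)
  if (nw < 3) stopf("beat window too short")
  tgrid <- movie_time(movie)
  d <- dim(movie$frames)
  acc <- array(0, dim = c(nw, d[2], d[3]))
  for (bt in beat_times) {
    i0 <- which(tgrid >= bt)[1L]
    if (is.na(i0) || i0 + nw - 1L > d[1])
      stopf("beat window at %.1f ms extends beyond the recording", bt)
    acc <- acc + movie$frames[i0:(i0 + nw - 1L), , , drop = FALSE]
  }
  voltage_movie(acc / length(beat_times), movie$sampling_rate,
                movie$valid_mask, movie$pixel_pitch)
}

#' Difference of two APD maps
#'
#' `after - before` on the intersection of the validity masks; use for
#' drug-response (e.g. tyramine) delta-APD80 maps compared at the same cycle
#' length.
#'
#' @param apd_before,apd_after [map_matrix] objects of identical shape.
#' @return a [map_matrix] in ms.
#' @export
delta_apd_map <- function(apd_before, apd_after) {
  stopifnot(inherits(apd_before, "map_matrix"), inherits(apd_after, "map_matrix"))
  if (!identical(dim(apd_before$values), dim(apd_after$values)))
    stopf("APD maps must have the same shape")
  mask <- apd_before$valid_mask & apd_after$valid_mask
  if (!any(mask)) warnf("delta-APD map has no jointly valid pixels")
  vals <- apd_after$values - apd_before$values
  vals[!mask] <- NA_real_
  map_matrix(vals, "ms", apd_before$pixel_pitch, valid_mask = mask)
}
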