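#' Synthesise an optical action-potential movie
#'
#' Builds a per-pixel voltage trace from an activation map and an APD map:
#' a sigmoidal upstroke centred at the activation time (time constant
#' `upstroke_tau`), multiplied by a plateau-then-fall repolarisation
#' `exp(-log(5) * (s / APD)^3)` that reaches 20% of amplitude exactly APD ms
#' after the upstroke midpoint.  Amplitude is normalised to 1; optional
#' additive Gaussian noise.  Deterministic per seed.
#'
#' @param activation_map [map_matrix] of activation times (ms).
#' @param apd_map [map_matrix] of APD (ms), positive on valid pixels, or a
#'   single number recycled over the frame.
#' @param sampling_rate kHz (1.03 matches the reference acquisition).
#' @param upstroke_tau sigmoid time constant, ms.
#' @param noise_sd additive Gaussian noise SD (amplitude units).
#' @param seed integer seed.
#' @param pre_ms quiescent baseline before the earliest upstroke, ms.
#' @param post_ms recording continued after the latest repolarisation, ms.
#' @return a [voltage_movie].
#' @export
make_ap_movie <- function(activation_map, apd_map, sampling_rate = 1.03,
                          upstroke_tau = 1, noise_sd = 0, seed = 1,
                          pre_ms = 15, post_ms = 40) {
  stopifnot(inherits(activation_map, "map_matrix"))
  if (sampling_rate <= 0) stopf("sampling_rate must be positive")
  act <- activation_map$values
  if (is.numeric(apd_map) && length(apd_map) == 1L) {
    apd <- matrix(apd_map, nrow(act), ncol(act))
  } else {
    stopifnot(inherits(apd_map, "map_matrix"))
    apd <- apd_map$values
  }
  valid <- activation_map$valid_mask & is.finite(apd)
  if (any(apd[valid] <= 0)) stopf("apd_map must be positive on valid pixels")

  t_end <- max(act[valid]) + max(apd[valid]) + post_ms
  tgrid <- seq(0, t_end + pre_ms, by = 1 / sampling_rate)
  nt <- length(tgrid)
  h <- nrow(act); w <- ncol(act)
  frames <- array(0, dim = c(nt, h, w))
  vi <- which(valid)
  t_act <- act[vi] + pre_ms
  apd_v <- apd[vi]
  # trace matrix: time x pixel
  tm <- outer(tgrid, t_act, "-")                        # t - t_act
  up <- 1 / (1 + exp(-tm / upstroke_tau))
  s <- pmax(tm, 0)
  repol <- exp(-log(5) * sweep(s, 2, apd_v, "/")^3)
  traces <- up * repol
  if (noise_sd > 0) {
    traces <- with_seed(seed, traces + stats::rnorm(length(traces), 0, noise_sd))
  }
  flat <- matrix(0, nt, h * w)
  if (noise_sd > 0) {
    flat <- with_seed(seed + 1L,
                      matrix(stats::rnorm(nt * h * w, 0, noise_sd), nt, h * w))
  }
  flat[, vi] <- traces
  frames[] <- flat
  voltage_movie(frames, sampling_rate = sampling_rate, valid_mask = valid,
                pixel_pitch = activation_map$pixel_pitch)
}
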