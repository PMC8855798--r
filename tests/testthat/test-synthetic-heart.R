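# Phantom generator: determinism, fiber-field structure, eikonal activation,
# AP movies, vessel scenes, nerve renderings.

test_that("phantoms are deterministic per seed and masks are consistent", {
  p1 <- make_phantom(48, 48, pixel_pitch = 110, disorder_level = 0.5,
                     scar_radius_um = 900, bz_width_um = 300, seed = 7)
  p2 <- make_phantom(48, 48, pixel_pitch = 110, disorder_level = 0.5,
                     scar_radius_um = 900, bz_width_um = 300, seed = 7)
  expect_identical(p1$fiber_angle, p2$fiber_angle)
  expect_identical(p1$autofluorescence$values, p2$autofluorescence$values)
  p3 <- make_phantom(48, 48, pixel_pitch = 110, disorder_level = 0.5,
                     scar_radius_um = 900, bz_width_um = 300, seed = 8)
  expect_false(identical(p1$fiber_angle, p3$fiber_angle))
  # invariants: scar inside tissue, BZ disjoint from scar, angles axial
  expect_true(all(p1$tissue_mask[p1$scar_mask]))
  expect_false(any(p1$bz_mask & p1$scar_mask))
  th <- p1$fiber_angle[!is.na(p1$fiber_angle)]
  expect_true(all(th >= 0 & th < pi))
  expect_error(make_phantom(0, 32), "positive")
  expect_error(make_phantom(32, 32, pixel_pitch = 110, scar_radius_um = 5000),
               "scar")
})

test_that("disorder-free fields are noise-free; BZ dispersion grows with disorder", {
  p0 <- make_phantom(64, 64, disorder_level = 0, seed = 3)
  # with zero disorder the field is the smooth harmonic: tiny local variance
  th <- p0$fiber_angle
  ok <- !is.na(th[2:63, 2:63]) & !is.na(th[1:62, 2:63])
  d <- abs(th[2:63, 2:63] - th[1:62, 2:63])[ok]
  expect_lt(max(pmin(d, pi - d)), 0.1)

  sd_at <- function(dl) {
    p <- make_phantom(128, 128, pixel_pitch = 110, disorder_level = dl,
                      scar_radius_um = 2500, bz_width_um = 1500, seed = 11)
    pb <- make_phantom(128, 128, pixel_pitch = 110, disorder_level = 0,
                       scar_radius_um = 2500, bz_width_um = 1500, seed = 11)
    idx <- which(p$bz_mask & !is.na(p$fiber_angle))
    expect_gt(length(idx), 1e3)
    # circular SD of the axial jitter (residual from the known smooth base)
    resid <- p$fiber_angle[idx] - pb$fiber_angle[idx]
    cardiomapr:::axial_stats(resid)$sd
  }
  expect_gt(sd_at(0.8), sd_at(0.1))
})

test_that("isotropic activation reproduces euclidean travel time within 3%", {
  p <- make_phantom(64, 64, pixel_pitch = 110, disorder_level = 0, seed = 2)
  act <- simulate_activation(p, 0.4, 0.4, c(20, 27))
  xs <- matrix(rep(1:64, each = 64), 64, 64)
  ys <- matrix(rep(1:64, 64), 64, 64)
  d_mm <- sqrt((xs - 20)^2 + (ys - 27)^2) * 110 / 1000
  sel <- act$valid_mask & d_mm > 3 * 110 / 1000
  rel <- abs(act$values[sel] - d_mm[sel] / 0.4) / (d_mm[sel] / 0.4)
  expect_lt(max(rel), 0.03)
})

test_that("uniform fibers give anisotropic travel times, exact along the axis", {
  p <- make_phantom(64, 64, pixel_pitch = 110, disorder_level = 0, seed = 2)
  p$fiber_angle[] <- 0
  act <- simulate_activation(p, 0.5, 0.2, c(20, 32))
  # along the fiber axis (0 degrees = +x): t = d / speed_along, exact up to
  # stencil metrication
  d_px <- 20
  t_along <- act$values[32, 20 + d_px]
  expect_lt(abs(t_along - d_px * 0.11 / 0.5) / (d_px * 0.11 / 0.5), 0.03)
  # across the axis propagation is substantially slower (the graph metric
  # allows oblique zigzag paths, so d/speed_across is an upper bound)
  t_across <- act$values[32 + d_px, 20]
  expect_gt(t_across, 1.5 * t_along)
  expect_lte(t_across, d_px * 0.11 / 0.2 * 1.001)
  expect_error(simulate_activation(p, 0.1, 0.2), "speed_along >= speed_across")
})

test_that("a blocking scar delays arrival beyond the no-scar time", {
  p0 <- make_phantom(64, 64, pixel_pitch = 110, disorder_level = 0, seed = 5)
  p1 <- make_phantom(64, 64, pixel_pitch = 110, disorder_level = 0,
                     scar_radius_um = 900, bz_width_um = 200, seed = 5)
  src <- c(32, 14)
  a0 <- simulate_activation(p0, 0.4, 0.4, src)
  a1 <- simulate_activation(p1, 0.4, 0.4, src)
  # far pixel on the other side of the scar disk
  far <- c(32, 56)
  expect_gt(a1$values[far[2], far[1]], a0$values[far[2], far[1]] * 1.05)
  expect_error(simulate_activation(p1, 0.4, 0.4, round(p1$scar_center)),
               "scar")
  # eikonal monotonicity: activation nondecreasing along time-sorted pixels
  expect_true(all(diff(sort(a1$values[a1$valid_mask])) >= 0))
})

test_that("noise-free movies return the generator maps within one sample", {
  p <- make_phantom(40, 40, pixel_pitch = 110, disorder_level = 0, seed = 2)
  act <- simulate_activation(p, 0.4, 0.2, c(13, 17))
  mov <- make_ap_movie(act, 60, noise_sd = 0, seed = 1, pre_ms = 15)
  samp <- 1 / mov$sampling_rate
  am <- activation_map(mov, "midpoint")
  err <- abs((am$values - 15) - act$values)
  expect_lt(max(err, na.rm = TRUE), samp)
  ap <- apd_map(mov, 0.8)
  expect_lt(max(abs(ap$values - 60), na.rm = TRUE), samp)
  expect_error(make_ap_movie(act, 60, sampling_rate = 0), "positive")
  expect_error(make_ap_movie(act, -5), "positive")
})

test_that("noisy movies still recover APD to a couple of ms", {
  p <- make_phantom(40, 40, pixel_pitch = 110, disorder_level = 0, seed = 2)
  act <- simulate_activation(p, 0.4, 0.2, c(13, 17))
  mov <- make_ap_movie(act, 50, noise_sd = 0.05, seed = 4)
  movf <- preprocess(mov, spatial = FALSE, tophat_window_ms = 80)
  ap <- apd_map(movf, 0.8)
  err <- abs(ap$values - 50)
  expect_gt(sum(is.finite(err)), 1e3)
  expect_lt(median(err, na.rm = TRUE), 2)
})

test_that("vessel scenes give exact registration without jitter", {
  p <- make_phantom(96, 96, seed = 4)
  vt0 <- make_vessel_tree(p, diag(3), n_points = 8, jitter_sd = 0, seed = 3)
  expect_identical(vt0$optical$values, vt0$structural$values)
  vt <- make_vessel_tree(p, H_example, n_points = 8, jitter_sd = 0, seed = 3)
  fit <- fit_homography(vt$fiducials)
  expect_lt(max(fit$residuals$residual_px), 1e-6)
  expect_lt(max(abs(fit$H / fit$H[3, 3] - H_example / H_example[3, 3])), 1e-6)
  expect_error(make_vessel_tree(p, diag(3), n_points = 3), "at least 4")
  expect_error(make_vessel_tree(p, matrix(0, 3, 3)), "invertible")
})

test_that("jittered fiducials refit within 2 px RMS over many seeds", {
  p <- make_phantom(96, 96, seed = 4)
  rms <- vapply(1:100, function(s) {
    v <- make_vessel_tree(p, H_example, n_points = 8, jitter_sd = 1, seed = s)
    fit_homography(v$fiducials)$rmse
  }, numeric(1))
  expect_lte(sqrt(mean(rms^2)), 2)
})

test_that("nerve renderings carry exact per-bin truth", {
  empty <- make_nerve_image(NULL, background_sd = 0, seed = 1)
  expect_equal(sum(empty$image$values), 0)
  expect_equal(sum(empty$truth$length_um), 0)

  one <- make_nerve_image(tube_spec(1, 5, 20, 105, 20, 4),
                          background_sd = 0, seed = 1,
                          width_um = 115, height_um = 40)
  expect_equal(one$truth$length_um[one$truth$bin == "medium"], 100)
  expect_equal(sum(one$truth$length_um[one$truth$bin != "medium"]), 0)

  set.seed(42)
  specs <- dplyr::bind_rows(lapply(1:20, function(i) {
    tube_spec(i, runif(1, 5, 60), runif(1, 5, 60),
              runif(1, 60, 115), runif(1, 60, 115),
              runif(1, 1.3, 8))
  }))
  many <- make_nerve_image(specs, background_sd = 0, seed = 1,
                           width_um = 120, height_um = 120)
  total_drawn <- sum(vapply(split(specs, specs$fiber), function(f)
    sum(sqrt(diff(f$x_um)^2 + diff(f$y_um)^2)), numeric(1)))
  expect_equal(sum(many$truth$length_um), total_drawn, tolerance = 1e-12)

  expect_warning(
    thin <- make_nerve_image(tube_spec(1, 5, 10, 40, 10, 1.0),
                             background_sd = 0, seed = 1),
    "floor")
  expect_equal(thin$flagged, "1")
})
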