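# Trace-level estimators and the movie preprocessing chain.

test_that("activation time finds sigmoid centres by both conventions", {
  t <- seq(0, 40, by = 1 / 1.03)
  tr <- sigmoid_trace(t, t_act = 5, apd = 100, tau = 1)
  expect_lt(abs(activation_time(tr, t, "dvdt_max") - 5), 1 / 1.03)
  expect_lt(abs(activation_time(tr, t, "midpoint") - 5), 0.1 / 1.03)
})

test_that("dvdt ties resolve to the earliest sample on a monotone ramp", {
  t <- seq(0, 10, by = 1)
  tr <- t / 10
  expect_lte(activation_time(tr, t, "dvdt_max"), 0.5)
})

test_that("flat traces are marked invalid, not errors", {
  t <- seq(0, 20, by = 1)
  expect_true(is.na(activation_time(rep(1, 21), t)))
  expect_true(is.na(apd(rep(0.5, 21), t)))
  expect_true(is.na(activation_time(seq(0, 0.01, length.out = 21), t,
                                    min_amplitude = 0.05)))
})

test_that("apd matches closed forms for pulse shapes", {
  t <- seq(0, 120, by = 0.25)
  # square pulse of width 50 ms
  sq <- as.numeric(t >= 10 & t < 60)
  expect_lt(abs(apd(sq, t, 0.8) - 50), 0.25 + 1e-9)
  # 20 ms plateau then linear fall over 40 ms: APD80 = 20 + 0.8*40 = 52
  tr <- ifelse(t < 10, 0, ifelse(t < 30, 1, pmax(0, 1 - (t - 30) / 40)))
  expect_lt(abs(apd(tr, t, 0.8) - 52), 0.25 + 1e-9)
  # no repolarisation before end of trace -> invalid
  expect_true(is.na(apd(ifelse(t > 10, 1, 0), t)))
  expect_error(apd(sq, t, level = 1.2), "level")
})

test_that("estimators are invariant to affine trace rescaling", {
  t <- seq(0, 80, by = 1 / 1.03)
  tr <- sigmoid_trace(t, t_act = 12, apd = 45)
  for (g in c(0.2, 5)) for (o in c(-3, 7)) {
    expect_equal(activation_time(g * tr + o, t, "midpoint"),
                 activation_time(tr, t, "midpoint"), tolerance = 1e-9)
    expect_equal(apd(g * tr + o, t), apd(tr, t), tolerance = 1e-9)
  }
})

test_that("midpoint and dvdt activation agree within the upstroke timescale", {
  t <- seq(0, 60, by = 1 / 1.03)
  for (tau in c(0.5, 1, 2)) {
    tr <- sigmoid_trace(t, t_act = 15, apd = 40, tau = tau)
    d <- abs(activation_time(tr, t, "midpoint") -
               activation_time(tr, t, "dvdt_max"))
    expect_lt(d, tau + 1 / 1.03)
  }
})

test_that("preprocess removes linear drift and attenuates noise", {
  nt <- 400
  tgrid <- (seq_len(nt) - 1) / 1.03
  ap <- sigmoid_trace(tgrid, t_act = 150, apd = 50)
  drift <- 0.004 * tgrid
  frames <- array(0, dim = c(nt, 3, 3))
  for (i in 1:3) for (j in 1:3) frames[, i, j] <- ap + drift
  mov <- voltage_movie(frames, 1.03)
  out <- preprocess(mov, spatial = FALSE, tophat_window_ms = 120)
  # baseline (pre-upstroke samples) should sit near zero after top-hat
  base <- out$frames[1:100, 2, 2]
  expect_lt(abs(mean(base)), 0.01)

  set.seed(1)
  noise <- array(rnorm(nt * 9, 0, 0.1), dim = c(nt, 3, 3))
  outn <- preprocess(voltage_movie(noise, 1.03), spatial = FALSE,
                     tophat_window_ms = 120, sg_window = 9, sg_order = 3)
  expect_lt(sd(outn$frames[150:250, 2, 2]), 0.1)

  expect_error(preprocess(mov, tophat_window_ms = 1000), "longer")
})

test_that("constant movies survive preprocessing up to baseline removal", {
  frames <- array(0.7, dim = c(200, 2, 2))
  out <- preprocess(voltage_movie(frames, 1.03), tophat_window_ms = 50)
  expect_lt(max(abs(out$frames)), 1e-9)
})

test_that("beat averaging reduces noise and validates windows", {
  # 1 kHz sampling so a 110 ms cycle length aligns exactly on samples
  nt <- 480
  tgrid <- seq_len(nt) - 1
  cl <- 110
  beat <- sigmoid_trace(tgrid %% cl, t_act = 20, apd = 40)
  set.seed(2)
  frames <- array(0, dim = c(nt, 2, 2))
  for (i in 1:2) for (j in 1:2)
    frames[, i, j] <- beat + rnorm(nt, 0, 0.1)
  mov <- voltage_movie(frames, 1.0)
  onsets <- c(0, cl, 2 * cl, 3 * cl)
  avg <- beat_average(mov, onsets, n_beats = 4)
  ref <- sigmoid_trace(seq_len(dim(avg$frames)[1]) - 1, t_act = 20, apd = 40)
  resid <- avg$frames[, 1, 1] - ref
  expect_lt(sd(resid), 0.1 / 2 * 1.4)   # about sigma/2
  # 4 identical beats average to a single beat
  frames0 <- array(0, dim = c(nt, 2, 2))
  for (i in 1:2) for (j in 1:2) frames0[, i, j] <- beat
  avg0 <- beat_average(voltage_movie(frames0, 1.0), onsets, 4)
  nw <- dim(avg0$frames)[1]
  expect_equal(avg0$frames[, 1, 1], beat[1:nw], tolerance = 1e-12)
  expect_error(beat_average(mov, c(0, cl), n_beats = 4), "at least 4")
  expect_error(beat_average(mov, c(0, cl, 2 * cl, 420), n_beats = 4),
               "beyond")
})

test_that("delta maps subtract on the joint mask and check shape", {
  a <- map_matrix(matrix(50, 4, 4), "ms")
  b <- map_matrix(matrix(60, 4, 4), "ms")
  expect_true(all(delta_apd_map(a, b)$values == 10))
  expect_true(all(delta_apd_map(a, a)$values == 0))
  expect_error(delta_apd_map(a, map_matrix(matrix(1, 3, 3), "ms")), "shape")
  m1 <- matrix(c(1, NA, NA, NA), 2, 2)
  m2 <- matrix(c(NA, NA, 1, NA), 2, 2)
  expect_warning(d <- delta_apd_map(map_matrix(m1, "ms"), map_matrix(m2, "ms")),
                 "valid")
  expect_false(any(d$valid_mask))
})
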