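# ROI segmentation, cosine similarity, circular correlation, Mantel test,
# exact rank tests, and the regional composites.

test_that("scar and BZ are segmented from autofluorescence", {
  p <- make_phantom(96, 96, pixel_pitch = 110, disorder_level = 0.5,
                    scar_radius_um = 1200, bz_width_um = 300, seed = 5)
  lms <- list(lv_rv = rbind(c(30, 1), c(30, 96)),
              base_apex = rbind(c(96, 45), c(30, 45)))
  rs <- segment_rois(p$autofluorescence, lms, tissue_mask = p$tissue_mask,
                     bz_width_um = 300)
  sc <- roi_mask(rs, "scar")
  jac <- sum(sc & p$scar_mask) / sum(sc | p$scar_mask)
  expect_gt(jac, 0.9)
  expect_true(all(c("LV_base", "LV_apex", "RV", "BZ") %in% roi_labels(rs)))
  # scar never overlaps BZ
  expect_false(any(sc & roi_mask(rs, "BZ")))

  # sham heart: no scar, labels are exactly the anatomical three
  p0 <- make_phantom(96, 96, pixel_pitch = 110, seed = 6)
  expect_warning(rs0 <- segment_rois(p0$autofluorescence, lms,
                                     tissue_mask = p0$tissue_mask), "no scar")
  expect_setequal(roi_labels(rs0), c("LV_base", "LV_apex", "RV"))
  # zero BZ width: no BZ band
  rs1 <- segment_rois(p$autofluorescence, lms, tissue_mask = p$tissue_mask,
                      bz_width_um = 0)
  expect_false("BZ" %in% roi_labels(rs1))
})

test_that("cosine similarity follows the angle identities in both modes", {
  th <- matrix(runif(100, 0, pi), 10, 10)
  of <- orientation_field(th, pixel_pitch = 55)
  vf_same <- vector_field(th, matrix(0.5, 10, 10), pixel_pitch = 55)
  expect_true(all(abs(cosine_similarity_map(of, vf_same, "axial")$values - 1) < 1e-9))
  expect_true(all(abs(cosine_similarity_map(of, vf_same, "literal")$values - 1) < 1e-9))
  vf_90 <- vector_field((th + pi / 2) %% (2 * pi), matrix(0.5, 10, 10),
                        pixel_pitch = 55)
  expect_true(all(abs(cosine_similarity_map(of, vf_90, "axial")$values + 1) < 1e-9))
  expect_true(all(abs(cosine_similarity_map(of, vf_90, "literal")$values) < 1e-9))
  # axial mode invariant to theta -> theta + pi on the conduction side
  vf_flip <- vector_field((th + pi) %% (2 * pi), matrix(0.5, 10, 10),
                          pixel_pitch = 55)
  expect_equal(cosine_similarity_map(of, vf_flip, "axial")$values,
               cosine_similarity_map(of, vf_same, "axial")$values,
               tolerance = 1e-9)
  expect_error(cosine_similarity_map(
    of, vector_field(matrix(0, 4, 4), matrix(1, 4, 4)), "axial"), "shape")
})

test_that("conduction aligns with fibers when fibers follow the wave path", {
  # radial fiber field centred on the pacing site: propagation runs along
  # fibers everywhere, so the conduction direction matches the fiber axis
  p <- make_phantom(64, 64, pixel_pitch = 110, disorder_level = 0, seed = 9)
  src <- c(32, 32)
  xs <- matrix(rep(1:64, each = 64), 64, 64)
  ys <- matrix(rep(1:64, 64), 64, 64)
  radial <- atan2(ys - src[2], xs - src[1]) %% pi
  p$fiber_angle[] <- radial
  of <- orientation_field(p$fiber_angle, pixel_pitch = 110)
  act <- simulate_activation(p, 0.6, 0.2, src)
  vf <- conduction_vectors(act, 7)
  cs <- cosine_similarity_map(of, vf, "axial")
  far <- sqrt((xs - src[1])^2 + (ys - src[2])^2) > 8  # source singularity out
  vals <- cs$values[cs$valid_mask & far]
  expect_gt(stats::median(vals, na.rm = TRUE), 0.9)
})

test_that("circular correlation hits its algebraic anchors", {
  set.seed(4)
  a <- runif(60, 0, 2 * pi)
  r1 <- angular_correlation(a, a)
  expect_equal(r1$statistic, 1, tolerance = 1e-12)
  abar <- atan2(mean(sin(a)), mean(cos(a)))
  r2 <- angular_correlation(a, (2 * abar - a) %% (2 * pi))
  expect_equal(r2$statistic, -1, tolerance = 1e-9)
  expect_error(angular_correlation(a, rep(1, 60)), "zero circular variance")
  expect_error(angular_correlation(1:4, 1:4), "at least 5")
  # null: independent uniform angles rarely look correlated.  The null SD of
  # rho_c at n = 100 is about 0.1, so |rho| < 0.2 holds for ~95% of draws; a
  # 90% bound keeps the check well clear of binomial fluctuation.
  hits <- 0
  for (s in 1:200) {
    set.seed(s)
    x <- runif(100, 0, 2 * pi); y <- runif(100, 0, 2 * pi)
    hits <- hits + (abs(angular_correlation(x, y)$statistic) < 0.2)
  }
  expect_gte(hits, 180)
})

test_that("Mantel permutation test is seeded, bounded and sane", {
  set.seed(10)
  a <- matrix(runif(36 * 36, 0, 2 * pi), 36, 36)
  self <- mantel_matrix_test(a, a, n_perm = 1000, seed = 3)
  expect_lte(self$p_value, 0.05)
  expect_equal(self$statistic, 1, tolerance = 1e-12)
  b <- matrix(runif(36 * 36, 0, 2 * pi), 36, 36)
  t1 <- mantel_matrix_test(a, b, n_perm = 200, seed = 9)
  t2 <- mantel_matrix_test(a, b, n_perm = 200, seed = 9)
  expect_identical(t1$p_value, t2$p_value)
  expect_error(mantel_matrix_test(a[1:10, ], b[1:10, ], 200, 1), "square")
  expect_error(mantel_matrix_test(a, b, n_perm = 50), "99")
  # masked path: invalid entries are tolerated
  am <- a; am[1:3, ] <- NA
  tm <- mantel_matrix_test(am, b, n_perm = 100, seed = 2)
  expect_true(tm$p_value > 0 && tm$p_value <= 1)
})

test_that("exact Mann-Whitney matches enumeration and the printed anchor", {
  sep <- mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(sep$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(round(sep$p_value, 4), 0.0286)
  expect_true(sep$exact)
  # one inversion from complete separation
  inv <- mann_whitney_exact(c(1, 2, 3, 5), c(4, 6, 7, 8))
  expect_equal(inv$p_value, 4 / 70, tolerance = 1e-12)
  # centred statistic -> p = 1
  ctr <- mann_whitney_exact(c(1, 4, 5, 8), c(2, 3, 6, 7))
  expect_equal(ctr$p_value, 1)
  expect_error(mann_whitney_exact(numeric(0), 1:3), "nonempty")
  # ties fall back to the flagged approximation
  tie <- mann_whitney_exact(c(1, 2, 2, 3), c(2, 4, 5, 6))
  expect_false(tie$exact)
})

test_that("rank tests agree with independent oracles on small designs", {
  set.seed(5)
  for (i in 1:10) {
    nx <- sample(3:5, 1); ny <- sample(3:5, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    expect_equal(mann_whitney_exact(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  for (i in 1:10) {
    n <- sample(5:9, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(spearman(x, y)$p_value,
                 suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                                  exact = TRUE)$p.value),
                 tolerance = 1e-9)
  }
  # Kruskal-Wallis against per-assignment enumeration with stats::kruskal.test
  for (sizes in list(c(3, 3, 3), c(2, 4, 4))) {
    set.seed(sum(sizes))
    vals <- lapply(sizes, rnorm)
    ours <- kruskal_wallis(vals)
    pooled <- unlist(vals)
    labs <- cardiomapr:::enum_partitions(sizes)
    h_obs <- stats::kruskal.test(pooled,
                                 factor(rep(seq_along(sizes), sizes)))$statistic
    h_all <- apply(labs, 2, function(l)
      stats::kruskal.test(pooled, factor(l))$statistic)
    expect_equal(ours$statistic, unname(h_obs), tolerance = 1e-9)
    expect_equal(ours$p_value, mean(h_all >= h_obs - 1e-9), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis and Spearman hit their enumeration anchors", {
  kw <- kruskal_wallis(list(1:4, 5:8, 9:12))
  expect_equal(kw$p_value, 6 / 34650, tolerance = 1e-12)
  expect_true(kw$exact)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))$p_value, 1)
  big <- kruskal_wallis(list(rnorm(10), rnorm(10), rnorm(10)))
  expect_false(big$exact)

  sp <- spearman(1:5, 1:5)
  expect_equal(sp$statistic, 1)
  expect_equal(sp$p_value, 2 / 120, tolerance = 1e-12)
  expect_equal(spearman(1:6, 6:1)$statistic, -1)
  fig <- spearman(1:9, c(4, 2, 3, 1, 6, 5, 7, 8, 9))
  expect_equal(fig$statistic, 1 - 120 / 720, tolerance = 1e-12)
  expect_equal(round(fig$p_value, 4), 0.0083)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("permutation p-values are valid under a simulated null", {
  set.seed(77)
  p_small <- replicate(400, mann_whitney_exact(rnorm(4), rnorm(4))$p_value)
  for (alpha in c(0.01, 0.05)) {
    se <- sqrt(alpha * (1 - alpha) / 400)
    expect_lte(mean(p_small <= alpha), alpha + 2 * se + 1e-12)
  }
})

test_that("the composite flags BZ and rejects degenerate inputs", {
  rt <- tibble::tibble(
    roi = c("LV_base", "RV", "BZ", "LV_base", "RV", "BZ"),
    anisotropy_index = c(0.01, 0.012, 0.05, 0.011, 0.013, 0.047),
    tissue_activation_time = c(2.0, 2.2, 5.5, 2.1, 2.3, 5.1))
  cp <- bz_composite(rt)
  expect_true(all(cp$data$is_bz == (cp$data$roi == "BZ")))
  expect_gt(cp$tests$rho, 0)
  expect_error(bz_composite(rt[1, ]), "at least 3")
  same <- tibble::tibble(roi = c("a", "b", "c", "d"),
                         anisotropy_index = c(1, 1, 1, 1),
                         tissue_activation_time = c(1, 1, 1, 1))
  expect_error(bz_composite(same), "constant")
})

test_that("regional delta-APD analysis mirrors the imposed relationships", {
  p <- make_phantom(64, 64, pixel_pitch = 110, disorder_level = 0.4,
                    scar_radius_um = 1000, bz_width_um = 400, seed = 31)
  lms <- list(lv_rv = rbind(c(20, 1), c(20, 64)),
              base_apex = rbind(c(64, 30), c(20, 30)))
  rs <- segment_rois(p$autofluorescence, lms, tissue_mask = p$tissue_mask,
                     bz_width_um = 400)
  # uniform delta map: no regional variation at all
  uni <- map_matrix(matrix(10, 64, 64), "ms", 110)
  r0 <- regional_delta_apd(uni, rs)
  expect_gt(r0$kruskal$p_value, 0.5)
  expect_true(all(r0$table$delta_apd80_median == 10))

  # imposed delta proportional to prevalence in non-BZ regions, flat in BZ
  prev <- tibble::tibble(roi = c("LV_base", "LV_apex", "RV", "BZ"),
                         prev_small = c(0.8, 1.0, 1.6, 2.5))
  dm <- matrix(NA_real_, 64, 64)
  for (lb in prev$roi) {
    amp <- if (lb == "BZ") 0 else 10 * prev$prev_small[prev$roi == lb]
    dm[roi_mask(rs, lb)] <- amp
  }
  set.seed(2)
  dm <- dm + matrix(rnorm(64^2, 0, 0.3), 64, 64)
  dmap <- map_matrix(dm, "ms", 110)
  # a second heart's worth of regions pooled in, as in a
  # regions-from-several-hearts design
  second <- tibble::tibble(
    roi = c("LV_base", "LV_apex", "RV", "BZ"),
    delta_apd80_median = c(7.6, 10.4, 15.8, 0.2),
    prev_small = c(0.75, 1.05, 1.55, 2.4))
  r1 <- regional_delta_apd(dmap, rs, small_prevalence = prev,
                           pooled_rows = second)
  expect_false(is.null(r1$spearman_with_bz))
  expect_gt(r1$spearman_without_bz$statistic, 0.9)
  expect_gt(r1$spearman_without_bz$statistic, r1$spearman_with_bz$statistic)
  expect_lt(r1$kruskal$p_value, 0.01)
  # a BZ given high prevalence but no APD response drags the pooled
  # correlation toward zero
  expect_lt(r1$spearman_with_bz$statistic, 0.6)
})
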