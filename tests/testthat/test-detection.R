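# Detection-distance solver, sensitivity map and iris comparison.

test_that("zero spark radiance gives zero contrast and no detection", {
  sc <- default_scene(spark_level = 0)
  scan <- detection_scan(sc$L_base, sc$L_spark, sc$R_retro, sc$geometry,
                         sc$vsp)
  expect_equal(scan$achromatic, rep(0, 141))
  expect_equal(scan$chromatic, rep(0, 141))
  expect_true(is.na(scan$max_detect_achromatic_mm))
  expect_true(is.na(scan$max_detect_chromatic_mm))
})

test_that("solver matches the analytic root for a constant-spectra scene", {
  # constant everything and a unit observer: C(d) = k / (2 m d^2 + k)
  lb <- 0.004; ls <- 1.3; rr <- 1.1
  As <- 0.9; At <- 2.2; Asp <- 11
  g <- geometry_params(As, At, Asp, 60)
  vsp <- unit_vsp()
  scan <- detection_scan(flat_spec(lb, "radiance"), flat_spec(ls, "radiance"),
                         flat_spec(rr, "reflectance"), g, vsp)
  k4 <- ls * As * rr / pi * Asp * At * 301      # d^-4 coefficient
  k2 <- lb * Asp * At * 301                     # d^-2 coefficient
  thr <- vsp$achromatic_threshold
  d_star <- sqrt(k4 * (1 - thr) / (2 * k2 * thr))
  expect_true(d_star > 10 && d_star < 150)
  expect_equal(scan$max_detect_achromatic_mm, floor(d_star))

  # threshold 0: the whole grid is compliant
  vsp0 <- unit_vsp(achromatic_threshold = 0, chromatic_threshold_jnd = 0)
  scan0 <- detection_scan(flat_spec(lb, "radiance"), flat_spec(ls, "radiance"),
                          flat_spec(rr, "reflectance"), g, vsp0)
  expect_equal(scan0$max_detect_achromatic_mm, 150)
})

test_that("solver agrees with a 0.1 mm brute-force oracle on 50 random scenes", {
  vsp <- default_visual_system()
  for (i in 1:50) {
    sc <- random_scene(i)
    scan <- detection_scan(sc$L_base, sc$L_spark, sc$R_retro, sc$geometry, vsp)
    oracle <- oracle_max_detect(sc, vsp, step = 0.1)
    if (is.na(oracle)) {
      expect_true(is.na(scan$max_detect_achromatic_mm))
    } else {
      expect_lte(abs(scan$max_detect_achromatic_mm - oracle), 1)
    }
  }
})

test_that("sensitivity grid is consistent with single scans and monotone", {
  sc <- default_scene()
  levels <- seq(0, 2, by = 0.25)
  gr <- sensitivity_grid(sc$L_base, sc$L_spark, sc$R_retro, sc$geometry,
                         sc$vsp, spark_levels = levels, retro_levels = levels)
  # zero-level row and column: no detection anywhere
  expect_true(all(is.na(gr$detect_mm[1, ])))
  expect_true(all(is.na(gr$detect_mm[, 1])))
  # cell (1.0, 1.0) equals a direct detection_scan call
  direct <- detection_scan(sc$L_base, sc$L_spark, sc$R_retro, sc$geometry,
                           sc$vsp)
  expect_equal(gr$detect_mm["1.00", "1.00"], direct$max_detect_achromatic_mm)
  # non-decreasing along both axes (NA = no detection = 0)
  m <- gr$detect_mm; m[is.na(m)] <- 0
  expect_true(all(apply(m, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(m, 2, function(cl) all(diff(cl) >= 0))))
})

test_that("scaling ambient irradiance never decreases a grid cell", {
  sc <- default_scene()
  levels <- seq(0.25, 1.75, by = 0.5)
  run <- function(gain) sensitivity_grid(
    sc$L_base * gain, sc$L_spark * gain, sc$R_retro, sc$geometry, sc$vsp,
    spark_levels = levels, retro_levels = levels)$detect_mm
  g1 <- run(1); g2 <- run(2)
  g1[is.na(g1)] <- 0; g2[is.na(g2)] <- 0
  expect_true(all(g2 >= g1))
})

test_that("iris comparison shows no perceptible effect under defaults", {
  sc <- default_scene()
  iris <- iris_comparison(sc$L_base_iris, sc$L_spark, sc$R_iris, sc$geometry,
                          sc$vsp)
  expect_true(is.na(iris$max_detect_achromatic_mm))
  expect_true(is.na(iris$max_detect_chromatic_mm))

  zero <- iris_comparison(sc$L_base_iris, sc$L_spark,
                          sc$R_iris * 0, sc$geometry, sc$vsp)
  expect_true(is.na(zero$max_detect_achromatic_mm))

  # pupil beats iris whenever the pupil actually retroreflects
  pupil <- detection_scan(sc$L_base, sc$L_spark, sc$R_retro, sc$geometry,
                          sc$vsp)
  expect_gt(pupil$max_detect_achromatic_mm, 0)

  # degenerate equality: iris given the pupil's spectra reproduces the
  # pupil scan exactly
  same <- iris_comparison(sc$L_base, sc$L_spark, sc$R_retro, sc$geometry,
                          sc$vsp)
  expect_identical(same$achromatic, pupil$achromatic)
  expect_identical(same$max_detect_achromatic_mm,
                   pupil$max_detect_achromatic_mm)
})
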