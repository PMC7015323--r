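# Radiometric chain: solid angles, baseline and retroreflected fluxes,
# exact distance power laws and linearity.

test_that("solid angle is A/d^2 and matches the exact disc formula", {
  expect_equal(solid_angle(1, 100), 1e-4)
  expect_equal(solid_angle(1, 200) * 4, solid_angle(1, 100))
  expect_error(solid_angle(-1, 10), "positive")
  expect_error(solid_angle(1, 0), "positive")

  # exact disc solid angle 2*pi*(1 - cos(atan(r/d))), within 1% for
  # sqrt(A/pi)/d < 0.1
  for (case in list(c(3, 60), c(1, 50), c(0.5, 10))) {
    A <- case[1]; d <- case[2]
    r <- sqrt(A / pi)
    stopifnot(r / d < 0.1)
    exact <- 2 * pi * (1 - cos(atan(r / d)))
    expect_lt(abs(solid_angle(A, d) - exact) / exact, 0.01)
  }
})

test_that("baseline flux follows the inverse-square law exactly", {
  g <- geometry_params(1, 1, 1, 100)
  expect_equal(baseline_flux(flat_spec(0, "radiance"), g)$value, rep(0, 301))
  expect_equal(baseline_flux(flat_spec(1, "radiance"), g)$value, rep(1e-4, 301))

  set.seed(4)
  L <- new_spectrum(wl_grid, runif(301, 0, 3), "radiance")
  g1 <- geometry_params(distance_mm = 57)
  g2 <- geometry_params(distance_mm = 114)
  ratio <- baseline_flux(L, g1)$value / baseline_flux(L, g2)$value
  expect_equal(ratio, rep(4, 301), tolerance = 1e-12)
  expect_error(baseline_flux(flat_spec(1, "irradiance"), g1), "radiance")
})

test_that("spark radiance is Lambertian: R * E / pi", {
  E <- flat_spec(pi, "irradiance")
  expect_equal(spark_radiance(flat_spec(1, "reflectance"), E)$value,
               rep(1, 301))
  expect_equal(spark_radiance(flat_spec(0, "reflectance"), E)$value,
               rep(0, 301))
  # total photons scale linearly with a scalar multiplier on R
  R <- make_reflectance("spark", level = 0.7)
  tot1 <- integrate_spectrum(spark_radiance(R, E))
  tot3 <- integrate_spectrum(spark_radiance(R * 3, E))
  expect_equal(tot3, 3 * tot1)
  short <- new_spectrum(500:600, rep(1, 101), "reflectance")
  expect_error(spark_radiance(short, E), "different wavelength grids")
})

test_that("retro flux follows d^-4 and the closed-form chain product", {
  g <- geometry_params(0.8, 2, 12, 60)
  expect_equal(retro_flux(flat_spec(1, "radiance"), flat_spec(0, "reflectance"),
                          g)$value, rep(0, 301))

  set.seed(5)
  L <- new_spectrum(wl_grid, runif(301, 0, 2), "radiance")
  R <- new_spectrum(wl_grid, runif(301, 0, 2), "reflectance")
  g2 <- geometry_params(0.8, 2, 12, 120)
  ratio <- retro_flux(L, R, g)$value / retro_flux(L, R, g2)$value
  expect_equal(ratio, rep(16, 301), tolerance = 1e-12)

  # constant spectra: full chain equals the single closed-form product
  Rsp <- 0.6; E <- 2.5; Rr <- 1.4
  L_spark <- spark_radiance(flat_spec(Rsp, "reflectance"),
                            flat_spec(E, "irradiance"))
  got <- retro_flux(L_spark, flat_spec(Rr, "reflectance"), g)$value
  closed <- Rsp * E / pi * 0.8 / 60^2 * Rr / pi * 12 * 2 / 60^2
  expect_equal(got, rep(closed, 301), tolerance = 1e-12)
})

test_that("fluxes are linear in every input spectrum separately", {
  sc <- random_scene(1)
  b1 <- baseline_flux(sc$L_base, sc$geometry)$value
  b2 <- baseline_flux(sc$L_base * 2.5, sc$geometry)$value
  expect_equal(b2, 2.5 * b1)
  r1 <- retro_flux(sc$L_spark, sc$R_retro, sc$geometry)$value
  expect_equal(retro_flux(sc$L_spark * 3, sc$R_retro, sc$geometry)$value, 3 * r1)
  expect_equal(retro_flux(sc$L_spark, sc$R_retro * 3, sc$geometry)$value, 3 * r1)
})

test_that("scene fluxes: spark only adds photons (flux1 >= flux2)", {
  sc <- random_scene(2)
  off <- scene_fluxes(sc$L_base, sc$L_spark * 0, sc$R_retro, sc$geometry)
  expect_equal(off$flux_with_spark$value, off$flux_without_spark$value)

  on <- scene_fluxes(sc$L_base, sc$L_spark, sc$R_retro, sc$geometry)
  diff <- on$flux_with_spark$value - on$flux_without_spark$value
  expect_equal(diff, retro_flux(sc$L_spark, sc$R_retro, sc$geometry)$value)

  # ordering invariant over randomised spectra
  set.seed(6)
  for (i in 1:1000) {
    lb <- runif(1, 0, 2); ls <- runif(1, 0, 2); rr <- runif(1, 0, 2)
    v <- scene_fluxes(flat_spec(lb, "radiance") * runif(1),
                      flat_spec(ls, "radiance") * runif(1),
                      flat_spec(rr, "reflectance"),
                      sc$geometry)
    expect_true(all(v$flux_with_spark$value >= v$flux_without_spark$value))
  }
})
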