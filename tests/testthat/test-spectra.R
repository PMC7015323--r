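# Spectral data type: construction, resampling, integration, file I/O.

test_that("spectrum construction enforces its invariants", {
  expect_s3_class(flat_spec(1, "irradiance"), "spectrum")
  expect_error(new_spectrum(c(400, 400, 401), c(1, 1, 1), "radiance"),
               "strictly increasing")
  expect_error(new_spectrum(c(400, 401, 403), c(1, 1, 1), "radiance"),
               "uniform")
  expect_error(new_spectrum(400:402, c(1, -1, 1), "radiance"),
               "nonnegative")
  expect_error(new_spectrum(400:402, c(0.5, 1.5, 0.5), "transmission"),
               "\\[0, 1\\]")
  # retroreflectance above 1 is physical (relative to a white standard)
  expect_silent(new_spectrum(400:402, c(0.5, 1.5, 0.5), "reflectance"))
  expect_error(new_spectrum(400:402, c(1, Inf, 1), "flux"), "finite")
})

test_that("resampling interpolates linearly and zero-fills outside support", {
  s <- flat_spec(2, "radiance")
  sub <- resample_spectrum(s, 450:550)
  expect_equal(sub$value, rep(2, 101))
  expect_identical(sub$kind, "radiance")

  two <- new_spectrum(c(400, 700), c(0, 3), "radiance")
  mid <- resample_spectrum(two, seq(400, 700, by = 150))
  expect_equal(mid$value[mid$wavelength_nm == 550], 1.5)

  # zero-fill, not constant-fill, outside the measured support
  narrow <- new_spectrum(500:600, rep(1, 101), "sensitivity")
  wide <- resample_spectrum(narrow, wl_grid)
  expect_equal(wide$value[wl_grid < 500], rep(0, 100))
  expect_equal(wide$value[wl_grid > 600], rep(0, 100))

  expect_error(resample_spectrum(narrow, 650:700), "no overlap")
})

test_that("resample-then-integrate matches a fine-grid oracle", {
  # piecewise-linear spectrum with zero endpoints, knots on the nm grid
  knots <- c(400, 450, 520, 600, 700)
  vals <- c(0, 2.3, 0.7, 1.9, 0)
  s <- new_spectrum(seq(400, 700, by = 50),
                    stats::approx(knots, vals, seq(400, 700, by = 50))$y,
                    "irradiance")
  got <- integrate_spectrum(resample_spectrum(s, wl_grid))
  fine <- seq(400, 700, by = 0.01)
  oracle <- sum(stats::approx(s$wavelength_nm, s$value, fine)$y) * 0.01
  expect_lt(abs(got - oracle) / oracle, 1e-6)
})

test_that("rectangle-rule integration is exact for constants and Gaussians", {
  expect_equal(integrate_spectrum(flat_spec(1, "irradiance")), 301)
  expect_equal(integrate_spectrum(flat_spec(0, "flux")), 0)

  g <- gauss_spec(550, 30, kind = "irradiance")
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  closed <- 30 * sqrt(pi) / 2 * (erf((700 - 550) / 30) - erf((400 - 550) / 30))
  expect_lt(abs(integrate_spectrum(g) - closed) / closed, 1e-3)
})

test_that("integration is linear and resampling idempotent", {
  set.seed(1)
  s <- new_spectrum(wl_grid, runif(301), "irradiance")
  t <- new_spectrum(wl_grid, runif(301), "irradiance")
  for (ab in list(c(1, 1), c(2.5, 0.3), c(0, 4))) {
    comb <- s * ab[1] + t * ab[2]
    expect_equal(integrate_spectrum(comb),
                 ab[1] * integrate_spectrum(s) + ab[2] * integrate_spectrum(t))
  }
  expect_equal(resample_spectrum(s, wl_grid)$value, s$value)
})

test_that("pointwise products are commutative, associative, grid-preserving", {
  set.seed(2)
  r <- new_spectrum(wl_grid, runif(301, 0, 2), "reflectance")
  tr <- new_spectrum(wl_grid, runif(301), "transmission")
  sn <- new_spectrum(wl_grid, runif(301), "sensitivity")
  ab <- r * tr; ba <- tr * r
  expect_equal(ab$value, ba$value)
  expect_identical(ab$kind, ba$kind)
  abc <- (r * tr) * sn; acb <- r * (tr * sn)
  expect_equal(abc$value, acb$value)
  expect_identical(abc$kind, acb$kind)
  expect_equal(abc$wavelength_nm, wl_grid + 0)
  # a dimensionless factor preserves the radiometric kind
  L <- flat_spec(3, "radiance")
  expect_identical((L * r)$kind, "radiance")
})

test_that("CSV round trip preserves values and kind; bad files error", {
  s <- new_spectrum(400:401, c(1, 2), "irradiance")
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, f)
  back <- read_spectrum_csv(f)               # kind from the # kind: comment
  expect_identical(back$kind, "irradiance")
  expect_identical(back$value, s$value)

  set.seed(3)
  s2 <- new_spectrum(wl_grid, runif(301, 0, 5), "radiance")
  write_spectrum_csv(s2, f)
  expect_identical(read_spectrum_csv(f, "radiance")$value, s2$value)

  writeLines(c("wavelength_nm,value", "400,1", "500,2", "500,3", "600,4"), f)
  expect_error(read_spectrum_csv(f, "radiance"), "duplicate wavelength")
  writeLines(c("wavelength_nm,value", "400,1", "500,abc"), f)
  expect_error(read_spectrum_csv(f, "radiance"), "non-numeric")
  writeLines(c("wavelength_nm,value", "400,1", "500,-2", "600,1"), f)
  expect_error(read_spectrum_csv(f, "transmission"), "negative")
})
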