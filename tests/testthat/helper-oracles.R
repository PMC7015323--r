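# Shared fixtures and independent oracles for the test suite.

wl_grid <- default_wavelengths()

flat_spec <- function(value, kind) constant_spectrum(value, kind, wl_grid)

gauss_spec <- function(peak, width, height = 1, kind = "reflectance") {
  new_spectrum(wl_grid, height * exp(-((wl_grid - peak) / width)^2), kind)
}

# a unit-sensitivity observer: flat sensitivities and clear ocular media,
# so quantum catches reduce to plain rectangle sums of the flux
unit_vsp <- function(...) {
  visual_system(
    sensitivities = list(flat_spec(1, "sensitivity"),
                         flat_spec(1, "sensitivity"),
                         flat_spec(1, "sensitivity")),
    ocular_media = flat_spec(1, "transmission"), ...)
}

# reproducible random smooth scene for property sweeps
random_scene <- function(i) {
  set.seed(7000 + i)
  g <- geometry_params(area_spark_mm2 = runif(1, 0.2, 1.5),
                       area_tf_pupil_mm2 = runif(1, 1, 4),
                       area_sp_pupil_mm2 = runif(1, 5, 20),
                       distance_mm = 60)
  amb <- make_ambient(ambient_model(depth_m = runif(1, 2, 15)))
  R_spark <- make_reflectance("spark", level = runif(1, 0.3, 2),
                              peak_nm = runif(1, 430, 500),
                              width_nm = runif(1, 50, 100))
  R_retro <- make_reflectance("retro_pupil", level = runif(1, 0.3, 2))
  R_base <- make_reflectance("baseline_pupil_radiance",
                             level = runif(1, 0.001, 0.01))
  list(L_base = spark_radiance(R_base, amb),
       L_spark = spark_radiance(R_spark, amb),
       R_retro = R_retro,
       geometry = g)
}

# Brute-force detection oracle: evaluates the full radiometric chain
# through scene_fluxes() at every distance on a fine grid and takes the
# supremum compliant distance.  Independent of detection_scan()'s
# power-law evaluation and descending-scan extraction.
oracle_max_detect <- function(sc, vsp, step = 0.1, lo = 10, hi = 150) {
  media <- resample_spectrum(vsp$ocular_media, wl_grid)$value
  resp <- sapply(vsp$sensitivities,
                 function(s) resample_spectrum(s, wl_grid)$value * media)
  ds <- seq(lo, hi, by = step)
  contr <- vapply(ds, function(d) {
    g <- suppressWarnings(geometry_params(sc$geometry$area_spark_mm2,
                                          sc$geometry$area_tf_pupil_mm2,
                                          sc$geometry$area_sp_pupil_mm2, d))
    sf <- scene_fluxes(sc$L_base, sc$L_spark, sc$R_retro, g)
    q1 <- colSums(sf$flux_with_spark$value * resp)
    q2 <- colSums(sf$flux_without_spark$value * resp)
    (sum(q1[2:3]) - sum(q2[2:3])) / (sum(q1[2:3]) + sum(q2[2:3]))
  }, numeric(1))
  ok <- which(contr >= vsp$achromatic_threshold)
  if (length(ok)) ds[max(ok)] else NA_real_
}

# Independent exact-test oracles built directly on the hypergeometric
# support via stats::dhyper / explicit likelihood enumeration.
oracle_fisher_p <- function(a, b, cc, d) {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(k, r1, r2, c1)
  sum(pr[pr <= pr[k == a] * (1 + 1e-7)])
}

oracle_cmle_or <- function(a, b, cc, d) {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  k <- max(0, c1 - r2):min(r1, c1)
  if (a == min(k)) return(0)
  if (a == max(k)) return(Inf)
  logdc <- lchoose(r1, k) + lchoose(r2, c1 - k)
  nll <- function(t) {
    w <- logdc + k * t
    -(logdc[k == a] + a * t - (max(w) + log(sum(exp(w - max(w))))))
  }
  exp(stats::optimize(nll, c(-25, 25), tol = 1e-10)$minimum)
}
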