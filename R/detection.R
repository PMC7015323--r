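# Distance scanning: evaluate the paired scene fluxes and both contrasts
# at every millimetre between 1 and 15 cm, and extract the maximum
# distance at which each contrast still reaches its detection threshold.
# Because contrast falls with distance, the descending-scan first hit --
# equivalently the largest compliant grid distance -- is the "maximum
# discernible distance".

#' Detection-distance scan
#'
#' Evaluates the scene at every distance of `distances_mm`, computing the
#' achromatic Michelson contrast and the receptor-noise-limited chromatic
#' contrast between the spark-on and spark-off fluxes, and extracts the
#' maximum distance at which each contrast equals or exceeds its
#' threshold.
#'
#' The baseline flux scales exactly as d^-2 and the retroreflected spark
#' flux as d^-4, and quantum catches are linear in flux, so the scan
#' evaluates the full radiometric chain once at a reference distance and
#' applies the exact power laws across the grid.  Contrast should fall
#' monotonically with distance (d^-4 light fades faster than d^-2 light);
#' a warning is raised if it does not.
#'
#' @param L_base Baseline pupil radiance (`"radiance"` spectrum).
#' @param L_spark Spark radiance (`"radiance"` spectrum).
#' @param R_retro Pupil retroreflectance (`"reflectance"` spectrum).
#' @param geometry A [geometry_params()] supplying the areas; its
#'   `distance_mm` is only used as the reference evaluation distance.
#' @param vsp A [visual_system()].
#' @param distances_mm Distance grid (default 10--150 mm in 1 mm steps,
#'   i.e. 1--15 cm at each millimetre).
#' @return An object of class `detection_scan`: list with `distances_mm`,
#'   `achromatic` and `chromatic` contrast vectors,
#'   `max_detect_achromatic_mm` and `max_detect_chromatic_mm` (`NA` when
#'   no distance qualifies), and the thresholds used.  Chromatic contrast
#'   is `NA` when any baseline catch is zero (log-form model undefined).
#' @export
detection_scan <- function(L_base, L_spark, R_retro, geometry, vsp,
                           distances_mm = 10:150) {
  stopifnot(inherits(geometry, "geometry_params"),
            inherits(vsp, "visual_system"))
  distances_mm <- as.numeric(distances_mm)
  if (any(distances_mm <= 0) || is.unsorted(distances_mm, strictly = TRUE))
    stop("distances_mm must be positive and strictly increasing")

  d0 <- geometry$distance_mm
  qb0 <- .as_catches(quantum_catch(baseline_flux(L_base, geometry), vsp))
  qr0 <- .as_catches(quantum_catch(retro_flux(L_spark, R_retro, geometry), vsp))

  s2 <- (d0 / distances_mm)^2   # baseline path scaling
  s4 <- s2^2                    # spark path scaling
  qb <- outer(qb0, s2)          # 3 x n matrices of catches
  qr <- outer(qr0, s4)

  Qb <- qb["mws", ] + qb["lws", ]
  Qr <- qr["mws", ] + qr["lws", ]
  denom <- 2 * Qb + Qr
  ach <- ifelse(denom > 0, Qr / denom, 0)

  if (all(qb0 > 0)) {
    eta <- vsp$cone_abundance
    e <- vsp$weber_fraction * sqrt(max(eta) / eta)
    f <- log1p(qr / qb)         # log((qb + qr)/qb), per channel x distance
    num <- e[1]^2 * (f[2, ] - f[3, ])^2 +
           e[2]^2 * (f[1, ] - f[3, ])^2 +
           e[3]^2 * (f[1, ] - f[2, ])^2
    den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
    chr <- sqrt(num / den)
  } else {
    chr <- rep(NA_real_, length(distances_mm))
  }

  .max_detect <- function(contrast, threshold) {
    ok <- which(!is.na(contrast) & contrast >= threshold)
    if (length(ok)) distances_mm[max(ok)] else NA_real_
  }
  .check_monotone <- function(contrast, label) {
    if (all(is.na(contrast))) return(invisible())
    tol <- 1e-12 * max(contrast, na.rm = TRUE)
    if (any(diff(contrast) > tol, na.rm = TRUE))
      warning(label, " contrast is not monotone decreasing in distance")
  }
  .check_monotone(ach, "achromatic")
  .check_monotone(chr, "chromatic")

  structure(list(distances_mm = distances_mm,
                 achromatic = unname(ach),
                 chromatic = unname(chr),
                 max_detect_achromatic_mm = .max_detect(ach, vsp$achromatic_threshold),
                 max_detect_chromatic_mm = .max_detect(chr, vsp$chromatic_threshold_jnd),
                 achromatic_threshold = vsp$achromatic_threshold,
                 chromatic_threshold_jnd = vsp$chromatic_threshold_jnd),
            class = "detection_scan")
}

#' @export
print.detection_scan <- function(x, ...) {
  fmt <- function(d) if (is.na(d)) "none" else sprintf("%g mm (%.1f cm)", d, d / 10)
  cat("<detection_scan>\n")
  cat(sprintf("  distances: %g-%g mm (%d points)\n", min(x$distances_mm),
              max(x$distances_mm), length(x$distances_mm)))
  cat(sprintf("  max achromatic detection (C >= %g): %s\n",
              x$achromatic_threshold, fmt(x$max_detect_achromatic_mm)))
  cat(sprintf("  max chromatic detection (>= %g JND): %s\n",
              x$chromatic_threshold_jnd, fmt(x$max_detect_chromatic_mm)))
  invisible(x)
}

#' @export
as.data.frame.detection_scan <- function(x, ...) {
  data.frame(distance_mm = x$distances_mm,
             achromatic = x$achromatic,
             chromatic = x$chromatic)
}

#' Sensitivity map of detection distance
#'
#' Recomputes the achromatic maximum detection distance over a grid of
#' spark-reflectance and pupil-retroreflectance multipliers, reproducing
#' the two-driver sensitivity map: detection distance is non-decreasing
#' along both axes.
#'
#' @param L_base,L_spark,R_retro,geometry,vsp,distances_mm As in
#'   [detection_scan()]; `L_spark` and `R_retro` are the unit-level
#'   spectra that the grid levels multiply.
#' @param spark_levels,retro_levels Nonnegative multiplier grids (defaults
#'   0--2 in 0.05 steps).  A level of 0 switches that driver off and the
#'   cell reports `NA` (no detection at any distance).
#' @return An object of class `sensitivity_grid`: list with
#'   `spark_levels`, `retro_levels` and `detect_mm`, a matrix of maximum
#'   achromatic detection distances (rows: spark levels; columns: retro
#'   levels).
#' @export
sensitivity_grid <- function(L_base, L_spark, R_retro, geometry, vsp,
                             spark_levels = seq(0, 2, by = 0.05),
                             retro_levels = seq(0, 2, by = 0.05),
                             distances_mm = 10:150) {
  if (any(spark_levels < 0) || any(retro_levels < 0))
    stop("grid levels must be nonnegative")
  m <- matrix(NA_real_, length(spark_levels), length(retro_levels),
              dimnames = list(spark = format(spark_levels),
                              retro = format(retro_levels)))
  for (i in seq_along(spark_levels)) {
    for (j in seq_along(retro_levels)) {
      sl <- spark_levels[i]; rl <- retro_levels[j]
      if (sl == 0 || rl == 0) next   # no added photons: no detection
      scan <- detection_scan(L_base, L_spark * sl, R_retro * rl,
                             geometry, vsp, distances_mm)
      m[i, j] <- scan$max_detect_achromatic_mm
    }
  }
  structure(list(spark_levels = spark_levels, retro_levels = retro_levels,
                 detect_mm = m),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("<sensitivity_grid: %d x %d (spark x retro levels)>\n",
              length(x$spark_levels), length(x$retro_levels)))
  rng <- range(x$detect_mm, na.rm = TRUE)
  cat(sprintf("  detection distances: %g-%g mm (NA where undetectable)\n",
              rng[1], rng[2]))
  invisible(x)
}

#' Heatmap of a sensitivity grid
#'
#' @param x A `sensitivity_grid`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.sensitivity_grid <- function(x, ...) {
  graphics::image(x$spark_levels, x$retro_levels, x$detect_mm / 10,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "spark reflectance (prop. of white standard)",
                  ylab = "pupil retroreflectance (prop. of white standard)",
                  main = "max. achromatic detection distance (cm)", ...)
  invisible(x)
}

#' Iris comparison scan
#'
#' Repeats the detection calculation with the scorpionfish iris in place
#' of the retroreflective pupil: the iris is a plain diffuse reflector, so
#' its reflectance (typically well below 1, with no retroreflective gain)
#' replaces the pupil retroreflectance in the spark path, and the iris's
#' own baseline radiance replaces the pupil's.  Under realistic iris
#' reflectance the spark adds the same *proportion* of light to a much
#' brighter baseline, so no perceptible contrast arises at any distance.
#'
#' @param L_base_iris Baseline iris radiance (`"radiance"` spectrum).
#' @param L_spark Spark radiance (`"radiance"` spectrum).
#' @param R_iris Diffuse iris reflectance (`"reflectance"` spectrum).
#' @param geometry,vsp,distances_mm As in [detection_scan()].
#' @return A `detection_scan` for the iris target.
#' @export
iris_comparison <- function(L_base_iris, L_spark, R_iris, geometry, vsp,
                            distances_mm = 10:150) {
  detection_scan(L_base_iris, L_spark, R_iris, geometry, vsp, distances_mm)
}

#' Default synthetic scene
#'
#' Assembles the documented default synthetic world: flat surface light
#' attenuated to blue-green at 10 m depth, a blue-peaked spark at unit
#' peak reflectance, a spectrally flat pupil retroreflectance of 1.2
#' relative to a diffuse white standard, a dark baseline pupil
#' (diffuse-equivalent reflectance 0.002) tinted like the spark
#' reflection, and a diffuse iris of peak reflectance 0.1.
#'
#' @param depth_m Water depth in metres (default 10).
#' @param spark_level Peak spark reflectance (default 1).
#' @param retro_level Pupil retroreflectance level (default 1.2; values
#'   above 1 are physical for retroreflectors measured against a diffuse
#'   white standard).
#' @param baseline_level Diffuse-equivalent reflectance of the baseline
#'   pupil radiance (default 0.002).
#' @param iris_level Peak iris reflectance (default 0.1).
#' @param geometry A [geometry_params()].
#' @param vsp A [visual_system()].
#' @return A list with the assembled spectra (`ambient`, `R_spark`,
#'   `L_spark`, `R_retro`, `L_base`, `R_iris`, `L_base_iris`), the
#'   geometry and the visual system.
#' @export
default_scene <- function(depth_m = 10, spark_level = 1, retro_level = 1.2,
                          baseline_level = 0.002, iris_level = 0.1,
                          geometry = geometry_params(),
                          vsp = default_visual_system()) {
  ambient <- make_ambient(ambient_model(depth_m = depth_m))
  R_spark <- make_reflectance("spark", level = spark_level)
  R_retro <- make_reflectance("retro_pupil", level = retro_level)
  R_base <- make_reflectance("baseline_pupil_radiance", level = baseline_level)
  R_iris <- make_reflectance("iris", level = iris_level)
  list(ambient = ambient,
       R_spark = R_spark,
       L_spark = spark_radiance(R_spark, ambient),
       R_retro = R_retro,
       L_base = spark_radiance(R_base, ambient),
       R_iris = R_iris,
       L_base_iris = spark_radiance(R_iris, ambient),
       geometry = geometry,
       vsp = vsp)
}
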