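# Radiometric propagation along the two optical paths of the scene:
#
#   baseline path:  scorpionfish pupil radiance -> triplefin pupil (flux2)
#   spark path:     ocular spark -> scorpionfish pupil -> retroreflection
#                   -> triplefin pupil (the flux1 addition)
#
# The chain is the standard on-axis small-source model: the spark is a
# diffuse (Lambertian) reflector of downwelling light, retroreflectance is
# expressed relative to a diffuse white standard (so values above 1 absorb
# the narrowing of the return beam), and solid angles use the small-angle
# approximation A / d^2.  Areas are in mm^2 and distances in mm; because
# both contrast metrics are ratios of fluxes computed in the same units,
# no absolute unit conversion is applied.

#' Scene geometry
#'
#' @param area_spark_mm2 Area of the ocular spark (default 0.8 mm^2).
#' @param area_tf_pupil_mm2 Area of the observing triplefin pupil
#'   (default 2 mm^2).
#' @param area_sp_pupil_mm2 Area of the scorpionfish pupil
#'   (default 12 mm^2).
#' @param distance_mm On-axis eye-to-eye distance (default 60 mm).
#' @return An object of class `geometry_params`.  A warning is issued when
#'   any source subtends sqrt(area)/distance > 0.3, outside the
#'   small-angle regime the solid-angle approximation assumes.
#' @export
geometry_params <- function(area_spark_mm2 = 0.8,
                            area_tf_pupil_mm2 = 2,
                            area_sp_pupil_mm2 = 12,
                            distance_mm = 60) {
  vals <- c(area_spark_mm2, area_tf_pupil_mm2, area_sp_pupil_mm2, distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all areas and the distance must be strictly positive")
  if (any(sqrt(vals[1:3]) / distance_mm > 0.3))
    warning("sqrt(area)/distance exceeds 0.3: outside the small-angle regime")
  structure(list(area_spark_mm2 = area_spark_mm2,
                 area_tf_pupil_mm2 = area_tf_pupil_mm2,
                 area_sp_pupil_mm2 = area_sp_pupil_mm2,
                 distance_mm = distance_mm),
            class = "geometry_params")
}

#' Small-angle solid angle of a source
#'
#' @param area_mm2 Source area in mm^2.
#' @param distance_mm Distance in mm.
#' @return Solid angle A / d^2 in steradians.
#' @export
solid_angle <- function(area_mm2, distance_mm) {
  if (any(area_mm2 <= 0) || any(distance_mm <= 0))
    stop("area and distance must be strictly positive")
  area_mm2 / distance_mm^2
}

#' Baseline photon flux from the scorpionfish pupil (flux 2)
#'
#' Photon flux entering the observer's pupil from the baseline radiance of
#' the target pupil alone:
#' Phi2(lambda) = L_base(lambda) * A_sp_pupil * A_tf_pupil / d^2,
#' which scales exactly as d^-2.
#'
#' @param L_base `spectrum` of kind `"radiance"`: baseline radiance of the
#'   scorpionfish pupil.
#' @param g A [geometry_params()].
#' @return A `spectrum` of kind `"flux"` (photons s-1 nm-1).
#' @export
baseline_flux <- function(L_base, g) {
  stopifnot(inherits(L_base, "spectrum"), inherits(g, "geometry_params"))
  if (L_base$kind != "radiance")
    stop("L_base must be a radiance spectrum, not '", L_base$kind, "'")
  omega <- solid_angle(g$area_tf_pupil_mm2, g$distance_mm)
  new_spectrum(L_base$wavelength_nm,
               L_base$value * g$area_sp_pupil_mm2 * omega,
               "flux")
}

#' Radiance of the ocular spark under downwelling light
#'
#' The spark patch behaves like a diffuse Lambertian reflector, so its
#' radiance is L(lambda) = R(lambda) * E(lambda) / pi.
#'
#' @param R_spark `spectrum` of kind `"reflectance"`.
#' @param E_down `spectrum` of kind `"irradiance"`: downwelling irradiance
#'   at the fish's depth.
#' @return A `spectrum` of kind `"radiance"` on the common grid.
#' @export
spark_radiance <- function(R_spark, E_down) {
  stopifnot(inherits(R_spark, "spectrum"), inherits(E_down, "spectrum"))
  if (R_spark$kind != "reflectance")
    stop("R_spark must be a reflectance spectrum")
  if (E_down$kind != "irradiance")
    stop("E_down must be an irradiance spectrum")
  .check_same_grid(R_spark, E_down)
  new_spectrum(R_spark$wavelength_nm,
               R_spark$value * E_down$value / pi,
               "radiance")
}

#' Retroreflected spark flux at the observer's pupil
#'
#' The spark path chained end to end:
#' \enumerate{
#'   \item irradiance at the target pupil:
#'     E_t(lambda) = L_spark(lambda) * A_spark / d^2;
#'   \item radiance returned by the retroreflective pupil, relative to a
#'     diffuse white standard (so `R_retro` may exceed 1):
#'     L_r(lambda) = E_t(lambda) * R_retro(lambda) / pi;
#'   \item flux through the observer's pupil:
#'     Phi_r(lambda) = L_r(lambda) * A_sp_pupil * A_tf_pupil / d^2.
#' }
#' The net scaling with distance is exactly d^-4.
#'
#' @param L_spark `spectrum` of kind `"radiance"`: spark radiance (either
#'   measured directly or from [spark_radiance()]).
#' @param R_retro `spectrum` of kind `"reflectance"`: pupil
#'   retroreflectance relative to a diffuse white standard.
#' @param g A [geometry_params()].
#' @return A `spectrum` of kind `"flux"`.
#' @export
retro_flux <- function(L_spark, R_retro, g) {
  stopifnot(inherits(L_spark, "spectrum"), inherits(R_retro, "spectrum"),
            inherits(g, "geometry_params"))
  if (L_spark$kind != "radiance")
    stop("L_spark must be a radiance spectrum")
  if (R_retro$kind != "reflectance")
    stop("R_retro must be a reflectance spectrum")
  .check_same_grid(L_spark, R_retro)
  d2 <- g$distance_mm^2
  e_target <- L_spark$value * g$area_spark_mm2 / d2
  l_return <- e_target * R_retro$value / pi
  new_spectrum(L_spark$wavelength_nm,
               l_return * g$area_sp_pupil_mm2 * g$area_tf_pupil_mm2 / d2,
               "flux")
}

#' Paired scene fluxes with and without the ocular spark
#'
#' Flux 1 (spark on) is the sum of the baseline pupil flux and the
#' retroreflected spark flux; flux 2 (spark off) is the baseline flux
#' alone.  The spark only adds photons, so flux 1 >= flux 2 pointwise.
#'
#' @param L_base Baseline pupil radiance (`"radiance"`).
#' @param L_spark Spark radiance (`"radiance"`).
#' @param R_retro Pupil retroreflectance (`"reflectance"`).
#' @param g A [geometry_params()].
#' @return An object of class `scene_fluxes`: list with `flux_with_spark`,
#'   `flux_without_spark` (both `"flux"` spectra) and `distance_mm`.
#' @export
scene_fluxes <- function(L_base, L_spark, R_retro, g) {
  f2 <- baseline_flux(L_base, g)
  fr <- retro_flux(L_spark, R_retro, g)
  .check_same_grid(f2, fr)
  f1 <- new_spectrum(f2$wavelength_nm, f2$value + fr$value, "flux")
  structure(list(flux_with_spark = f1,
                 flux_without_spark = f2,
                 distance_mm = g$distance_mm),
            class = "scene_fluxes")
}

#' @export
print.scene_fluxes <- function(x, ...) {
  cat(sprintf("<scene_fluxes at %g mm>\n", x$distance_mm))
  cat(sprintf("  total flux with spark:    %.4g\n",
              integrate_spectrum(x$flux_with_spark)))
  cat(sprintf("  total flux without spark: %.4g\n",
              integrate_spectrum(x$flux_without_spark)))
  invisible(x)
}
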