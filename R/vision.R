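# Observer model: quantum catches of the triplefin's three cone channels
# and the two contrast metrics used to judge discriminability -- the
# receptor-noise-limited chromatic distance (in just-noticeable
# differences) and the achromatic Michelson contrast of the summed
# double-cone channel.

#' Visual system parameters
#'
#' @param sensitivities List of exactly three `"sensitivity"` spectra, in
#'   the order SWS single cone, MWS double-cone member, LWS double-cone
#'   member.
#' @param ocular_media `spectrum` of kind `"transmission"`: spectral
#'   transmission of the ocular media (lens and cornea).
#' @param cone_abundance Relative densities of the three channels
#'   (default `c(1, 4, 4)`: single to double cone members 1:4:4, as in the
#'   triplefin fovea).
#' @param weber_fraction Weber fraction omega of the most abundant cone
#'   class (default 0.05).  Channel noise is
#'   `e_i = omega * sqrt(eta_max / eta_i)`.
#' @param chromatic_threshold_jnd Chromatic detection threshold in JND
#'   (default 1.0).
#' @param achromatic_threshold Michelson contrast detection threshold
#'   (default 0.008).
#' @return An object of class `visual_system`.
#' @export
visual_system <- function(sensitivities, ocular_media,
                          cone_abundance = c(1, 4, 4),
                          weber_fraction = 0.05,
                          chromatic_threshold_jnd = 1.0,
                          achromatic_threshold = 0.008) {
  if (!is.list(sensitivities) || length(sensitivities) != 3L)
    stop("exactly three sensitivity spectra are required (SWS, MWS, LWS)")
  for (s in sensitivities) {
    stopifnot(inherits(s, "spectrum"))
    if (s$kind != "sensitivity")
      stop("sensitivities must be spectra of kind 'sensitivity'")
  }
  stopifnot(inherits(ocular_media, "spectrum"))
  if (ocular_media$kind != "transmission")
    stop("ocular_media must be a transmission spectrum")
  if (length(cone_abundance) != 3L || any(cone_abundance <= 0))
    stop("cone_abundance must be three positive numbers")
  if (weber_fraction <= 0) stop("weber_fraction must be > 0")
  if (chromatic_threshold_jnd < 0 || achromatic_threshold < 0)
    stop("thresholds must be nonnegative")
  names(sensitivities) <- c("sws", "mws", "lws")
  structure(list(sensitivities = sensitivities,
                 ocular_media = ocular_media,
                 cone_abundance = as.numeric(cone_abundance),
                 weber_fraction = weber_fraction,
                 chromatic_threshold_jnd = chromatic_threshold_jnd,
                 achromatic_threshold = achromatic_threshold),
            class = "visual_system")
}

#' Default triplefin-like visual system
#'
#' Builds a [visual_system()] from A1 pigment templates and a sigmoidal
#' short-wave ocular media cutoff.  The lambda-max values (SWS 468, MWS
#' 516, LWS 530 nm) are documented placeholders standing in for measured
#' curves, and should be overridden when real sensitivities are available.
#'
#' @param lambda_max_nm Three pigment peaks in nm (SWS, MWS, LWS).
#' @param media_cutoff_nm,media_slope_nm Midpoint and slope of the
#'   sigmoidal ocular-media transmission (defaults 410 and 8 nm).
#' @param wavelength_nm Working grid.
#' @param ... Passed on to [visual_system()] (abundances, Weber fraction,
#'   thresholds).
#' @return A `visual_system`.
#' @export
default_visual_system <- function(lambda_max_nm = c(468, 516, 530),
                                  media_cutoff_nm = 410,
                                  media_slope_nm = 8,
                                  wavelength_nm = default_wavelengths(),
                                  ...) {
  sens <- lapply(lambda_max_nm, make_pigment_sensitivity,
                 wavelength_nm = wavelength_nm)
  tr <- 1 / (1 + exp(-(wavelength_nm - media_cutoff_nm) / media_slope_nm))
  media <- new_spectrum(wavelength_nm, tr, "transmission")
  visual_system(sens, media, ...)
}

#' Per-cone quantum catches
#'
#' q_i = sum over lambda of flux(lambda) * T_ocular(lambda) *
#' S_i(lambda) * dlambda, the rectangle-rule integral over the working
#' range.  Linear in the flux.
#'
#' @param flux `spectrum` of kind `"flux"` (or any radiometric kind) at
#'   the observer's pupil.
#' @param vsp A [visual_system()].
#' @return Named numeric vector `c(sws=, mws=, lws=)` of class
#'   `quantum_catches`.
#' @export
quantum_catch <- function(flux, vsp) {
  stopifnot(inherits(flux, "spectrum"), inherits(vsp, "visual_system"))
  tm <- resample_spectrum(vsp$ocular_media, flux$wavelength_nm)
  step <- spectrum_step(flux)
  q <- vapply(vsp$sensitivities, function(s) {
    s <- resample_spectrum(s, flux$wavelength_nm)
    sum(flux$value * tm$value * s$value) * step
  }, numeric(1))
  structure(q, class = "quantum_catches")
}

.as_catches <- function(q) {
  q <- unclass(q)
  if (length(q) != 3L) stop("quantum catches must have three channels")
  if (is.null(names(q))) names(q) <- c("sws", "mws", "lws")
  q
}

#' Achromatic Michelson contrast
#'
#' C = (Q1 - Q2) / (Q1 + Q2), where Q_k is the sum of the quantum catches
#' of the two double-cone members (MWS + LWS) -- the achromatic channel --
#' under scene 1 and scene 2.  The SWS single cone is ignored.
#'
#' @param qc1,qc2 `quantum_catches` under the two scenes (conventionally
#'   spark on and spark off).
#' @return Michelson contrast in (-1, 1); nonnegative whenever scene 1
#'   dominates scene 2 pointwise.
#' @export
michelson_contrast <- function(qc1, qc2) {
  q1 <- .as_catches(qc1); q2 <- .as_catches(qc2)
  Q1 <- q1[["mws"]] + q1[["lws"]]
  Q2 <- q2[["mws"]] + q2[["lws"]]
  if (Q1 + Q2 == 0)
    stop("Michelson contrast undefined: both achromatic catches are zero")
  (Q1 - Q2) / (Q1 + Q2)
}

#' Receptor-noise-limited chromatic contrast
#'
#' Trichromatic Vorobyev--Osorio log-form receptor-noise model.  Channel
#' signals are f_i = ln(q_i1 / q_i2); channel noise is
#' e_i = omega * sqrt(eta_max / eta_i) with eta the relative cone
#' abundances (the reported Weber fraction is anchored to the most
#' abundant class); and
#'
#'   dS = sqrt( (e1^2 (f2 - f3)^2 + e2^2 (f1 - f3)^2 + e3^2 (f1 - f2)^2)
#'              / ((e1 e2)^2 + (e1 e3)^2 + (e2 e3)^2) )
#'
#' in units of just-noticeable differences: values above 1 exceed the
#' minimum discernible difference.  The two double-cone members enter as
#' independent channels.
#'
#' @param qc1,qc2 `quantum_catches` under the two scenes; all six catches
#'   must be strictly positive (the log signal is undefined at zero).
#' @param vsp A [visual_system()] supplying abundances and the Weber
#'   fraction.
#' @return Chromatic distance in JND (nonnegative).
#' @export
rnl_chromatic_contrast <- function(qc1, qc2, vsp) {
  stopifnot(inherits(vsp, "visual_system"))
  q1 <- .as_catches(qc1); q2 <- .as_catches(qc2)
  if (any(q1 <= 0) || any(q2 <= 0))
    stop("all quantum catches must be > 0 for the log-form RNL model")
  eta <- vsp$cone_abundance
  e <- vsp$weber_fraction * sqrt(max(eta) / eta)
  f <- log(q1 / q2)
  num <- e[1]^2 * (f[2] - f[3])^2 +
         e[2]^2 * (f[1] - f[3])^2 +
         e[3]^2 * (f[1] - f[2])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  unname(sqrt(num / den))
}
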