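# Synthetic stand-ins for the field inputs: blue-shifted underwater
# ambient light, visual-pigment sensitivity templates, reflectance /
# radiance spectra of the spark and the scorpionfish eye, and
# treatment-dependent approach/retreat trajectories in a 50 cm arena.

#' Ambient light model
#'
#' Downwelling irradiance at depth, modelled as a surface spectrum
#' attenuated by a wavelength-dependent diffuse attenuation coefficient
#' K(lambda): E(lambda) = E0(lambda) * exp(-K(lambda) * depth).
#'
#' The default surface spectrum is flat (the absolute photon scale cancels
#' from both contrast metrics) and the default K rises steeply toward the
#' red with a mild short-wave rise, in the manner of clear coastal
#' (Jerlov-type) water, so that the 10 m spectrum is blue-green.
#'
#' @param surface_irradiance `spectrum` of kind `"irradiance"`; default a
#'   flat spectrum of 1 photon unit per nm.
#' @param attenuation_coeff `spectrum` of per-metre attenuation values
#'   (dimensionless per metre; carried with the `"reflectance"` tag since
#'   K is unbounded above).  Values must be nonnegative.
#' @param depth_m Depth in metres, `>= 0` (default 10, the tank depth the
#'   model emulates).
#' @return An object of class `ambient_model`.
#' @export
ambient_model <- function(surface_irradiance = NULL,
                          attenuation_coeff = NULL,
                          depth_m = 10) {
  if (is.null(surface_irradiance))
    surface_irradiance <- constant_spectrum(1, "irradiance")
  if (is.null(attenuation_coeff)) {
    wl <- surface_irradiance$wavelength_nm
    k <- 0.035 +
      ifelse(wl < 460, 0.05 * ((460 - wl) / 60)^2, 0) +
      ifelse(wl >= 460, 0.55 * ((wl - 460) / 240)^2.2, 0)
    attenuation_coeff <- new_spectrum(wl, k, "reflectance")
  }
  stopifnot(inherits(surface_irradiance, "spectrum"),
            surface_irradiance$kind == "irradiance",
            inherits(attenuation_coeff, "spectrum"))
  if (!is.numeric(depth_m) || length(depth_m) != 1L || depth_m < 0)
    stop("depth_m must be a single nonnegative number")
  if (any(attenuation_coeff$value < 0))
    stop("attenuation coefficients must be nonnegative")
  structure(list(surface_irradiance = surface_irradiance,
                 attenuation_coeff = attenuation_coeff,
                 depth_m = depth_m),
            class = "ambient_model")
}

#' Downwelling irradiance at depth
#'
#' Applies Beer--Lambert attenuation to the model's surface spectrum:
#' E(lambda) = E0(lambda) * exp(-K(lambda) * depth).
#'
#' @param model An [ambient_model()].
#' @return A `spectrum` of kind `"irradiance"` on the surface spectrum's
#'   grid.
#' @export
make_ambient <- function(model) {
  stopifnot(inherits(model, "ambient_model"))
  e0 <- model$surface_irradiance
  k <- resample_spectrum(model$attenuation_coeff, e0$wavelength_nm)
  new_spectrum(e0$wavelength_nm,
               e0$value * exp(-k$value * model$depth_m),
               "irradiance")
}

#' Visual-pigment spectral sensitivity template
#'
#' Generates an A1 visual-pigment absorbance curve (alpha band) from the
#' standard rhodopsin nomogram template of Govardovskii and colleagues,
#' normalised to peak at 1.  The beta band is omitted: for the lambda-max
#' values used here it lies below the 400 nm edge of the working range.
#'
#' @param lambda_max_nm Wavelength of peak sensitivity, in 330--650 nm.
#' @param wavelength_nm Output grid (default 400--700 nm).
#' @return A `spectrum` of kind `"sensitivity"` with values in \[0, 1\]
#'   and its maximum at `lambda_max_nm` (to within one grid step).
#' @export
make_pigment_sensitivity <- function(lambda_max_nm,
                                     wavelength_nm = default_wavelengths()) {
  if (!is.numeric(lambda_max_nm) || length(lambda_max_nm) != 1L ||
      lambda_max_nm < 330 || lambda_max_nm > 650)
    stop("lambda_max_nm must be a single value in [330, 650] nm")
  x <- lambda_max_nm / wavelength_nm
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; cc <- 1.104
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  s <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  s <- pmin(s / max(s), 1)
  new_spectrum(wavelength_nm, s, "sensitivity")
}

#' Synthetic reflectance / radiance-shape spectra
#'
#' Generates the surface spectra of the optical scene.  All shapes have a
#' maximum of 1 before scaling, so `level` is the peak value:
#' \describe{
#'   \item{`spark`}{blue-peaked (Gaussian bump near 465 nm over a flat
#'     floor), emulating the blue ocular spark.}
#'   \item{`retro_pupil`}{spectrally flat pupil retroreflectance relative
#'     to a diffuse white standard; `level` may exceed 1 (a
#'     retroreflector can return more light toward the source than a
#'     diffuse white surface does).}
#'   \item{`iris`}{flat-to-reddish diffuse iris reflectance.}
#'   \item{`baseline_pupil_radiance`}{diffuse-equivalent reflectance shape
#'     of the dim baseline eyeshine of an undisturbed scorpionfish pupil;
#'     tinted like the spark reflection (85 % spark shape, 15 % flat) so
#'     that the spark adds photons of nearly the spectral shape already
#'     present -- the documented default calibration that keeps chromatic
#'     shifts small.  Multiply by downwelling irradiance over pi (see
#'     [spark_radiance()]) to obtain a radiance.}
#' }
#'
#' @param kind One of `"spark"`, `"retro_pupil"`, `"iris"`,
#'   `"baseline_pupil_radiance"`.
#' @param level Peak value of the returned spectrum; must be `>= 0`.
#' @param peak_nm,width_nm Centre and e-folding half-width of the spark's
#'   Gaussian bump (defaults 465 and 75 nm); used by the `spark` and
#'   `baseline_pupil_radiance` shapes.
#' @param wavelength_nm Output grid.
#' @return A `spectrum` of kind `"reflectance"`.
#' @export
make_reflectance <- function(kind = c("spark", "retro_pupil", "iris",
                                      "baseline_pupil_radiance"),
                             level = 1, peak_nm = 465, width_nm = 75,
                             wavelength_nm = default_wavelengths()) {
  kind <- match.arg(kind)
  if (!is.numeric(level) || length(level) != 1L || level < 0)
    stop("level must be a single nonnegative number")
  wl <- wavelength_nm
  spark_shape <- 0.3 + 0.7 * exp(-((wl - peak_nm) / width_nm)^2)
  shape <- switch(kind,
    spark = spark_shape,
    retro_pupil = rep(1, length(wl)),
    iris = 0.5 + 0.5 * pmax((wl - 400) / 300, 0)^1.5,
    baseline_pupil_radiance = 0.85 * spark_shape + 0.15)
  shape <- shape / max(shape)
  new_spectrum(wl, level * shape, "reflectance")
}

#' Behavioural simulation configuration
#'
#' Parameters of the synthetic approach/retreat experiment: individuals
#' released at the arena midpoint in two hat treatments (`"clear"`, whose
#' ocular sparks remain visible, and `"shaded"`, whose sparks are masked),
#' measured at `n_timepoints` occasions up to `total_time_min`.  The
#' shaded arm starts `treatment_effect_cm` closer to the stimulus at the
#' first time point (the effect decays with time constant
#' `effect_decay_min`); both arms drift toward the far wall at an initial
#' `retreat_rate` cm per minute with quadratic-in-time saturation.
#' Residuals are Gaussian with within-individual AR1 correlation, and
#' distances are clipped to the arena.
#'
#' @param n_per_treatment Individuals per arm (default 40).
#' @param arena_length_cm Arena length (default 50).
#' @param release_point_cm Release distance from the stimulus (default 25).
#' @param n_timepoints Number of measurement occasions (default 7).
#' @param total_time_min Time of the last measurement (default 100).
#' @param treatment_effect_cm Expected extra closeness of the shaded arm
#'   at the first time point (default 8).
#' @param retreat_rate Initial drift toward the far wall, cm per minute
#'   (default 0.3).
#' @param ar1_rho Lag-one autocorrelation of within-individual residuals,
#'   in (-1, 1) (default 0.5).
#' @param noise_sd_cm Stationary residual standard deviation (default 10).
#' @param effect_decay_min Exponential decay time of the treatment effect
#'   (default 30).
#' @param seed Integer seed; the generator is fully reproducible given the
#'   configuration.
#' @return An object of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(n_per_treatment = 40,
                                arena_length_cm = 50,
                                release_point_cm = 25,
                                n_timepoints = 7,
                                total_time_min = 100,
                                treatment_effect_cm = 8,
                                retreat_rate = 0.3,
                                ar1_rho = 0.5,
                                noise_sd_cm = 10,
                                effect_decay_min = 30,
                                seed = 1L) {
  if (release_point_cm <= 0 || release_point_cm >= arena_length_cm)
    stop("release_point_cm must lie strictly inside the arena")
  if (n_timepoints < 1) stop("n_timepoints must be >= 1")
  if (abs(ar1_rho) >= 1) stop("ar1_rho must lie in (-1, 1)")
  if (noise_sd_cm < 0) stop("noise_sd_cm must be >= 0")
  if (n_per_treatment < 1) stop("n_per_treatment must be >= 1")
  structure(as.list(environment()), class = "behavior_sim_config")
}

#' Simulate approach/retreat distance records
#'
#' Draws per-individual distance trajectories under the configuration's
#' mean model plus clipped AR1 Gaussian noise.  Reproducible under a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param config A [behavior_sim_config()].
#' @return A data frame with columns `individual`, `treatment`
#'   (`"clear"`/`"shaded"`), `time_min` and `distance_cm` (clipped to
#'   \[0, arena_length_cm\]).
#' @export
simulate_behavior <- function(config = behavior_sim_config()) {
  stopifnot(inherits(config, "behavior_sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  tt <- if (config$n_timepoints == 1L) 1
        else seq(1, config$total_time_min, length.out = config$n_timepoints)
  T <- max(config$total_time_min, 1)
  # quadratic-in-time saturating drift: unit slope at t = 0
  drift <- config$retreat_rate * tt * (1 - tt / (2 * T))
  m_clear <- config$release_point_cm + drift
  m_shaded <- m_clear -
    config$treatment_effect_cm * exp(-(tt - tt[1L]) / config$effect_decay_min)

  one_arm <- function(means, prefix, treatment) {
    n <- config$n_per_treatment
    rho <- config$ar1_rho; sd <- config$noise_sd_cm
    out <- vector("list", n)
    for (i in seq_len(n)) {
      e <- numeric(length(tt))
      e[1L] <- stats::rnorm(1, 0, sd)
      if (length(tt) > 1L)
        for (j in 2:length(tt))
          e[j] <- rho * e[j - 1L] + stats::rnorm(1, 0, sd * sqrt(1 - rho^2))
      d <- pmin(pmax(means + e, 0), config$arena_length_cm)
      out[[i]] <- data.frame(
        individual = sprintf("%s%03d", prefix, i),
        treatment = treatment, time_min = tt, distance_cm = d)
    }
    do.call(rbind, out)
  }
  res <- rbind(one_arm(m_clear, "C", "clear"),
               one_arm(m_shaded, "S", "shaded"))
  rownames(res) <- NULL
  res
}
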