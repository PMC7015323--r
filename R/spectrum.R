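# Spectral data type shared by all pipeline stages.
#
# A `spectrum` is a wavelength-indexed nonnegative function on a uniform
# grid (default 400--700 nm at 1 nm), tagged with a `kind` that records
# what physical quantity it carries.  All pipeline arithmetic happens on
# the default grid after resampling at load time.

.spectrum_kinds <- c("radiance", "irradiance", "reflectance",
                     "transmission", "sensitivity", "flux")

# kinds that are dimensionless proportions
.dimless_kinds <- c("reflectance", "transmission", "sensitivity")

#' Default wavelength grid
#'
#' The visible-range grid on which all spectral computations are carried
#' out: 400 to 700 nm in 1 nm steps, closed at both ends (301 samples).
#'
#' @return Integer vector of wavelengths in nm.
#' @export
default_wavelengths <- function() 400:700

#' Construct a spectrum
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm; strictly
#'   increasing with a uniform step.
#' @param value Numeric vector of the same length.  Values must be finite
#'   and nonnegative.  `transmission` and `sensitivity` spectra must lie in
#'   \[0, 1\]; `reflectance` spectra may exceed 1 (retroreflectance is
#'   expressed relative to a diffuse white standard, so values above 1
#'   mean a return of more than 100 per cent).
#' @param kind One of `"radiance"` (photons s-1 m-2 sr-1 nm-1),
#'   `"irradiance"` (photons s-1 m-2 nm-1), `"reflectance"`,
#'   `"transmission"`, `"sensitivity"` (dimensionless) or `"flux"`
#'   (photons s-1 nm-1 at the observer's pupil).
#'
#' @return An object of class `spectrum`: a list with elements
#'   `wavelength_nm`, `value` and `kind`.
#' @examples
#' s <- new_spectrum(400:700, rep(1, 301), "irradiance")
#' integrate_spectrum(s)
#' @export
new_spectrum <- function(wavelength_nm, value, kind) {
  kind <- match.arg(kind, .spectrum_kinds)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least two wavelength samples")
  if (length(wavelength_nm) != length(value))
    stop("wavelength_nm and value must have the same length")
  if (anyNA(wavelength_nm) || anyNA(value) || any(!is.finite(value)))
    stop("spectrum values and wavelengths must be finite")
  dw <- diff(wavelength_nm)
  if (any(dw <= 0))
    stop("wavelengths must be strictly increasing")
  if (max(dw) - min(dw) > 1e-8 * max(dw))
    stop("wavelength grid must have a uniform step")
  # tolerate floating-point dust from arithmetic chains
  tiny <- -1e-9 * max(abs(value), 1e-300)
  if (any(value < tiny))
    stop("spectrum values must be nonnegative (kind '", kind, "')")
  value[value < 0] <- 0
  if (kind %in% c("transmission", "sensitivity") && any(value > 1 + 1e-9))
    stop(kind, " values must lie in [0, 1]")
  structure(list(wavelength_nm = wavelength_nm, value = value, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d samples, %g-%g nm (step %g)>\n",
              x$kind, length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), spectrum_step(x)))
  cat(sprintf("  value range: [%.4g, %.4g]\n", min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength_nm, value = x$value)
}

#' Grid step of a spectrum
#' @param s A `spectrum`.
#' @return The wavelength step in nm.
#' @export
spectrum_step <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  (max(s$wavelength_nm) - min(s$wavelength_nm)) / (length(s$wavelength_nm) - 1)
}

#' Coerce a two-column table to a spectrum
#'
#' @param x A data frame with columns `wavelength_nm` and `value` (or any
#'   two numeric columns, taken in order).
#' @param kind Spectrum kind tag; see [new_spectrum()].
#' @return A `spectrum`.
#' @export
as_spectrum <- function(x, kind) {
  if (inherits(x, "spectrum")) return(x)
  x <- as.data.frame(x)
  cols <- intersect(c("wavelength_nm", "value"), names(x))
  if (length(cols) == 2L) x <- x[cols] else x <- x[, 1:2]
  new_spectrum(x[[1L]], x[[2L]], kind)
}

#' Constant spectrum helper
#'
#' @param value Scalar value replicated across the grid.
#' @param kind Spectrum kind tag.
#' @param wavelength_nm Wavelength grid (default 400--700 nm).
#' @return A `spectrum`.
#' @export
constant_spectrum <- function(value, kind, wavelength_nm = default_wavelengths()) {
  new_spectrum(wavelength_nm, rep(value, length(wavelength_nm)), kind)
}

# resulting kind of a pointwise product; symmetric so that the product is
# commutative.  A dimensionless factor leaves the other kind unchanged;
# two dimensionless factors give a generic dimensionless result tagged
# "reflectance" (the only dimensionless kind free of a [0, 1] constraint).
.product_kind <- function(k1, k2) {
  if (k1 == k2) return(k1)
  d1 <- k1 %in% .dimless_kinds
  d2 <- k2 %in% .dimless_kinds
  if (d1 && d2) return("reflectance")
  if (d1) return(k2)
  if (d2) return(k1)
  stop("ambiguous product of spectrum kinds '", k1, "' and '", k2, "'")
}

.check_same_grid <- function(s, t) {
  if (length(s$wavelength_nm) != length(t$wavelength_nm) ||
      max(abs(s$wavelength_nm - t$wavelength_nm)) > 1e-8)
    stop("spectra are on different wavelength grids; resample first")
}

#' @export
Ops.spectrum <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/"))
    stop("operation '", .Generic, "' not defined for spectra")
  if (inherits(e1, "spectrum") && inherits(e2, "spectrum")) {
    .check_same_grid(e1, e2)
    v <- get(.Generic)(e1$value, e2$value)
    kind <- switch(.Generic,
      "+" = , "-" = {
        if (e1$kind != e2$kind)
          stop("cannot ", .Generic, " spectra of kinds '", e1$kind,
               "' and '", e2$kind, "'")
        e1$kind
      },
      "*" = .product_kind(e1$kind, e2$kind),
      "/" = "reflectance")
    return(new_spectrum(e1$wavelength_nm, v, kind))
  }
  s <- if (inherits(e1, "spectrum")) e1 else e2
  x <- if (inherits(e1, "spectrum")) e2 else e1
  if (!is.numeric(x) || length(x) != 1L)
    stop("spectrum arithmetic with non-scalar objects is not defined")
  v <- if (inherits(e1, "spectrum")) get(.Generic)(e1$value, x)
       else get(.Generic)(x, e2$value)
  new_spectrum(s$wavelength_nm, v, s$kind)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto `grid`; wavelengths outside the support of
#' `s` are zero-filled (sensitivities and transmissions outside their
#' measured range are treated as dark), never constant-extrapolated.
#'
#' @param s A `spectrum`.
#' @param grid Target wavelength grid (numeric, uniform step).
#' @return A `spectrum` on `grid` with the kind of `s` preserved.
#' @export
resample_spectrum <- function(s, grid = default_wavelengths()) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  lo <- max(min(s$wavelength_nm), min(grid))
  hi <- min(max(s$wavelength_nm), max(grid))
  if (lo > hi)
    stop(sprintf(
      "no overlap between spectrum range [%g, %g] nm and target grid [%g, %g] nm",
      min(s$wavelength_nm), max(s$wavelength_nm), min(grid), max(grid)))
  v <- stats::approx(s$wavelength_nm, s$value, xout = grid, rule = 1)$y
  v[is.na(v)] <- 0
  new_spectrum(grid, v, s$kind)
}

#' Integrate a spectrum over wavelength
#'
#' Rectangle-rule Riemann sum: the sum of the sampled values times the
#' grid step.  On the 1 nm default grid this is the "for each nanometre"
#' summation used throughout the quantum-catch pipeline.
#'
#' @param s A `spectrum` on a uniform grid.
#' @return Scalar integral (value units times nm).
#' @export
integrate_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  sum(s$value) * spectrum_step(s)
}

#' Read a spectrum from a CSV file
#'
#' Expects a two-column UTF-8 CSV with header `wavelength_nm,value`;
#' lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param kind Spectrum kind tag.  If `NULL`, a `# kind: <tag>` comment
#'   written by [write_spectrum_csv()] is honoured; otherwise an error.
#' @param grid Optional wavelength grid to resample onto after reading
#'   (required when the file's own grid is non-uniform).
#' @return A `spectrum`.
#' @export
read_spectrum_csv <- function(path, kind = NULL, grid = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (is.null(kind)) {
    km <- grep("^#\\s*kind:", raw, value = TRUE)
    if (length(km))
      kind <- trimws(sub("^#\\s*kind:", "", km[[1L]]))
    else
      stop("no 'kind' given and no '# kind:' comment found in ", path)
  }
  body <- raw[!startsWith(trimws(raw), "#") & nzchar(trimws(raw))]
  if (length(body) < 2L) stop("no data rows in ", path)
  hdr <- tolower(trimws(strsplit(body[[1L]], ",")[[1L]]))
  if (!identical(hdr[1:2], c("wavelength_nm", "value")))
    stop("expected header 'wavelength_nm,value' in ", path,
         " but found '", body[[1L]], "'")
  parts <- strsplit(body[-1L], ",")
  wl <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  va <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(wl) | is.na(va))
  if (length(bad))
    stop("non-numeric data in ", path, " at row(s) ",
         paste(bad + 1L, collapse = ", "))
  o <- order(wl)
  wl <- wl[o]; va <- va[o]
  dup <- which(duplicated(wl))
  if (length(dup))
    stop("duplicate wavelength(s) in ", path, ": ",
         paste(unique(wl[dup]), collapse = ", "))
  if (any(va < 0))
    stop("negative value(s) in ", path, " at row(s) ",
         paste(which(va < 0) + 1L, collapse = ", "),
         " (", kind, " spectra must be nonnegative)")
  dw <- diff(wl)
  if (max(dw) - min(dw) > 1e-8 * max(dw)) {
    if (is.null(grid))
      stop("wavelength grid in ", path,
           " is non-uniform; pass `grid` to resample on read")
    # interpolate from the raw non-uniform samples
    v <- stats::approx(wl, va, xout = grid, rule = 1)$y
    v[is.na(v)] <- 0
    return(new_spectrum(grid, v, kind))
  }
  s <- new_spectrum(wl, va, kind)
  if (!is.null(grid)) s <- resample_spectrum(s, grid)
  s
}

#' Write a spectrum to a CSV file
#'
#' Writes a `# kind:` comment line followed by `wavelength_nm,value` rows
#' at full double precision, so that a write-then-read round trip
#' reproduces the spectrum exactly.
#'
#' @param s A `spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  lines <- c(sprintf("# kind: %s", s$kind),
             "wavelength_nm,value",
             sprintf("%s,%s",
                     formatC(s$wavelength_nm, format = "g", digits = 17),
                     formatC(s$value, format = "g", digits = 17)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
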