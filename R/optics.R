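#' Relativistic electron wavelength
#'
#' de Broglie wavelength of an electron accelerated through `voltage_kv`
#' kilovolts, with the relativistic correction, using CODATA 2018 constants.
#'
#' @param voltage_kv accelerating voltage in kilovolts (> 0).
#' @return wavelength in Angstrom.  300 kV gives 0.019687 A.
#' @export
electron_wavelength <- function(voltage_kv) {
  if (any(!is.finite(voltage_kv)) || any(voltage_kv <= 0))
    stop("voltage must be positive")
  h <- 6.62607015e-34   # J s
  m0 <- 9.1093837015e-31 # kg
  e <- 1.602176634e-19  # C
  cl <- 299792458       # m/s
  v <- voltage_kv * 1e3
  lam_m <- h / sqrt(2 * m0 * e * v * (1 + e * v / (2 * m0 * cl^2)))
  lam_m * 1e10
}

#' Depth of focus at a given resolution
#'
#' The axial extent `L = 2 d^2 / lambda` over which the planar (flat Ewald
#' sphere) approximation holds at resolution `d`.  When a particle's diameter
#' exceeds `L`, sphere curvature matters for that resolution shell.
#'
#' @param resolution_d resolution in Angstrom (> 0).
#' @param wavelength electron wavelength in Angstrom (> 0).
#' @return depth of focus in Angstrom.
#' @export
depth_of_focus <- function(resolution_d, wavelength) {
  if (any(resolution_d <= 0) || any(wavelength <= 0))
    stop("resolution and wavelength must be positive")
  2 * resolution_d^2 / wavelength
}

#' Resolution at which Ewald-sphere curvature becomes material
#'
#' Within a particle the defocus varies over roughly `[-Rg, +Rg]`.  The
#' wavefront spread across that range reaches ~0.5 (i.e. +-0.25) at the
#' resolution `d* = sqrt(2 Rg lambda)`; beyond it the curvature must be
#' modelled.  At `d*`, `depth_of_focus(d*, lambda) = 4 Rg` exactly.
#'
#' @param radius_of_gyration particle radius of gyration in Angstrom (> 0).
#' @param wavelength electron wavelength in Angstrom (> 0).
#' @return threshold resolution `d*` in Angstrom.
#' @export
curvature_threshold_resolution <- function(radius_of_gyration, wavelength) {
  if (any(radius_of_gyration <= 0) || any(wavelength <= 0))
    stop("radius of gyration and wavelength must be positive")
  sqrt(2 * radius_of_gyration * wavelength)
}

#' Electron-optical parameters
#'
#' Bundles the microscope constants used throughout the pipeline.  The
#' wavelength is derived from the voltage and cached; `lambda_scale`
#' multiplies it, which exaggerates Ewald curvature for desk-scale synthetic
#' experiments (1 for physical optics).  Spherical aberration and amplitude
#' contrast are carried for metadata round trips but ignored by the
#' quadratic wavefront model.
#'
#' @param voltage_kv accelerating voltage, kilovolts.
#' @param pixel_size detector pixel size, Angstrom per pixel.
#' @param spherical_aberration_mm Cs in millimetres (metadata only).
#' @param amplitude_contrast fractional amplitude contrast (metadata only).
#' @param lambda_scale multiplier applied to the physical wavelength;
#'   0 selects the planar (flat-sphere, zero CTF phase) testing limit.
#' @return an object of class `ewald_optics`.
#' @export
ewald_optics <- function(voltage_kv, pixel_size,
                         spherical_aberration_mm = 2.7,
                         amplitude_contrast = 0.07,
                         lambda_scale = 1) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (lambda_scale < 0) stop("lambda_scale must be non-negative")
  structure(list(
    voltage_kv = voltage_kv,
    wavelength = electron_wavelength(voltage_kv) * lambda_scale,
    lambda_scale = lambda_scale,
    pixel_size = pixel_size,
    spherical_aberration_mm = spherical_aberration_mm,
    amplitude_contrast = amplitude_contrast
  ), class = "ewald_optics")
}

#' @export
print.ewald_optics <- function(x, ...) {
  cat(sprintf("<ewald_optics> %g kV (lambda %.6g A%s), %g A/px\n",
              x$voltage_kv, x$wavelength,
              if (x$lambda_scale != 1)
                sprintf(", scale x%g", x$lambda_scale) else "",
              x$pixel_size))
  invisible(x)
}

#' Defocus wavefront phase grid
#'
#' Evaluates the quadratic wavefront `W(k) = -z lambda k^2 / 2` (positive
#' defocus = underfocus) as a phase `phi = 2 pi W` on the centred 2D
#' frequency grid of an even `box_size`.  Higher-order aberrations are
#' deliberately not modelled.
#'
#' @param optics an [ewald_optics()] object.
#' @param defocus defocus z in Angstrom for this particle.
#' @param box_size image box size in pixels (even, >= 8).
#' @return object of class `wavefront_field` with elements `phase`
#'   (box x box matrix, radians, centred layout), `defocus_used`,
#'   `wavelength`, `pixel_size`.
#' @export
compute_wavefront <- function(optics, defocus, box_size) {
  stopifnot(inherits(optics, "ewald_optics"))
  if (box_size < 8 || box_size %% 2 != 0)
    stop("box_size must be even and >= 8")
  dk <- 1 / (box_size * optics$pixel_size)
  ax <- (seq_len(box_size) - 1 - box_size / 2) * dk
  k2 <- outer(ax^2, ax^2, `+`)
  structure(list(
    phase = -pi * defocus * optics$wavelength * k2,
    defocus_used = defocus,
    wavelength = optics$wavelength,
    pixel_size = optics$pixel_size
  ), class = "wavefront_field")
}

#' Apply the wavefront as a phase-shift correction
#'
#' Multiplies the image Fourier transform by `exp(+i phi(k))`, undoing the
#' `exp(-i phi)` the microscope applied to the Ewald-sphere term.  This is a
#' pure phase correction: amplitudes are untouched (no Wiener division).
#'
#' @param image_ft complex matrix (centred layout) — FT of a boxed particle.
#' @param wavefront a `wavefront_field` from [compute_wavefront()] (a bare
#'   phase matrix is also accepted).
#' @return phase-corrected complex matrix of the same shape.
#' @export
phase_correct_image <- function(image_ft, wavefront) {
  phase <- if (inherits(wavefront, "wavefront_field")) wavefront$phase else wavefront
  if (!identical(dim(image_ft), dim(phase)))
    stop("image and wavefront grids have different shapes")
  image_ft * exp(.ewald_const$phase_correction_sign * 1i * phase)
}

#' Hermite / anti-Hermite factorization of a Fourier grid
#'
#' Splits a complex grid `F` into `H(k) = (F(k) + conj(F(-k)))/2` and
#' `A(k) = (F(k) - conj(F(-k)))/2`, the Fourier equivalents of the real and
#' imaginary parts of the corresponding real-space image.  `H + A == F`
#' exactly; the Nyquist rows are their own Friedel partners.
#'
#' @param corrected_ft complex matrix (even box, centred or unshifted
#'   layout — the mirror indexing is identical for both).
#' @param pixel_size optional pixel size carried along, Angstrom.
#' @return object of class `component_images` with elements `hermite`,
#'   `antihermite`, `box`, `pixel_size`.
#' @export
factorize_components <- function(corrected_ft, pixel_size = NA_real_) {
  cm <- conj_mirror(corrected_ft)
  structure(list(
    hermite = (corrected_ft + cm) / 2,
    antihermite = (corrected_ft - cm) / 2,
    box = nrow(corrected_ft),
    pixel_size = pixel_size
  ), class = "component_images")
}
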