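#' Optical configuration for RGB CCP-BRM image formation
#'
#' Bundles the wavelengths and incident intensity used by the Jones-calculus
#' forward model. CCP-BRM images a birefringent sample between opposite-handed
#' circular polarizers, each built from a linear polarizer and a quarter-wave
#' plate (QWP). The QWP is exact only at its design wavelength `lambda0`;
#' detuning at the red and blue camera bands is what converts fiber
#' orientation into color.
#'
#' @param lambda0 QWP design wavelength in nm. The green band of the camera is
#'   assumed to sit on the design wavelength (green-band circular polarizers),
#'   so `lambda_g` defaults to `lambda0`.
#' @param lambda_r,lambda_g,lambda_b Effective center wavelengths (nm) of the
#'   camera's R, G and B channels.
#' @param i0 Incident intensity after the first linear polarizer (arbitrary
#'   units, > 0). Transmitted intensities lie in `[0, i0]`.
#' @return An object of class `optical_config`.
#' @examples
#' opt <- optical_config()
#' opt$lambda_g == opt$lambda0
#' @export
optical_config <- function(lambda0 = 550, lambda_r = 610, lambda_g = lambda0,
                           lambda_b = 470, i0 = 1) {
  stopifnot(lambda0 > 0, lambda_r > 0, lambda_g > 0, lambda_b > 0, i0 > 0)
  structure(list(lambda0 = lambda0, lambda_r = lambda_r, lambda_g = lambda_g,
                 lambda_b = lambda_b, i0 = i0),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> lambda0 = %g nm | RGB = %g/%g/%g nm | i0 = %g\n",
    x$lambda0, x$lambda_r, x$lambda_g, x$lambda_b, x$i0))
  invisible(x)
}

#' Retardance of a birefringent fiber
#'
#' Phase delay accumulated between the ordinary and extraordinary rays of a
#' uniaxial birefringent medium: `delta = 2 * pi * d * delta_n / lambda`,
#' with the thickness `d` (um) and wavelength (nm) reduced to a common length
#' unit before dividing.
#'
#' @param thickness_d Fiber thickness in micrometers (> 0). Vectorized.
#' @param delta_n Birefringence index difference `n_e - n_o` (>= 0,
#'   dimensionless). Vectorized.
#' @param wavelength Wavelength in nanometers (> 0).
#' @return Phase delay in radians.
#' @examples
#' retardance(1, 0.275, 550)  # = pi
#' @export
retardance <- function(thickness_d, delta_n, wavelength) {
  if (any(thickness_d <= 0)) stop("thickness_d must be > 0")
  if (any(delta_n < 0)) stop("delta_n must be >= 0")
  if (any(wavelength <= 0)) stop("wavelength must be > 0")
  2 * pi * (thickness_d * 1000) * delta_n / wavelength
}

#' Quarter-wave plate retardance off the design wavelength
#'
#' Zero-order plate model: the plate's optical path difference is fixed at
#' `lambda0 / 4`, so its phase retardance at wavelength `lambda` is
#' `Gamma = (pi / 2) * lambda0 / lambda` — exactly `pi/2` at the design
#' wavelength, larger for shorter (bluer) wavelengths and smaller for longer
#' (redder) ones.
#'
#' @param wavelength Wavelength in nm (> 0). Vectorized.
#' @param lambda0 Design wavelength in nm (> 0).
#' @return QWP retardance in radians.
#' @examples
#' qwp_retardance(550, 550)  # pi/2
#' qwp_retardance(1100, 550) # pi/4
#' @export
qwp_retardance <- function(wavelength, lambda0) {
  if (any(wavelength <= 0) || any(lambda0 <= 0))
    stop("wavelengths must be > 0")
  (pi / 2) * lambda0 / wavelength
}

#' Transmitted intensity between detuned crossed circular polarizers
#'
#' Intensity of the Jones chain linear polarizer (0 deg) -> QWP(`gamma`) at
#' +45 deg -> sample linear retarder(`delta`, axis `theta`) -> QWP(`gamma`)
#' at -45 deg -> crossed linear polarizer (90 deg), with `i0` the intensity
#' entering the first QWP. The closed form is
#'
#'   `I = i0 * sin^2(delta / 2) * (1 - cos^2(gamma) * cos^2(2 * theta))`
#'
#' At `gamma = pi/2` (ideal QWPs) this is `i0 * sin^2(delta/2)` for every
#' orientation: birefringent fibers are bright on a dark background with no
#' extinction positions. Detuned plates (`gamma != pi/2`) re-introduce an
#' orientation-dependent factor, which is the color-encoding mechanism of the
#' RGB implementation.
#'
#' @param delta Sample retardance in radians. Vectorized.
#' @param theta In-plane optic-axis orientation in radians. Vectorized.
#' @param gamma QWP retardance in radians (see [qwp_retardance()]).
#' @param i0 Incident intensity (> 0).
#' @return Transmitted intensity in `[0, i0]`.
#' @examples
#' ccp_intensity(pi, 0.7, pi / 2, 1)  # = 1, orientation-invariant
#' @export
ccp_intensity <- function(delta, theta, gamma, i0 = 1) {
  if (any(i0 <= 0)) stop("i0 must be > 0")
  i0 * sin(delta / 2)^2 * (1 - cos(gamma)^2 * cos(2 * theta)^2)
}

#' Per-channel QWP retardances for an optical configuration
#'
#' @param optics An [optical_config()].
#' @return Named numeric vector of QWP retardances (radians) for the R, G and
#'   B channels.
#' @keywords internal
channel_gammas <- function(optics) {
  c(r = qwp_retardance(optics$lambda_r, optics$lambda0),
    g = qwp_retardance(optics$lambda_g, optics$lambda0),
    b = qwp_retardance(optics$lambda_b, optics$lambda0))
}
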