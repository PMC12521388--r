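#' Pseudo-Voigt line shape
#'
#' Height-normalised Gaussian--Lorentzian mixture used throughout the
#' package for both synthetic Bragg reflections and Raman bands.
#' `eta = 1` is a pure Lorentzian, `eta = 0` a pure Gaussian; both
#' components share the same full width at half maximum.
#'
#' @param x Numeric vector of abscissa values (q in 1/Angstrom or
#'   wavenumber in 1/cm).
#' @param center Peak position, same units as `x`.
#' @param height Peak maximum.
#' @param fwhm Full width at half maximum, same units as `x`.
#' @param eta Lorentzian fraction in `[0, 1]`.
#' @return Numeric vector of intensities, same length as `x`.
#' @examples
#' q <- seq(0.05, 0.08, by = 5e-4)
#' y <- pseudo_voigt(q, center = 0.0633, height = 1, fwhm = 0.0025)
#' @export
pseudo_voigt <- function(x, center, height, fwhm, eta = 0.5) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  u2 <- ((x - center) / (fwhm / 2))^2
  height * (eta / (1 + u2) + (1 - eta) * exp(-log(2) * u2))
}

#' Analytic area of a pseudo-Voigt peak
#'
#' @inheritParams pseudo_voigt
#' @return The integral of the line shape over the whole real line.
#' @export
pseudo_voigt_area <- function(height, fwhm, eta = 0.5) {
  height * fwhm * (eta * pi / 2 + (1 - eta) * sqrt(pi / (4 * log(2))))
}

#' X-ray photon energy to wavelength
#'
#' Converts photon energy in keV to wavelength in Angstrom via
#' lambda = hc / E with hc = 12.3984198 keV A.
#'
#' @param energy_kev Photon energy in keV.
#' @return Wavelength in Angstrom.
#' @examples
#' kev_to_wavelength(20.137) # 0.6157 A
#' @export
kev_to_wavelength <- function(energy_kev) {
  stopifnot(all(energy_kev > 0))
  12.39841984 / energy_kev
}
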