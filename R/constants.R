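#' Physical constants used throughout the package
#'
#' Returns the set of physical constants entering the dielectric model and
#' the free-water statistic. The 3-digit values (Boltzmann constant, water
#' dipole moment, Avogadro number, molar concentration of liquid water) are
#' the conventional rounded values used in THz hydration work; they are kept
#' at that precision deliberately so that published free-water fractions are
#' reproduced on their own terms rather than drifting with CODATA updates.
#'
#' @param temperature_K solution temperature in kelvin (default 298.15, i.e.
#'   25 degrees Celsius).
#' @return A named list with elements
#'   \describe{
#'     \item{k}{Boltzmann constant, 1.38e-23 J/K}
#'     \item{eps0}{vacuum permittivity, 8.8541878128e-12 F/m}
#'     \item{p}{electric dipole moment of a water molecule, 6.17e-30 C m}
#'     \item{N_A}{Avogadro constant, 6.02e23 / mol}
#'     \item{N_water}{number density of water molecules,
#'       N_A x 55.56e3 molecules/m^3}
#'     \item{c_cm}{speed of light, cm/s}
#'     \item{T}{temperature, K}
#'   }
#' @export
#' @examples
#' physical_constants()$N_water
physical_constants <- function(temperature_K = 298.15) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  list(
    k       = 1.38e-23,
    eps0    = 8.8541878128e-12,
    p       = 6.17e-30,
    N_A     = 6.02e23,
    N_water = 6.02e23 * 55.56e3,
    c_cm    = 2.99792458e10,
    T       = temperature_K
  )
}

#' Convert wavenumber to angular frequency
#'
#' omega = 2 pi c nu, with nu in cm^-1 and c in cm/s, giving omega in rad/s.
#' All external interfaces of the package use wavenumbers in cm^-1; internal
#' evaluation of the dielectric model converts to angular frequency through
#' this function exactly once.
#'
#' @param wavenumber_cm wavenumber(s) in cm^-1, strictly positive.
#' @return angular frequency in rad/s.
#' @seealso [angular_to_wavenumber()]
#' @export
wavenumber_to_angular <- function(wavenumber_cm) {
  if (any(!is.finite(wavenumber_cm)) || any(wavenumber_cm <= 0)) {
    stop("wavenumbers must be finite and strictly positive")
  }
  2 * pi * physical_constants()$c_cm * wavenumber_cm
}

#' Convert angular frequency to wavenumber
#'
#' Inverse of [wavenumber_to_angular()].
#'
#' @param omega angular frequency in rad/s, strictly positive.
#' @return wavenumber in cm^-1.
#' @export
angular_to_wavenumber <- function(omega) {
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    stop("angular frequencies must be finite and strictly positive")
  }
  omega / (2 * pi * physical_constants()$c_cm)
}
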