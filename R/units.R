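#' Physical constants and unit conversions
#'
#' The package works throughout in GROMACS-style units: lengths in nm, times
#' in ps, masses in amu, energies in kJ/mol, temperatures in K.  In these
#' units 1 amu nm^2/ps^2 = 1 kJ/mol, so kinetic energies and correlation
#' matrix entries are directly comparable to `kB * T`.
#'
#' @format `kB` is the Boltzmann constant in kJ/mol/K; `SPEED_OF_LIGHT_CM_PS`
#'   is c in cm/ps, the factor connecting angular frequencies in 1/ps to
#'   wavenumbers in cm^-1 via `omega = 2*pi*c*nu`.
#' @name constants
NULL

#' @rdname constants
#' @export
kB <- 0.0083144621

#' @rdname constants
#' @export
SPEED_OF_LIGHT_CM_PS <- 0.0299792458

#' Convert between wavenumber, frequency and oscillation period
#'
#' Low-frequency vibrational spectroscopy quotes mode positions in
#' wavenumbers (cm^-1).  These helpers convert a wavenumber to a linear
#' frequency in THz (`nu_THz = nu_cm * c`), to an angular frequency in 1/ps,
#' and to the corresponding oscillation period in ps.  For example 10 cm^-1
#' corresponds to roughly 0.3 THz, i.e. one oscillation every ~3 ps.
#'
#' @param nu_cm wavenumber in cm^-1
#' @return a numeric scalar/vector in the requested unit
#' @examples
#' wavenumber_to_thz(10)       # ~0.2998 THz
#' wavenumber_to_period_ps(10) # ~3.34 ps
#' @export
wavenumber_to_thz <- function(nu_cm) {
  nu_cm * SPEED_OF_LIGHT_CM_PS # cm^-1 * cm/ps = 1/ps = THz
}

#' @rdname wavenumber_to_thz
#' @export
wavenumber_to_period_ps <- function(nu_cm) {
  1 / wavenumber_to_thz(nu_cm)
}

#' @rdname wavenumber_to_thz
#' @export
wavenumber_to_angular_ps <- function(nu_cm) {
  2 * pi * SPEED_OF_LIGHT_CM_PS * nu_cm
}

#' @rdname wavenumber_to_thz
#' @export
angular_ps_to_wavenumber <- function(omega) {
  omega / (2 * pi * SPEED_OF_LIGHT_CM_PS)
}
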