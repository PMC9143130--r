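#' Physical constants and unit conversions
#'
#' All energies inside the package are kcal/mol, distances Angstrom,
#' times ps, temperatures Kelvin.  Inputs in kJ/mol must be converted at
#' the boundary with [kj_to_kcal()].
#'
#' @format `KB_KCAL` is the Boltzmann constant in kcal/mol/K;
#'   `KCAL_PER_KJ` the kJ -> kcal factor (1 kcal = 4.184 kJ);
#'   `COULOMB_KCAL` the Coulomb constant in kcal*A/mol/e^2.
#' @name constants
NULL

#' @rdname constants
#' @export
KB_KCAL <- 0.0019872041

#' @rdname constants
#' @export
KCAL_PER_KJ <- 1 / 4.184

#' @rdname constants
#' @export
COULOMB_KCAL <- 332.0636

#' Convert kJ/mol to kcal/mol
#'
#' @param x numeric, energy (or force constant) in kJ-based units.
#' @return numeric in kcal-based units.
#' @examples
#' kj_to_kcal(2500)  # the default umbrella force constant, 597.51 kcal/mol/A^2
#' @export
kj_to_kcal <- function(x) x * KCAL_PER_KJ

#' @rdname kj_to_kcal
#' @export
kcal_to_kj <- function(x) x * 4.184

#' Thermal energy kT in kcal/mol
#'
#' @param temperature temperature in K (default 310, body temperature used
#'   throughout the inhibition simulations).
#' @return kT in kcal/mol.
#' @export
kT <- function(temperature = 310) KB_KCAL * temperature

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
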