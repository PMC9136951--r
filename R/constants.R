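#' Physical constants used throughout the package
#'
#' Units are fixed package-wide: lengths in Angstrom, energies in kJ/mol,
#' temperatures in Kelvin, charges in units of the elementary charge.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.0083144626 kJ mol^-1 K^-1.}
#'   \item{coulomb}{Coulomb constant, 138.935458 kJ mol^-1 A e^-2.}
#'   \item{hardcore_dist}{Site-site separations below this (1e-6 A) signal a
#'     hard-core overlap and short-circuit to an infinite-energy sentinel.}
#' }
#' @export
wn_constants <- list(
  kB = 0.0083144626,
  coulomb = 138.935458,
  hardcore_dist = 1e-6
)

#' Thermodynamic beta at temperature T
#' @param T temperature in Kelvin.
#' @return 1/(kB T) in mol/kJ.
#' @keywords internal
wn_beta <- function(T) {
  stopifnot(is.numeric(T), T > 0)
  1 / (wn_constants$kB * T)
}
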