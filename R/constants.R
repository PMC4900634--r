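#' Physical constants and unit conversions
#'
#' The package works in a single unit system throughout: length in angstrom
#' (A), time in picoseconds (ps), energy in kcal/mol, charge in units of the
#' elementary charge (e), temperature in Kelvin, mass in atomic mass units
#' (amu). All conversion factors live here and nowhere else.
#'
#' * `coulomb`: Coulomb constant, 332.0636 kcal*A/(mol*e^2), so the energy of
#'   two unit charges 1 A apart is 332.0636 kcal/mol.
#' * `ev_per_volt_angstrom`: 23.0609 kcal/(mol*A) per e*(V/A); converts the
#'   product of a charge (e) and an electric field (V/A) into a force in
#'   kcal/(mol*A).
#' * `kB`: Boltzmann constant, 0.0019872041 kcal/(mol*K).
#' * `kcal_to_amu_A2_ps2`: 418.4; 1 kcal/mol expressed in amu*A^2/ps^2, used
#'   to convert forces into accelerations inside the integrator.
#'
#' @return A named list of the constants above.
#' @export
#' @examples
#' pk_constants()$coulomb
pk_constants <- function() {
  list(
    coulomb = 332.0636,
    ev_per_volt_angstrom = 23.0609,
    kB = 0.0019872041,
    kcal_to_amu_A2_ps2 = 418.4
  )
}
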