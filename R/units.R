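#' Unit system constants
#'
#' The package works in \enc{Å}{A} (length), ps (time), g/mol (mass),
#' kcal/mol (interaction energy) and kelvin.  With these choices one
#' "mass-velocity-squared" unit, g/mol \eqn{\cdot} (\enc{Å}{A}/ps)\eqn{^2},
#' equals 1/418.4 kcal/mol, so kinetic energy in kcal/mol is
#' \eqn{\sum_i m_i v_i^2 / 2 / 418.4}.
#'
#' Dynamical (internal) forces are carried in g/mol \enc{Å}{A}/ps\eqn{^2}:
#' this is the unit in which the low-frequency force reconstruction from
#' position averages is natural, and in which the random-force variance is
#' literally \eqn{2\gamma m k_B T/\delta t} with `kB_int`.
#' Force-field routines return kcal/mol/\enc{Å}{A}; multiply by
#' `mv2_per_kcal` to obtain internal forces.
#'
#' @format A list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.0019872041 kcal/mol/K.}
#'   \item{mv2_per_kcal}{418.4 g/mol (\enc{Å}{A}/ps)\eqn{^2} per kcal/mol.}
#'   \item{kB_int}{`kB * mv2_per_kcal`, Boltzmann constant in internal
#'     energy units per kelvin (numerically the gas constant in
#'     g/mol \enc{Å}{A}\eqn{^2}/ps\eqn{^2}/K).}
#' }
#' @export
#' @examples
#' sg_units$kB * 300   # kB T at 300 K in kcal/mol
sg_units <- list(
  kB           = 0.0019872041,
  mv2_per_kcal = 418.4,
  kB_int       = 0.0019872041 * 418.4
)
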