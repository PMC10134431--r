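#' Physical constants and unit conversions
#'
#' All internal arithmetic uses Hartree atomic units (hbar = 1, energies in
#' Hartree, lengths in Bohr, masses in electron masses). Conversions happen at
#' I/O boundaries only.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{ha_per_ev}{Hartree per electronvolt.}
#'   \item{ev_per_ha}{Electronvolt per Hartree (27.2114).}
#'   \item{bohr_per_ang}{Bohr per Angstrom.}
#'   \item{au_per_debye}{Atomic units of dipole per Debye (0.3934303).}
#'   \item{au_per_fs}{Atomic time units per femtosecond (41.3414).}
#'   \item{me_per_amu}{Electron masses per unified atomic mass unit.}
#' }
#' @export
#' @examples
#' 2.72 * polhop_units$ha_per_ev   # cavity photon energy, Hartree
polhop_units <- list(
  ev_per_ha    = 27.2114,
  ha_per_ev    = 1 / 27.2114,
  bohr_per_ang = 1 / 0.529177210903,
  ang_per_bohr = 0.529177210903,
  au_per_debye = 0.3934303,
  au_per_fs    = 41.3414,
  me_per_amu   = 1822.888486
)
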