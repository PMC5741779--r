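## Physical constants pinned in one place so every module agrees bit-for-bit.
## Electrostatics is evaluated in atomic units (e, bohr, hartree) and reported
## in the units the field prints: kcal mol^-1 per unit probe charge.

.HARTREE_KCALMOL <- 627.509474
.BOHR_ANGSTROM   <- 0.5291772109
.ANGSTROM_BOHR   <- 1 / .BOHR_ANGSTROM

#' Unit-conversion constants used by the package
#'
#' All potentials are evaluated in atomic units (charge in e, length in bohr,
#' potential in hartree/e) and converted once on output. The constants are
#' pinned here so that every module, test and file writer agrees exactly.
#'
#' @return A named list with elements `hartree_to_kcalmol` (627.509474 kcal
#'   mol^-1 per hartree), `bohr_to_angstrom` (0.5291772109 Å per bohr) and
#'   `angstrom_to_bohr` (its reciprocal).
#' @examples
#' # Coulomb potential of a unit charge at 1 Å, in kcal mol^-1 e^-1:
#' k <- field_constants()
#' k$hartree_to_kcalmol * k$bohr_to_angstrom   # 332.0637
#' @export
field_constants <- function() {
  list(
    hartree_to_kcalmol = .HARTREE_KCALMOL,
    bohr_to_angstrom   = .BOHR_ANGSTROM,
    angstrom_to_bohr   = .ANGSTROM_BOHR
  )
}
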