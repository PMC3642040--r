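#' Physical constants and unit helpers
#'
#' All internal coordinates and lengths are in nanometres; energies in
#' kJ/mol; times in picoseconds; temperatures in Kelvin.  Angstroms appear
#' only at PDB I/O and in user-facing gate/distance reports, matching the
#' conventions of structural biology figures.
#'
#' @name gatedyn-units
NULL

#' Boltzmann constant in kJ mol^-1 K^-1
#' @export
KB_KJMOL <- 0.0083145

#' Thermal energy kT in kJ/mol
#'
#' @param temperature temperature in Kelvin (default 310, physiological).
#' @return kT in kJ/mol (2.5775 kJ/mol at 310 K).
#' @export
kT <- function(temperature = 310) KB_KJMOL * temperature

# nm <-> Angstrom; PDB files store Angstrom
NM_PER_ANG <- 0.1
ANG_PER_NM <- 10

`%||%` <- function(a, b) if (is.null(a)) b else a
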