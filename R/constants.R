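#' Physical constants used throughout the package
#'
#' Internal units are nm for lengths, nm^-1 for momentum transfer and
#' e/nm^3 for electron-density contrasts (published tables in e/A^3 are
#' multiplied by 1000 on ingest).
#'
#' @name constants
NULL

#' Electron density of a liquid from bulk properties
#'
#' Number of electrons per nm^3 of a liquid, computed from its mass
#' density, electrons per molecule and molar mass.
#'
#' @param density_g_cm3 Mass density in g/cm^3. Default 0.997 (water near
#'   25 C).
#' @param electrons_per_molecule Electrons per molecule. Default 10 (H2O).
#' @param molar_mass Molar mass in g/mol. Default 18.015 (H2O).
#' @return Electron density in e/nm^3.
#' @examples
#' water_electron_density()        # ~333 e/nm^3
#' @export
water_electron_density <- function(density_g_cm3 = 0.997,
                                   electrons_per_molecule = 10,
                                   molar_mass = 18.015) {
  stopifnot(density_g_cm3 > 0, electrons_per_molecule > 0, molar_mass > 0)
  avogadro <- 6.02214076e23
  # molecules per nm^3 = (g/cm^3) / (g/mol) * N_A * 1e-21
  density_g_cm3 / molar_mass * avogadro * 1e-21 * electrons_per_molecule
}

# Solvent electron density used for bead contrasts: the conventional SAXS
# value for water, e/nm^3.
WATER_ELECTRON_DENSITY <- 334

# Monomer molecular weight of n-dodecyl-beta-maltoside (DDM), Da.
DDM_MONOMER_MW <- 510.6
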