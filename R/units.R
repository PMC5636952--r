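# Internal unit system: Angstrom, femtosecond, kcal/mol, amu, elementary charge.
# All conversion constants live here; nothing else hard-codes units.

#' Physical constants and unit conversions
#'
#' Named constants used throughout the package. Internal units are Angstrom
#' (length), femtosecond (time), kcal/mol (energy), atomic mass unit (mass)
#' and elementary charge (charge); dipole moments are reported in Debye.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/mol/K.}
#'   \item{kcal_per_internal}{kcal/mol per amu*A^2/fs^2 (2390.057...).}
#'   \item{debye_per_eA}{Debye per e*Angstrom (4.80320).}
#'   \item{cm1_per_invfs}{Wavenumbers (cm^-1) per inverse femtosecond.}
#' }
#' @export
nnpir_constants <- list(
  kB = 0.0019872041,
  # 1 amu A^2/fs^2 = 1e7 J/mol -> kcal/mol
  kcal_per_internal = 1e7 / 4184,
  debye_per_eA = 4.80320,
  # f [1/fs] / c [cm/fs]; c = 2.99792458e-5 cm/fs
  cm1_per_invfs = 1 / 2.99792458e-5
)

# Standard atomic masses (amu) for the elements the surrogates and examples use.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45
)

# Covalent radii (Angstrom, Cordero 2008) for bond perception.
.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, Cl = 1.02
)

# Standard X-H bond lengths (Angstrom) for capping hydrogens.
.cap_bond_lengths <- c(C = 1.09, N = 1.01, O = 0.96)

#' Look up standard atomic masses
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of masses in amu.
#' @export
atomic_masses <- function(elements) {
  m <- .atomic_masses[elements]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
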