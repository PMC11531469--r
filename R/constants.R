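#' @keywords internal
"_PACKAGE"

#' @useDynLib cgfork, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd integrate rnorm runif setNames
#' @importFrom utils head tail write.table read.table
NULL

## Internal unit system: length A, energy kcal/mol, mass amu.
## The intrinsic time unit is then sqrt(amu * A^2 * mol / kcal) = 48.89 fs,
## so the default 0.3-unit timestep corresponds to ~14.7 fs.

# Boltzmann constant, kcal/mol/K
KB <- 0.0019872

# Coulomb constant e^2 * NA / (4 pi eps0 * 1 A), in kcal*A/(mol*e^2).
# Derived from CODATA-2018 exact constants:
#   e = 1.602176634e-19 C, NA = 6.02214076e23 /mol,
#   eps0 = 8.8541878128e-12 F/m, 1 kcal = 4184 J.
KE_COULOMB <- 1.602176634e-19^2 * 6.02214076e23 /
  (4 * pi * 8.8541878128e-12 * 1e-10 * 4184)

# amu -> kg, elementary charge (C), eps0 (F/m), SI Boltzmann (J/K)
.EC_SI <- 1.602176634e-19
.EPS0_SI <- 8.8541878128e-12
.KB_SI <- 1.380649e-23
.NA_SI <- 6.02214076e23

# Intrinsic time unit in femtoseconds (documentation/metadata only)
TIME_UNIT_FS <- sqrt(1.66053906660e-27 * 1e-20 / (4184 / 6.02214076e23)) * 1e15

# Uniform bead mass: every coarse-grained site carries the average
# residue mass (amu). Equilibrium sampling is mass independent; this value
# only sets the stable-timestep scale.
BEAD_MASS <- 137.0

#' Debye screening length
#'
#' Computes the Debye length of a monovalent electrolyte from the ionic
#' strength, solvent dielectric constant and temperature.
#'
#' @param ionic_strength Ionic strength in mol/L.
#' @param dielectric Relative dielectric constant (dimensionless).
#' @param temperature Temperature in K.
#' @return Debye length in Angstrom.
#' @examples
#' debye_length(0.3, 78.0, 300) # ~5.6 A at physiological-like screening
#' @export
debye_length <- function(ionic_strength, dielectric, temperature) {
  stopifnot(ionic_strength > 0, dielectric > 0, temperature > 0)
  lambda_m <- sqrt(.EPS0_SI * dielectric * .KB_SI * temperature /
                     (2 * .NA_SI * .EC_SI^2 * ionic_strength * 1000))
  lambda_m * 1e10
}
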