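## Physical constants and unit conversions used throughout the package.
## Internal unit system: length in Angstrom, energy in kcal/mol, charge in
## elementary charges (e), mass in amu, time in fs.

## Coulomb constant: U = kCoulomb * q1*q2 / (eps * r)  [kcal/mol], r in A.
.kCoulomb <- 332.0636

## Boltzmann constant, kcal/(mol K).
.kBoltz <- 0.0019872041

## Avogadro constant, 1/mol.
.nAvogadro <- 6.02214076e23

## Acceleration conversion: a[A/fs^2] = .accConv * F[kcal/mol/A] / m[amu].
.accConv <- 4.184e-4

## kcal/mol/A per molecule expressed in piconewton.
## 1 kcal/mol/A = 4184 J/mol/A = 4184/(N_A * 1e-10 m) N = 69.48 pN.
.pNPerKcalMolA <- 4184 / (.nAvogadro * 1e-10) * 1e12

#' Convert a force from kcal/mol/A to piconewton
#'
#' Forces in this package are carried in kcal/mol/A, the unit in which
#' grid-derived steering forces naturally emerge. One kcal/mol/A corresponds
#' to 69.48 pN per molecule, so the conventional minimal steering force of
#' 0.01 kcal/mol/A is about 0.7 pN.
#'
#' @param f numeric vector of forces in kcal/mol/A.
#' @return numeric vector of forces in pN.
#' @examples
#' kcalPerMolAToPN(0.01)  # ~0.7 pN
#' @export
kcalPerMolAToPN <- function(f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  f * .pNPerKcalMolA
}

## Debye screening parameter squared, A^-2, for a 1:1 salt of ionic
## strength `molar` (mol/L) in a solvent of dielectric eps at temperature T.
.debyeKappaSq <- function(molar, eps, temperature) {
  if (molar <= 0) return(0)
  nDensity <- molar * .nAvogadro / 1e27   # ions/A^3 per unit ionic strength
  8 * pi * .kCoulomb * nDensity / (eps * .kBoltz * temperature)
}
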