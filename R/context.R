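# Physical constants (CODATA 2018). Fixed here so that every report can
# state exactly which values entered the computation.
.kB <- 1.380649e-23        # Boltzmann constant, J K^-1
.e_charge <- 1.602176634e-19 # elementary charge, C
.avogadro <- 6.02214076e23 # Avogadro constant, mol^-1
.eps0 <- 8.8541878128e-12  # vacuum permittivity, F m^-1

#' Physical context for hydrodynamic and electrokinetic formulas
#'
#' Bundles the solvent/thermodynamic state shared by every hydrodynamic and
#' electrokinetic computation: absolute temperature, solvent dynamic
#' viscosity, relative permittivity and solvent density. The defaults
#' describe aqueous NaCl at 298 K and reproduce standard Debye lengths and
#' Stokes-Einstein diameters for dilute electrolytes.
#'
#' @param temperature Absolute temperature in K.
#' @param viscosity Solvent dynamic viscosity in Pa s.
#' @param rel_permittivity Relative permittivity (dimensionless, > 1).
#' @param solvent_density Solvent density in kg m^-3.
#'
#' @return An object of class `physical_context`.
#' @examples
#' ctx <- physical_context()
#' ctx$temperature
#' @export
physical_context <- function(temperature = 298.15,
                             viscosity = 0.890e-3,
                             rel_permittivity = 78.5,
                             solvent_density = 997) {
  stopifnot(temperature > 0, viscosity > 0, rel_permittivity > 1,
            solvent_density > 0)
  structure(
    list(temperature = temperature,
         viscosity = viscosity,
         rel_permittivity = rel_permittivity,
         solvent_density = solvent_density),
    class = "physical_context")
}

#' @export
print.physical_context <- function(x, ...) {
  cat("Physical context\n")
  cat(sprintf("  temperature:        %.2f K\n", x$temperature))
  cat(sprintf("  solvent viscosity:  %.3g Pa s\n", x$viscosity))
  cat(sprintf("  rel. permittivity:  %.1f\n", x$rel_permittivity))
  cat(sprintf("  solvent density:    %.1f kg m^-3\n", x$solvent_density))
  invisible(x)
}

# Absolute permittivity of the solvent, F m^-1.
solvent_permittivity <- function(ctx) .eps0 * ctx$rel_permittivity

#' Polymer species parameters
#'
#' Per-monomer constants identifying a polymer species for the slender-body
#' analysis: the monomer molar mass, the monomer length along the fully
#' extended chain, and the extended-chain diameter.
#'
#' @param name Text label for the species.
#' @param M1 Monomer molar mass in kg mol^-1.
#' @param lm Monomer length for the extended chain in nm.
#' @param dc Extended-chain diameter in nm.
#'
#' @return An object of class `polymer_spec`.
#' @examples
#' parg <- poly_l_arginine()
#' parg$M1
#' @export
polymer_spec <- function(name, M1, lm, dc) {
  stopifnot(is.character(name), length(name) == 1L,
            M1 > 0, lm > 0, dc > 0)
  structure(list(name = name, M1 = M1, lm = lm, dc = dc),
            class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf("Polymer species: %s\n", x$name))
  cat(sprintf("  monomer molar mass M1: %.4g kg mol^-1\n", x$M1))
  cat(sprintf("  monomer length lm:     %.4g nm\n", x$lm))
  cat(sprintf("  chain diameter dc:     %.4g nm\n", x$dc))
  cat(sprintf("  mass-per-aspect Cm:    %.4g kg mol^-1\n", mass_per_aspect(x)))
  invisible(x)
}

#' Molar-mass-per-aspect-ratio constant of a polymer species
#'
#' The proportionality constant `Cm = M1 * dc / lm` linking the chain aspect
#' ratio to the molar mass of the rodlike molecule, in kg mol^-1 per unit of
#' aspect ratio.
#'
#' @param polymer A [polymer_spec()].
#' @param dc Optional chain diameter override in nm; the constant scales
#'   linearly with the diameter actually realized at a given ionic strength.
#' @return Numeric scalar, kg mol^-1.
#' @examples
#' mass_per_aspect(poly_l_arginine())
#' @export
mass_per_aspect <- function(polymer, dc = polymer$dc) {
  stopifnot(inherits(polymer, "polymer_spec"), dc > 0)
  polymer$M1 * dc / polymer$lm
}

#' Poly-L-arginine species constants
#'
#' Convenience constructor for poly-L-arginine: monomer molar mass
#' 0.174 kg mol^-1, extended-chain monomer length 0.333 nm and
#' extended-chain diameter 0.84 nm.
#'
#' @return A [polymer_spec()].
#' @export
poly_l_arginine <- function() {
  polymer_spec("poly-L-arginine", M1 = 0.174, lm = 0.333, dc = 0.84)
}

#' Physical constants used by the package
#'
#' Returns the fixed fundamental constants every computation in the package
#' uses, for inclusion in reports and provenance records.
#'
#' @return Named list with `kB` (J K^-1), `e` (C), `NA` (mol^-1) and
#'   `eps0` (F m^-1).
#' @export
polyrod_constants <- function() {
  list(kB = .kB, e = .e_charge, `NA` = .avogadro, eps0 = .eps0)
}
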