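# Density dilution method: solute density from the slope of the
# solvent-to-solution density ratio against mass fraction, and the
# geometric quantities (monomer/molecule volumes, cylinder and sphere
# dimensions) that follow from it.

#' Density dilution series
#'
#' Measured solution densities at known solute mass fractions, together
#' with the pure-solvent density.
#'
#' @param mass_fraction Solute mass fractions (dimensionless, `0 <= wp < 0.05`).
#' @param density Measured system densities in kg m^-3, same length.
#' @param solvent_density Pure-solvent density in kg m^-3.
#' @return An object of class `density_series`.
#' @export
density_series <- function(mass_fraction, density, solvent_density) {
  stopifnot(length(mass_fraction) == length(density),
            length(mass_fraction) >= 3,
            all(mass_fraction >= 0), all(mass_fraction < 0.05),
            all(density > 0), solvent_density > 0)
  structure(
    list(mass_fraction = mass_fraction, density = density,
         solvent_density = solvent_density),
    class = "density_series")
}

#' @export
print.density_series <- function(x, ...) {
  cat(sprintf("Density dilution series: %d points, wp up to %.3g\n",
              length(x$mass_fraction), max(x$mass_fraction)))
  invisible(x)
}

#' Slope of the density dilution line
#'
#' Fits `rho_sol / rho_sys = 1 + sp * wp` by least squares with the
#' intercept fixed at 1 (the ratio is exactly 1 at zero solute by
#' construction) and returns the slope `sp`. A free-intercept diagnostic
#' fit is returned alongside for inspection.
#'
#' @param series A [density_series()].
#' @return A list with `slope`, `stderr` (standard error of the slope) and
#'   `diagnostic` (free-intercept coefficients `c(intercept, slope)`).
#' @examples
#' wp <- seq(0, 5e-4, length.out = 6)
#' rho <- 997 / (1 + (997 / 1488 - 1) * wp)
#' dilution_slope(density_series(wp, rho, 997))$slope # -0.33
#' @export
dilution_slope <- function(series) {
  stopifnot(inherits(series, "density_series"))
  wp <- series$mass_fraction
  if (diff(range(wp)) == 0) {
    stop("all mass fractions identical; slope is unidentifiable",
         call. = FALSE)
  }
  y <- series$solvent_density / series$density - 1
  fit <- stats::lm(y ~ 0 + wp)
  diag_fit <- stats::lm(y ~ wp)
  list(slope = stats::coef(fit)[[1]],
       stderr = summary(fit)$coefficients[1, 2],
       diagnostic = stats::coef(diag_fit))
}

#' Solute density from the dilution slope
#'
#' `rho_p = rho_sol / (1 + sp)`.
#'
#' @param sp Dilution slope (dimensionless, > -1).
#' @param rho_sol Solvent density in kg m^-3.
#' @return Solute density in kg m^-3.
#' @examples
#' solute_density(-0.33, 997) # ~1488
#' @export
solute_density <- function(sp, rho_sol) {
  stopifnot(rho_sol > 0)
  if (any(sp <= -1)) {
    stop("dilution slope must exceed -1", call. = FALSE)
  }
  rho_sol / (1 + sp)
}

#' Monomer volume from monomer molar mass and solute density
#'
#' `v1 = 1e27 * M1 / (NA * rho_p)`, in nm^3.
#'
#' @param M1 Monomer molar mass in kg mol^-1.
#' @param rho_p Solute density in kg m^-3.
#' @return Monomer volume in nm^3.
#' @examples
#' monomer_volume(0.174, 1580) # ~0.183
#' @export
monomer_volume <- function(M1, rho_p) {
  stopifnot(M1 > 0, rho_p > 0)
  1e27 * M1 / (.avogadro * rho_p)
}

#' Molecule volume from molar mass and solute density
#'
#' `vm = 1e27 * Mn / (rho_p * NA)`, in nm^3. Same formula as
#' [monomer_volume()] applied to the whole-molecule molar mass.
#'
#' @param Mn Molecule (number-average) molar mass in kg mol^-1.
#' @param rho_p Solute density in kg m^-3.
#' @return Molecule volume in nm^3.
#' @examples
#' molecule_volume(42, 1500) # ~46.5
#' @export
molecule_volume <- function(Mn, rho_p) {
  monomer_volume(Mn, rho_p)
}

#' Average number of monomers in a molecule
#'
#' `Nm = Mn / M1`; the unrounded ratio is returned, with the rounded
#' integer attached as attribute `"rounded"` for display.
#'
#' @param Mn Molecule molar mass in kg mol^-1.
#' @param M1 Monomer molar mass in kg mol^-1.
#' @return Monomer count (numeric, unrounded).
#' @examples
#' monomer_count(42, 0.174) # ~241
#' @export
monomer_count <- function(Mn, M1) {
  stopifnot(Mn > 0, M1 > 0)
  n <- Mn / M1
  attr(n, "rounded") <- round(n)
  n
}

#' Extended chain length from the cylinder model
#'
#' Length of the cylinder with volume `vp` and diameter `dc`:
#' `Le = 4 vp / (pi dc^2)`.
#'
#' @param vp Molecule volume in nm^3.
#' @param dc Chain diameter in nm.
#' @return Extended length in nm.
#' @examples
#' extended_length_cylinder(46.5, 0.84) # ~84
#' @export
extended_length_cylinder <- function(vp, dc) {
  stopifnot(vp > 0, dc > 0)
  4 * vp / (pi * dc^2)
}

#' Extended chain length from the monomer count
#'
#' `Le = Nm * lm`: monomer count times the per-monomer length of the
#' extended chain.
#'
#' @param Nm Monomer count (> 0).
#' @param lm Monomer length in nm.
#' @return Extended length in nm.
#' @examples
#' extended_length_from_monomers(241, 0.333) # ~80
#' @export
extended_length_from_monomers <- function(Nm, lm) {
  stopifnot(all(Nm > 0), lm > 0)
  Nm * lm
}

#' Diameter of the sphere with a given volume
#'
#' `ds = (6 vp / pi)^(1/3)`.
#'
#' @param vp Volume in nm^3.
#' @return Sphere diameter in nm.
#' @examples
#' equivalent_sphere_diameter(46.5) # ~4.46
#' @export
equivalent_sphere_diameter <- function(vp) {
  stopifnot(all(vp > 0))
  (6 * vp / pi)^(1 / 3)
}

#' Read a density dilution series from CSV
#'
#' Expects columns `mass_fraction` and `density_kg_m3`.
#'
#' @param path CSV file path.
#' @param solvent_density Pure-solvent density in kg m^-3.
#' @return A [density_series()].
#' @export
read_density_csv <- function(path, solvent_density) {
  df <- read_csv_checked(path, c("mass_fraction", "density_kg_m3"))
  density_series(mass_fraction = df$mass_fraction,
                 density = df$density_kg_m3,
                 solvent_density = solvent_density)
}
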