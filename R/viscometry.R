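# Dilute-solution viscometry: the Huggins-type extrapolation of reduced
# specific viscosity to infinite dilution, whose intercept is the intrinsic
# viscosity in the volume-fraction convention.

#' Viscosity dilution series
#'
#' Container for a capillary-viscometry dilution series: mass
#' concentrations and measured solution viscosities, together with the
#' solvent viscosity and the solute density needed to convert
#' concentrations into volume fractions.
#'
#' @param conc Mass concentrations in kg m^-3 (equivalently g L^-1),
#'   strictly increasing, >= 0.
#' @param viscosity Solution dynamic viscosities in Pa s, same length.
#' @param solvent_viscosity Solvent dynamic viscosity in Pa s.
#' @param solute_density Solute density in kg m^-3 (from densitometry).
#' @param ionic_strength Optional ionic strength in mol L^-1 (metadata).
#'
#' @return An object of class `viscosity_series`.
#' @export
viscosity_series <- function(conc, viscosity, solvent_viscosity,
                             solute_density, ionic_strength = NA_real_) {
  stopifnot(length(conc) == length(viscosity), length(conc) >= 3,
            all(conc >= 0), all(diff(conc) > 0), all(viscosity > 0),
            solvent_viscosity > 0, solute_density > 0)
  rel <- viscosity / solvent_viscosity
  if (any(rel >= 1.2)) {
    warning(sum(rel >= 1.2), " record(s) with relative viscosity >= 1.2; ",
            "outside the dilute regime and excluded from fits",
            call. = FALSE)
  }
  structure(
    list(conc = conc, viscosity = viscosity,
         solvent_viscosity = solvent_viscosity,
         solute_density = solute_density,
         ionic_strength = ionic_strength),
    class = "viscosity_series")
}

#' @export
print.viscosity_series <- function(x, ...) {
  cat(sprintf("Viscosity dilution series: %d points, c = %.3g-%.3g kg m^-3\n",
              length(x$conc), min(x$conc), max(x$conc)))
  cat(sprintf("  solvent viscosity %.3g Pa s, solute density %.4g kg m^-3\n",
              x$solvent_viscosity, x$solute_density))
  invisible(x)
}

#' Solute volume fraction from mass concentration
#'
#' `Phi_V = cb / rho_p`: the volume fraction occupied by solute of mass
#' concentration `cb` and density `rho_p`.
#'
#' @param cb Mass concentration in kg m^-3 (>= 0). Vectorized.
#' @param rho_p Solute density in kg m^-3.
#' @return Volume fraction (dimensionless).
#' @examples
#' volume_fraction(0.5, 1500)
#' @export
volume_fraction <- function(cb, rho_p) {
  stopifnot(rho_p > 0, all(cb >= 0))
  cb / rho_p
}

#' Intrinsic viscosity from a dilution series
#'
#' Computes the reduced specific viscosity
#' `(eta_p/eta_e - 1) / Phi_V` for every record and fits an ordinary
#' least-squares line against the volume fraction. The intercept is the
#' intrinsic viscosity in the volume-fraction convention (2.5 for hard
#' spheres) and the slope is the quadratic (Huggins-type) coefficient
#' `kH * [eta]^2` of the concentration expansion.
#'
#' Records with relative viscosity at or above 1.2 lie outside the dilute
#' regime the expansion assumes and are excluded with a warning. Plotting
#' the reduced specific viscosity (rather than the raw relative viscosity)
#' removes the dominant linear term and makes the extrapolation to zero
#' concentration far more precise.
#'
#' @param series A [viscosity_series()].
#' @param weights Optional per-record fit weights (default unweighted).
#' @return A list with `eta` (the intrinsic viscosity), `huggins_slope`
#'   (slope of reduced viscosity vs volume fraction), `stderr` (standard
#'   error of the intercept), `n_used` and `n_excluded`.
#' @examples
#' phi <- seq(5e-5, 3.3e-4, length.out = 8)
#' eta_r <- 1 + 490 * phi + 0.3 * (490 * phi)^2
#' s <- viscosity_series(phi * 1500, eta_r * 8.9e-4, 8.9e-4, 1500)
#' intrinsic_viscosity_fit(s)$eta
#' @export
intrinsic_viscosity_fit <- function(series, weights = NULL) {
  stopifnot(inherits(series, "viscosity_series"))
  rel <- series$viscosity / series$solvent_viscosity
  phi <- volume_fraction(series$conc, series$solute_density)
  keep <- rel < 1.2 & phi > 0
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    warning("excluding ", n_excl, " record(s): relative viscosity >= 1.2 ",
            "or zero concentration", call. = FALSE)
  }
  phi <- phi[keep]
  rel <- rel[keep]
  if (length(phi) < 3) {
    stop("fewer than 3 usable records after exclusions", call. = FALSE)
  }
  if (diff(range(phi)) == 0) {
    stop("all volume fractions identical; intercept is unidentifiable",
         call. = FALSE)
  }
  reduced <- (rel - 1) / phi
  fit <- if (is.null(weights)) {
    stats::lm(reduced ~ phi)
  } else {
    stats::lm(reduced ~ phi, weights = weights[keep])
  }
  sm <- summary(fit)
  list(eta = stats::coef(fit)[[1]],
       huggins_slope = stats::coef(fit)[[2]],
       stderr = sm$coefficients[1, 2],
       n_used = length(phi),
       n_excluded = n_excl)
}

#' Read a viscosity dilution series from CSV
#'
#' Expects columns `conc_mg_per_L` and `viscosity_mPa_s`; concentrations
#' are converted to kg m^-3 and viscosities to Pa s.
#'
#' @param path CSV file path.
#' @param solvent_viscosity_mPas Solvent viscosity in mPa s.
#' @param solute_density Solute density in kg m^-3.
#' @param ionic_strength Optional ionic strength in mol L^-1.
#' @return A [viscosity_series()].
#' @export
read_viscosity_csv <- function(path, solvent_viscosity_mPas,
                               solute_density, ionic_strength = NA_real_) {
  df <- read_csv_checked(path, c("conc_mg_per_L", "viscosity_mPa_s"))
  viscosity_series(conc = df$conc_mg_per_L * 1e-3,
                   viscosity = df$viscosity_mPa_s * 1e-3,
                   solvent_viscosity = solvent_viscosity_mPas * 1e-3,
                   solute_density = solute_density,
                   ionic_strength = ionic_strength)
}
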