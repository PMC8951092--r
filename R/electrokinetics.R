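# Electrokinetics of dilute macroion solutions: Debye screening,
# Stokes-Einstein sizing, Lorentz-Stokes effective charge, ionization
# degree and the Henry-model zeta potential.

#' Debye screening length of a 1:1 electrolyte
#'
#' `kappa^-1 = sqrt(eps kB T / (2 e^2 NA * 1000 * I))` with
#' `eps = eps_r * eps0`; the double-layer thickness at ionic strength `I`.
#'
#' @param I Ionic strength in mol L^-1 (> 0). Vectorized.
#' @param ctx A [physical_context()].
#' @return Debye length in m.
#' @examples
#' debye_length(0.15) * 1e9 # ~0.786 nm
#' @export
debye_length <- function(I, ctx = physical_context()) {
  stopifnot(all(I > 0))
  eps <- solvent_permittivity(ctx)
  sqrt(eps * .kB * ctx$temperature /
         (2 * .e_charge^2 * .avogadro * 1000 * I))
}

#' Hydrodynamic diameter from a diffusion coefficient (Stokes-Einstein)
#'
#' `dH = kB T / (3 pi eta D)`; the algebraic inverse of
#' [diffusion_from_diameter()].
#'
#' @param D Diffusion coefficient in m^2 s^-1 (> 0). Vectorized.
#' @param ctx A [physical_context()].
#' @return Hydrodynamic diameter in m.
#' @examples
#' hydrodynamic_diameter_from_diffusion(2.9e-11) * 1e9 # ~17 nm
#' @export
hydrodynamic_diameter_from_diffusion <- function(D, ctx = physical_context()) {
  stopifnot(all(D > 0))
  .kB * ctx$temperature / (3 * pi * ctx$viscosity * D)
}

#' Electrokinetic charge from mobility (Lorentz-Stokes)
#'
#' `qe = kB T mu_e / D = 3 pi eta dH mu_e`: the effective charge carried by
#' a molecule of mobility `mu_e`, given either its diffusion coefficient or
#' its hydrodynamic diameter (exactly one of the two). The two routes agree
#' identically when `dH` is the Stokes-Einstein transform of `D`. The sign
#' of the charge follows the sign of the mobility.
#'
#' @param mu_e Electrophoretic mobility in m^2 V^-1 s^-1 (SI; use
#'   [mobility_to_si()] for instrument units).
#' @param D Diffusion coefficient in m^2 s^-1, or `NULL`.
#' @param dH Hydrodynamic diameter in m, or `NULL`.
#' @param ctx A [physical_context()].
#' @return Electrokinetic charge in C.
#' @examples
#' electrokinetic_charge(4.2e-8, D = 4.1e-11)
#' @export
electrokinetic_charge <- function(mu_e, D = NULL, dH = NULL,
                                  ctx = physical_context()) {
  if (is.null(D) == is.null(dH)) {
    stop("provide exactly one of D or dH", call. = FALSE)
  }
  if (!is.null(D)) {
    stopifnot(all(D > 0))
    .kB * ctx$temperature * mu_e / D
  } else {
    stopifnot(all(dH > 0))
    3 * pi * ctx$viscosity * dH * mu_e
  }
}

#' Number of elementary charges
#'
#' `Nc = qe / e` with `e` the elementary charge.
#'
#' @param qe Charge in C. Vectorized.
#' @return Charge number (dimensionless, signed).
#' @examples
#' charge_number(4.22e-18) # ~26
#' @export
charge_number <- function(qe) {
  qe / .e_charge
}

#' Effective ionization degree
#'
#' Fraction of ionizable monomers whose charge survives screening and
#' counterion condensation: `alpha = Nc / N_monomers`.
#'
#' @param Nc Electrokinetic charge number.
#' @param n_monomers Number of ionizable monomers (> 0).
#' @return Ionization degree (dimensionless); a warning is raised if it
#'   exceeds 1.
#' @examples
#' ionization_degree(40, 241) # ~0.17
#' @export
ionization_degree <- function(Nc, n_monomers) {
  stopifnot(all(n_monomers > 0), all(Nc >= 0))
  a <- Nc / n_monomers
  if (any(a > 1)) {
    warning("ionization degree exceeds 1: charge number larger than the ",
            "number of ionizable monomers", call. = FALSE)
  }
  a
}

#' Henry mobility correction factor
#'
#' Interpolates the electrophoretic mobility between the Hueckel
#' (`kappa a -> 0`, factor 1) and Smoluchowski (`kappa a -> Inf`, factor
#' 1.5) limits, computed with Ohshima's closed-form approximation
#'
#' \deqn{f(\kappa a) = 1 + \frac{1}{2\,[1 + 2.5 / (\kappa a (1 + 2 e^{-\kappa a}))]^3}}
#'
#' which is accurate to about 1% over the whole range.
#'
#' @param kappa_a Dimensionless product of inverse Debye length and
#'   particle radius (>= 0). Vectorized.
#' @return Correction factor in `[1, 1.5]`, monotonically increasing.
#' @examples
#' henry_factor(c(0, 1, 1e6))
#' @export
henry_factor <- function(kappa_a) {
  stopifnot(all(kappa_a >= 0))
  ifelse(kappa_a == 0, 1,
         1 + 0.5 / (1 + 2.5 / (kappa_a * (1 + 2 * exp(-kappa_a))))^3)
}

#' Zeta potential from mobility (Debye-Hueckel-Henry model)
#'
#' `zeta = 3 eta mu_e / (2 eps f(kappa a))` with `a = dH / 2` and the
#' Debye length from the ionic strength. Reduces to the Hueckel formula at
#' low `kappa a` and to the Smoluchowski formula at high `kappa a`.
#'
#' @param mu_e Electrophoretic mobility in m^2 V^-1 s^-1 (SI).
#' @param dH Hydrodynamic diameter in m (> 0).
#' @param I Ionic strength in mol L^-1 (> 0).
#' @param ctx A [physical_context()].
#' @return Zeta potential in V.
#' @examples
#' zeta_from_mobility(4.2e-8, 12e-9, 1e-4) # ~0.080 V
#' @export
zeta_from_mobility <- function(mu_e, dH, I, ctx = physical_context()) {
  stopifnot(all(dH > 0), all(I > 0))
  kappa_a <- (dH / 2) / debye_length(I, ctx)
  eps <- solvent_permittivity(ctx)
  3 * ctx$viscosity * mu_e / (2 * eps * henry_factor(kappa_a))
}

#' Convert mobility from instrument units to SI
#'
#' Electrophoresis instruments commonly report mobility in
#' um cm V^-1 s^-1; one such unit is 1e-8 m^2 V^-1 s^-1.
#'
#' @param mu_umcm Mobility in um cm V^-1 s^-1.
#' @return Mobility in m^2 V^-1 s^-1.
#' @examples
#' mobility_to_si(4.2)
#' @export
mobility_to_si <- function(mu_umcm) {
  mu_umcm * 1e-8
}

#' Electrokinetic characterization of a set of ionic-strength conditions
#'
#' For each condition (ionic strength, mobility, diffusion coefficient)
#' computes the Debye length, Stokes-Einstein hydrodynamic diameter, Henry
#' zeta potential, Lorentz-Stokes electrokinetic charge, charge number and
#' effective ionization degree.
#'
#' @param I Ionic strengths in mol L^-1.
#' @param mobility Electrophoretic mobilities in um cm V^-1 s^-1
#'   (instrument units), same length.
#' @param D Diffusion coefficients in m^2 s^-1, same length.
#' @param n_monomers Number of ionizable monomers per molecule, used for
#'   the ionization degree.
#' @param pH Optional pH metadata, recycled.
#' @param ctx A [physical_context()].
#' @return A data.frame with one row per condition and columns
#'   `ionic_strength_M`, `pH`, `mobility_umcm_per_Vs`, `diffusion_m2_per_s`,
#'   `debye_length_nm`, `hydrodynamic_diameter_nm`, `zeta_mV`, `charge_C`,
#'   `charge_number` and `ionization_degree`.
#' @examples
#' electrokinetic_table(I = 0.15, mobility = 2.1, D = 6.1e-11,
#'                      n_monomers = 241)
#' @export
electrokinetic_table <- function(I, mobility, D, n_monomers,
                                 pH = NA_real_, ctx = physical_context()) {
  stopifnot(length(I) == length(mobility), length(I) == length(D))
  mu_si <- mobility_to_si(mobility)
  dh <- hydrodynamic_diameter_from_diffusion(D, ctx)
  qe <- electrokinetic_charge(mu_si, D = D, ctx = ctx)
  nc <- charge_number(qe)
  data.frame(
    ionic_strength_M = I,
    pH = rep_len(pH, length(I)),
    mobility_umcm_per_Vs = mobility,
    diffusion_m2_per_s = D,
    debye_length_nm = debye_length(I, ctx) * 1e9,
    hydrodynamic_diameter_nm = dh * 1e9,
    zeta_mV = zeta_from_mobility(mu_si, dh, I, ctx) * 1e3,
    charge_C = qe,
    charge_number = nc,
    ionization_degree = ionization_degree(abs(nc), n_monomers))
}

#' Read electrokinetic measurements from CSV
#'
#' Expects columns `ionic_strength_M`, `pH`, `mobility_umcm_per_Vs` and
#' `diffusion_m2_per_s`.
#'
#' @param path CSV file path.
#' @return A data.frame with the four columns above.
#' @export
read_electrokinetics_csv <- function(path) {
  read_csv_checked(path, c("ionic_strength_M", "pH", "mobility_umcm_per_Vs",
                           "diffusion_m2_per_s"))
}
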