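# Seeded generators producing datasets with the statistical structure each
# analysis stage assumes, so every fit in the package can be validated
# end-to-end without instrument data. All generators are pure functions of
# (seed, arguments).

#' Generate a synthetic viscosity dilution series
#'
#' Emulates a capillary-viscometry dilution series: concentrations equally
#' spaced over 50-500 mg L^-1 and relative viscosities following the
#' dilute-solution expansion
#' `eta_r = 1 + eta * Phi_V + kH * (eta * Phi_V)^2`, with multiplicative
#' Gaussian noise on the specific-viscosity increment `eta_r - 1`. The
#' increment is what serial-dilution capillary viscometry resolves (the
#' solvent efflux time is measured in the same capillary and cancels), and
#' a ~1% relative error on it matches the ~1% precision the extrapolated
#' intrinsic viscosity achieves in practice; relative noise on the raw
#' solution viscosity would instead swamp the per-mille increments at the
#' dilute end of the series.
#'
#' @param eta True intrinsic viscosity.
#' @param kH Huggins coefficient (dimensionless, default 0.3, a typical
#'   polyelectrolyte value).
#' @param n_points Number of concentrations (>= 3).
#' @param noise Relative standard deviation of the noise on `eta_r - 1`.
#' @param solute_density Solute density in kg m^-3.
#' @param solvent_viscosity Solvent viscosity in Pa s.
#' @param conc_range Concentration range in kg m^-3 (default 0.05-0.5,
#'   i.e. 50-500 mg L^-1).
#' @param seed Integer seed; identical seed and arguments give identical
#'   output.
#' @return A [viscosity_series()].
#' @examples
#' s <- gen_viscometry(eta = 490, seed = 1)
#' intrinsic_viscosity_fit(s)$eta
#' @export
gen_viscometry <- function(eta, kH = 0.3, n_points = 10, noise = 0.01,
                           solute_density = 1500,
                           solvent_viscosity = 0.890e-3,
                           conc_range = c(0.05, 0.5), seed = 1) {
  stopifnot(eta > 0, kH >= 0, n_points >= 3, noise >= 0)
  conc <- seq(conc_range[1], conc_range[2], length.out = n_points)
  phi <- conc / solute_density
  eta_r <- 1 + eta * phi + kH * (eta * phi)^2
  if (noise > 0) {
    eta_r <- withr::with_seed(seed,
      1 + (eta_r - 1) * (1 + stats::rnorm(n_points, sd = noise)))
  }
  visc <- eta_r * solvent_viscosity
  viscosity_series(conc, visc, solvent_viscosity, solute_density)
}

#' Generate a synthetic density dilution series
#'
#' Mass fractions on a uniform grid up to 5e-4 and system densities from
#' the exact dilution relation `rho_sys = rho_sol / (1 + sp * wp)` with
#' `sp = rho_sol / rho_p - 1`, plus additive Gaussian noise at the stated
#' absolute level (default 5e-3 kg m^-3, a vibrating-tube densitometer
#' precision).
#'
#' @param rho_p True solute density in kg m^-3.
#' @param rho_sol Solvent density in kg m^-3.
#' @param n_points Number of mass fractions (>= 3).
#' @param noise Absolute density noise in kg m^-3.
#' @param wp_max Largest mass fraction.
#' @param seed Integer seed.
#' @return A [density_series()].
#' @examples
#' s <- gen_density_series(rho_p = 1488, seed = 1, noise = 0)
#' dilution_slope(s)$slope # -0.33
#' @export
gen_density_series <- function(rho_p, rho_sol = 997, n_points = 10,
                               noise = 5e-3, wp_max = 5e-4, seed = 1) {
  stopifnot(rho_p > 0, rho_sol > 0, n_points >= 3, noise >= 0)
  wp <- seq(0, wp_max, length.out = n_points)
  sp <- rho_sol / rho_p - 1
  rho_sys <- rho_sol / (1 + sp * wp)
  if (noise > 0) {
    rho_sys <- withr::with_seed(seed,
      rho_sys + stats::rnorm(n_points, sd = noise))
  }
  density_series(wp, rho_sys, rho_sol)
}

# One frame of a correlated random walk: n_bonds unit steps where each
# direction mixes the previous direction (weight `stiffness`) with a fresh
# isotropic direction. stiffness = 1 gives a straight rod, 0 a freely
# jointed chain.
.chain_ete <- function(n_frames, n_bonds, bond, stiffness) {
  if (stiffness >= 1) {
    return(rep(n_bonds * bond, n_frames))
  }
  # directions held as n_frames x 3 matrices, advanced bond by bond
  rand_unit <- function(n) {
    z <- stats::rnorm(3 * n)
    m <- matrix(z, ncol = 3)
    m / sqrt(rowSums(m^2))
  }
  dir <- rand_unit(n_frames)
  pos <- dir
  if (n_bonds > 1) {
    for (b in 2:n_bonds) {
      mix <- stiffness * dir + (1 - stiffness) * rand_unit(n_frames)
      dir <- mix / sqrt(rowSums(mix^2))
      pos <- pos + dir
    }
  }
  bond * sqrt(rowSums(pos^2))
}

#' Generate a synthetic end-to-end distance table
#'
#' Samples per-frame end-to-end distances of chains built as correlated
#' random walks with fixed bond length: each of the `Nm - 1` backbone
#' bonds points along a unit vector mixing the previous bond direction
#' (weight `stiffness`) with a fresh isotropic direction. `stiffness = 1`
#' is the rigid-rod limit, where every frame has EtE `(Nm - 1) * bond`;
#' `stiffness = 0` is the freely jointed chain, whose mean EtE grows as
#' `sqrt(Nm)`.
#'
#' @param n_monomers Vector of monomer counts (chains have
#'   `n_monomers - 1` bonds).
#' @param bond Bond length in nm.
#' @param stiffness Direction persistence in `[0, 1]`.
#' @param n_frames Frames per chain length.
#' @param long_format If `TRUE`, return the long per-frame data.frame
#'   (`n_monomers`, `frame`, `ete_nm`) instead of the summary table.
#' @param seed Integer seed.
#' @return An [ete_table()], or a long-format data.frame.
#' @examples
#' tab <- gen_ete_table(stiffness = 1, seed = 1)
#' fit_length_per_monomer(tab, "maximum")$slope
#' @export
gen_ete_table <- function(n_monomers = c(25, 30, 35, 40, 45, 50),
                          bond = 0.333, stiffness = 1, n_frames = 100,
                          long_format = FALSE, seed = 1) {
  stopifnot(all(n_monomers >= 2), bond > 0,
            stiffness >= 0, stiffness <= 1, n_frames >= 1)
  frames <- withr::with_seed(seed, {
    lapply(n_monomers, function(nm) {
      .chain_ete(n_frames, nm - 1, bond, stiffness)
    })
  })
  if (long_format) {
    return(data.frame(
      n_monomers = rep(n_monomers, each = n_frames),
      frame = rep(seq_len(n_frames), times = length(n_monomers)),
      ete_nm = unlist(frames)))
  }
  ete_table(n_monomers,
            vapply(frames, mean, numeric(1)),
            vapply(frames, max, numeric(1)))
}

#' Generate synthetic electrokinetic records
#'
#' For a true effective charge and hydrodynamic diameter, builds the
#' consistent noiseless record (Stokes-Einstein diffusion coefficient and
#' Lorentz-Stokes mobility) and perturbs the measured quantities with
#' multiplicative Gaussian noise.
#'
#' @param qe True electrokinetic charge in C.
#' @param dH True hydrodynamic diameter in m.
#' @param I Ionic strengths in mol L^-1 (one record per value).
#' @param noise Relative noise on mobility and diffusion coefficient.
#' @param ctx A [physical_context()].
#' @param seed Integer seed.
#' @return A data.frame with columns `ionic_strength_M`, `pH`,
#'   `mobility_umcm_per_Vs` and `diffusion_m2_per_s` (the CSV schema of
#'   [read_electrokinetics_csv()]).
#' @examples
#' gen_electrokinetic_records(qe = 6.4e-18, dH = 12e-9, I = 1e-4,
#'                            noise = 0, seed = 1)
#' @export
gen_electrokinetic_records <- function(qe, dH, I = c(1e-4, 1e-3, 1e-2),
                                       noise = 0.05,
                                       ctx = physical_context(), seed = 1) {
  stopifnot(all(dH > 0), noise >= 0)
  D <- diffusion_from_diameter(dH * 1e9, ctx)
  mu_si <- qe * D / (.kB * ctx$temperature)
  n <- length(I)
  D <- rep_len(D, n)
  mu_si <- rep_len(mu_si, n)
  if (noise > 0) {
    pert <- withr::with_seed(seed, {
      list(d = 1 + stats::rnorm(n, sd = noise),
           m = 1 + stats::rnorm(n, sd = noise))
    })
    D <- D * pert$d
    mu_si <- mu_si * pert$m
  }
  data.frame(ionic_strength_M = I,
             pH = NA_real_,
             mobility_umcm_per_Vs = mu_si / 1e-8,
             diffusion_m2_per_s = D)
}
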