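# Shared fixtures: tabulated simulation summaries and measured conditions
# used across the test files. All values are plain numbers; larger inputs
# are generated in code by the synthetic-data module.

# End-to-end summaries for chains of 25-50 monomers (nm)
ete_nm <- c(25, 30, 35, 40, 45, 50)
ete_avg <- c(5.95, 6.42, 8.17, 8.93, 10.24, 10.78)
ete_max <- c(8.38, 9.89, 11.48, 13.24, 15.16, 16.77)

table2_fixture <- function() ete_table(ete_nm, ete_avg, ete_max)

# Measured intrinsic viscosities and the aspect ratios / cylinder
# dimensions they should invert to (with molecule volume 46.5 nm^3)
visc_table <- data.frame(
  eta = c(490, 360, 180, 90, 62),
  lambda = c(89, 75, 51, 34, 28),
  lambda_tol = c(3, 3, 3, 2, 2),
  Lc = c(79, 70, 54, 41, 36),
  Lc_tol = c(3, 3, 2, 2, 2),
  dc = c(0.87, 0.93, 1.06, 1.2, 1.3),
  dc_tol = c(0.02, 0.02, 0.03, 0.05, 0.05))

# Electrokinetic conditions: ionic strength (M), diffusion coefficient
# (m^2/s), expected hydrodynamic diameter (nm), mobility (um cm/V/s)
ek_table <- data.frame(
  I = c(1e-5, 1e-4, 1e-3, 1e-2, 0.15),
  D = c(2.9e-11, 4.1e-11, 4.5e-11, 4.9e-11, 6.1e-11),
  dH = c(17, 12, 11, 10, 8),
  mobility = c(4.7, 4.2, 3.7, 3.2, 2.1))

# Debye lengths (nm) at the conditions where the nominal NaCl
# concentration sets the ionic strength
debye_expected <- data.frame(I = c(1e-4, 1e-3, 1e-2, 0.15),
                             kappa_inv_nm = c(30.5, 9.63, 3.05, 0.786))
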