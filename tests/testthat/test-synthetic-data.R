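# Seeded generators: determinism, exactness at zero noise, and the
# statistical structure each analysis stage assumes.

test_that("generators are pure functions of seed and arguments", {
  a <- gen_viscometry(eta = 490, seed = 11)
  b <- gen_viscometry(eta = 490, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$viscosity,
                         gen_viscometry(eta = 490, seed = 12)$viscosity))
  expect_identical(gen_density_series(rho_p = 1500, seed = 5),
                   gen_density_series(rho_p = 1500, seed = 5))
  expect_identical(gen_ete_table(stiffness = 0.5, n_frames = 20, seed = 9),
                   gen_ete_table(stiffness = 0.5, n_frames = 20, seed = 9))
  expect_identical(
    gen_electrokinetic_records(qe = 6e-18, dH = 1.2e-8, seed = 2),
    gen_electrokinetic_records(qe = 6e-18, dH = 1.2e-8, seed = 2))
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_viscometry(eta = 90, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noiseless viscometry series inverts exactly and stays dilute", {
  s <- gen_viscometry(eta = 490, noise = 0, seed = 1)
  expect_equal(intrinsic_viscosity_fit(s)$eta, 490, tolerance = 1e-10)
  # relative viscosity stays below 1.2 whenever eta * phi_max <= 0.18
  expect_true(all(s$viscosity / s$solvent_viscosity < 1.2))
})

test_that("noiseless density series embeds the exact dilution relation", {
  s <- gen_density_series(rho_p = 1488, noise = 0, seed = 1)
  expect_equal(dilution_slope(s)$slope, -0.33, tolerance = 1e-3)
  expect_equal(s$density[s$mass_fraction == 0], s$solvent_density)
})

test_that("stiff chains are rods and flexible chains are random walks", {
  # rigid-rod limit: constant end-to-end at (Nm - 1) bonds
  tab <- gen_ete_table(n_monomers = 50, bond = 0.333, stiffness = 1,
                       n_frames = 10, seed = 1)
  expect_equal(tab$ete_avg, 49 * 0.333, tolerance = 1e-12)
  expect_equal(tab$ete_max, tab$ete_avg)
  # in the extrapolation regime the through-origin slope recovers the bond
  big <- gen_ete_table(n_monomers = seq(100, 400, by = 50), bond = 0.333,
                       stiffness = 1, n_frames = 5, seed = 1)
  expect_equal(fit_length_per_monomer(big, "maximum")$slope, 0.333,
               tolerance = 5e-3)
  # freely jointed limit: mean end-to-end grows as sqrt(Nm)
  nm <- c(25, 50, 100, 200, 400)
  tab_flex <- gen_ete_table(n_monomers = nm, bond = 0.333, stiffness = 0,
                            n_frames = 2000, seed = 4)
  slope <- stats::coef(stats::lm(log(tab_flex$ete_avg) ~ log(nm)))[[2]]
  expect_lt(abs(slope - 0.5), 0.05)
})

test_that("electrokinetic records invert exactly at zero noise", {
  ctx <- physical_context()
  rec <- gen_electrokinetic_records(qe = 6.4e-18, dH = 12e-9,
                                    I = c(1e-4, 1e-2), noise = 0,
                                    ctx = ctx, seed = 1)
  qe <- electrokinetic_charge(mobility_to_si(rec$mobility_umcm_per_Vs),
                              D = rec$diffusion_m2_per_s, ctx = ctx)
  expect_equal(qe, rep(6.4e-18, 2), tolerance = 1e-10)
  expect_equal(
    hydrodynamic_diameter_from_diffusion(rec$diffusion_m2_per_s, ctx),
    rep(12e-9, 2), tolerance = 1e-12)
  # zero charge means zero mobility
  rec0 <- gen_electrokinetic_records(qe = 0, dH = 12e-9, noise = 0, seed = 1)
  expect_true(all(rec0$mobility_umcm_per_Vs == 0))
})

test_that("charge recovery under correlated measurement noise", {
  vals <- vapply(1:500, function(s) {
    rec <- gen_electrokinetic_records(qe = 6.4e-18, dH = 12e-9, I = 1e-4,
                                      noise = 0.05, seed = s)
    electrokinetic_charge(mobility_to_si(rec$mobility_umcm_per_Vs),
                          D = rec$diffusion_m2_per_s)
  }, numeric(1))
  expect_lt(abs(stats::median(vals) / 6.4e-18 - 1), 0.10)
})
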