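Package: polyrod
Title: Slender-Body Characterization of Rodlike Polyelectrolytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dilute-solution characterization of rodlike (slender-body)
    polyelectrolytes from bench measurements. Converts viscosity dilution
    series into intrinsic viscosities, density dilution series into solute
    densities, and inverts the slender-body intrinsic-viscosity model to
    obtain the chain aspect ratio and, from it, the molar mass,
    hydrodynamic diameter, diffusion coefficient, radius of gyration and
    sedimentation coefficient. Also computes Debye screening lengths,
    Stokes-Einstein sizes, Lorentz-Stokes electrokinetic charges,
    effective ionization degrees and Henry-model zeta potentials from
    electrophoretic mobility and dynamic light scattering data, and
    analyzes end-to-end-distance tables from chain simulations. Includes
    seeded synthetic-data generators so every fitting stage can be
    validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
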