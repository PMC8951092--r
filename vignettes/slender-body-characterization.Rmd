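---
title: "Characterizing rodlike polyelectrolytes from dilute-solution measurements"
author: "polyrod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing rodlike polyelectrolytes from dilute-solution measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrod)
```

## The problem

Cationic polypeptides such as poly-L-arginine are awkward to characterize
by the standard routes: size-exclusion chromatography and multi-angle
light scattering behave poorly for strongly charged macroions, and
ultracentrifugation at low ionic strength is confounded by electrostatic
interactions between sedimenting molecules. Yet the quantities a
formulation scientist needs — molar mass, hydrodynamic diameter, radius of
gyration, effective charge — govern everything these polymers are used
for, from gene-delivery polyplexes to layer-by-layer films.

`polyrod` implements an alternative route that needs only bench
measurements on dilute solutions. Its physical premise is that a strongly
charged chain at low ionic strength is electrostatically stiffened into a
nearly fully extended conformation, so its hydrodynamics are those of a
*slender body*: a rigid cylinder whose length `Lc` far exceeds its
diameter `dc`. In that regime every transport property is a closed-form
function of a single shape parameter, the aspect ratio
`lambda = Lc / dc`, and the aspect ratio itself can be read off a
dilute-solution viscosity measurement.

## The model

The zero-shear intrinsic viscosity of a blunt cylinder, in the
volume-fraction convention (a sphere gives 2.5), is

$$[\eta] = \frac{(3/15)\,\lambda^2}{\ln 2\lambda - 0.5}
        + \frac{(1/15)\,\lambda^2}{\ln 2\lambda - 1.5} + \frac{14}{15}.$$

The function is defined for $\lambda > e^{1.5}/2 \approx 2.24$ (the pole
of the second denominator), passes through a shallow minimum at
$\lambda \approx 3.16$, and is strictly increasing beyond it — growing
roughly as $\lambda^{1.8}$, which is why a modest change in chain
extension produces a dramatic change in viscosity, and why the inversion
is so well conditioned. `aspect_ratio_exact()` inverts the relation by
bracketed root-finding on $\lambda \in [3, 10^6]$ (starting the bracket at
the minimum, where monotonicity makes the root unique) and polishes to a
relative residual below $10^{-10}$.

A closed-form approximate inversion is also provided
(`aspect_ratio_iterative()`): seed $\lambda_1 = (15[\eta])^{1/2}$ and take
one refinement step

$$\lambda = \left\{\frac{15[\eta]}
  {3/(\ln 2\lambda_1 - 0.5) + 1/(\ln 2\lambda_1 - 1.5)}\right\}^{1/2}.$$

Two accuracy regimes are worth knowing, and the test suite freezes both.
The one-step formula is within 1% of the exact inversion for
$[\eta] \gtrsim 150$ but degrades to 3.5% at $[\eta] = 50$. Iterated to
convergence (`iterate = TRUE`) the scheme settles on the exact inverse of
the two-term part of the law, and its only residual is the neglected
$14/15$ background: at most 1.2% at $[\eta] = 50$, vanishing upward. The
often-quoted "about 1%" accuracy of the scheme is a statement about the
converged mode, not the single step.

From the aspect ratio follow, for a chain of monomer molar mass $M_1$,
extended-chain monomer length $l_m$ and diameter $d_c$:

* molar mass $M_m = (M_1 d_c / l_m)\,\lambda$ — each unit of aspect ratio
  is one diameter's worth of backbone, i.e. $d_c/l_m$ monomers;
* hydrodynamic diameter $d_H = \lambda d_c / (\ln 2\lambda - 0.11)$ and,
  via Stokes–Einstein, the diffusion coefficient
  $D = kT / (3\pi\eta\,d_H)$;
* radius of gyration $R_g = \lambda d_c / \sqrt{12}$ (thin-rod limit);
* a dimensionless sedimentation coefficient $S_c = d_H / d_s$, the
  hydrodynamic diameter over the equal-volume-sphere diameter, which for a
  cylinder reduces to
  $\lambda^{2/3} / (1.5^{1/3}(\ln 2\lambda - 0.11))$ — independent of
  $d_c$.

`characterize()` composes all of these from one intrinsic viscosity. When
a molecule volume $v_p$ is supplied (from densitometry and a nominal molar
mass), the cylinder diameter is re-derived from
$d_c = (4 v_p / \pi\lambda)^{1/3}$, so the geometry reflects the
conformation actually realized at the measured ionic strength rather than
the fully extended reference.

```{r characterize}
characterize(490, poly_l_arginine(), vp = 46.5)
```

## Getting the inputs

**Intrinsic viscosity** (`intrinsic_viscosity_fit()`). The reduced
specific viscosity $(\eta_p/\eta_e - 1)/\Phi_V$ is regressed on the
volume fraction $\Phi_V = c_b/\rho_p$; the intercept is $[\eta]$ and the
slope the quadratic (Huggins-type) coefficient. Plotting the *reduced*
quantity is essential: the raw relative viscosity divided by $\Phi_V$
diverges at zero concentration, whereas the reduced form extrapolates to
a finite intercept. Records with relative viscosity at or above 1.2 are
outside the dilute expansion and are excluded with a warning rather than
failing the fit. The fit is unweighted by default (a `weights` argument
exists); the intercept is invariant under common rescaling of solution
and solvent viscosities, since only their ratio enters.

**Solute density** (`dilution_slope()`, `solute_density()`). The ratio of
solvent to solution density is linear in the solute mass fraction with
slope $s_p$, and $\rho_p = \rho_{sol}/(1 + s_p)$. The fit fixes the
intercept at 1 — the ratio is exactly 1 at zero solute by construction —
and reports a free-intercept diagnostic alongside, so a drifting
densitometer shows up instead of silently biasing the slope.

**Electrokinetics** (`electrokinetic_table()`). From each
(ionic strength, mobility, diffusion coefficient) condition the package
computes the Debye length $\kappa^{-1} = (\varepsilon kT/2e^2 N_A
\cdot 10^3 I)^{1/2}$, the Stokes–Einstein diameter, the Lorentz–Stokes
electrokinetic charge $q_e = kT\mu_e/D = 3\pi\eta d_H \mu_e$, the charge
number $N_c = q_e/e$, the effective ionization degree $N_c/N_m$, and the
Henry-model zeta potential
$\zeta = 3\eta\mu_e/(2\varepsilon f(\kappa a))$ with $a = d_H/2$. The
Henry function is evaluated with Ohshima's closed-form approximation
$f(\kappa a) = 1 + \tfrac12\,[1 + 2.5/(\kappa a(1 + 2e^{-\kappa a}))]^{-3}$,
accurate to about 1% between the Hückel ($f \to 1$) and Smoluchowski
($f \to 3/2$) limits; every report records that this is the form used.
The effective charge from this route is far below the number of ionizable
monomers — counterion condensation on a densely charged rod screens most
of the structural charge — which is precisely why an electrokinetic
measurement cannot replace the viscometric molar-mass route for these
systems.

**Chain simulations** (`fit_length_per_monomer()`). Tables of end-to-end
distances from molecular simulations of short chains calibrate the
per-monomer length: a through-origin fit of the maximum end-to-end
distance against monomer count gives the extended-chain monomer length
$l_m$ (the proportional model has no intercept; a free-intercept
diagnostic is reported), and the same fit on the averages gives the mean
projected length per monomer at the simulated ionic strength. Chain
diameters follow from the cylinder relation
$d_c = (4 v_m / \pi L)^{1/2}$ with volumes additive in the monomer count.

## Default constants and units

Temperature 298.15 K, solvent viscosity 0.890 mPa s, relative
permittivity 78.5 and solvent density 997 kg m$^{-3}$ (aqueous NaCl near
25 °C), all overridable through `physical_context()`. Fundamental
constants are CODATA 2018 values, fixed in code and echoed by
`polyrod_constants()`. Lengths are handled in nm and molar masses in
kg mol$^{-1}$ at the interface (with mobility accepted in the instrument
convention µm·cm V$^{-1}$ s$^{-1}$, $10^{-8}$ m$^2$ V$^{-1}$ s$^{-1}$
each); everything is converted to SI internally. Ionic strength is taken
as the nominal salt concentration; H$^+$/OH$^-$ contributions are ignored,
which is adequate above $10^{-4}$ M but means the Debye length at
$10^{-5}$ M nominal salt overestimates the screening length actually
realized in a real, CO$_2$-equilibrated sample.

## Synthetic data and what the tests show

Every fitting stage has a seeded generator (`gen_viscometry()`,
`gen_density_series()`, `gen_ete_table()`,
`gen_electrokinetic_records()`) producing data with exactly the
statistical structure the stage assumes, so parameter recovery can be
verified end to end without instrument files.

* Viscometry: concentrations equally spaced over 50–500 mg L$^{-1}$,
  relative viscosities from the quadratic dilute expansion with Huggins
  coefficient 0.3 (a typical polyelectrolyte value), and multiplicative
  Gaussian noise on the specific-viscosity *increment* $\eta_r - 1$. The
  increment is what serial-dilution capillary viscometry resolves — the
  solvent efflux time is measured in the same capillary and cancels — and
  1% noise on it reproduces the ~1% precision the extrapolated intrinsic
  viscosity achieves in practice. (Relative noise on the raw viscosity
  would swamp the per-mille increments at the dilute end and make the
  intercept unrecoverable; that is a statement about instruments, not
  about the fit.)
* Densitometry: mass fractions up to $5\times10^{-4}$ and additive
  Gaussian density noise of 5 mg L$^{-1}$ equivalent
  ($5\times10^{-3}$ kg m$^{-3}$, a vibrating-tube densitometer
  precision).
* Chain conformations: correlated random walks with fixed bond length;
  stiffness 1 is the rigid rod (end-to-end exactly bonds × length every
  frame), stiffness 0 the freely jointed chain with $\sqrt{N}$ growth.
* Electrokinetics: records built from a true charge and diameter through
  the exact Stokes–Einstein and Lorentz–Stokes relations, then perturbed
  multiplicatively.

Recovery at these noise levels (medians over 500 seeded replicates:
intrinsic viscosity within 2%, solute density within 1%, bond length
within 0.5%, charge within 10%) demonstrates that the estimators are
unbiased and well conditioned *under the generators' assumptions* —
independent Gaussian errors, no concentration-dependent aggregation, no
polydispersity, perfectly known solvent properties. Real samples violate
all four to some degree; in particular polydispersity means the
viscometric molar mass is a particular average, and aggregation at low
ionic strength inflates DLS diameters long before it affects viscosity.
Passing tests validate the inference machinery, not those assumptions.

## Numerical choices

* Exact inversion: bracketed `uniroot` on $[3, 10^6]$ with the bracket
  floor at the curve's minimum ($\lambda \approx 3.16$); results below
  $\lambda = 10$ carry a warning, since "slender" is a stretch there.
* Interpolant fits (`fit_interpolants()`): 200 log-uniform points on
  $[\eta] \in [50, 600]$. The aspect-ratio law is fitted as
  $C[\eta]^b$ by log–log least squares; the molar-mass and
  gyration-radius interpolants are that fit scaled exactly by $C_m$ and
  $d_c/\sqrt{12}$; the hydrodynamic-diameter and sedimentation curves
  need an additive offset $a + C[\eta]^b$, fitted by Levenberg–Marquardt
  initialized from a log–log fit of the offset-subtracted curve. Fits are
  judged by rms relative error against the exact curve (all well under
  5%); the coefficients themselves are range-dependent and are not the
  quantity of interest.
* Report serialization fixes numbers at 6 significant digits with stable
  key order, so identical inputs give byte-identical JSON.
* Degenerate inputs (identical concentrations or mass fractions, a
  single distinct chain length, zero-range histograms) raise errors
  naming the failing precondition rather than producing NaN.

## Scope and limitations

The model is a rigid rod at zero shear: no shear-thinning, no
excluded-volume or flexible-chain corrections, no persistence-length
crossover — at high ionic strength, where the chain coils, the recovered
"aspect ratio" is an effective cylinder parameter, not a literal length
over diameter. The zeta-potential model is Debye–Hückel–Henry for a
sphere of the DLS diameter; relaxation corrections (O'Brien–White) and
soft-layer conduction are out of scope, and the electrokinetic charge is
the Lorentz–Stokes effective value, not a titratable charge. The
equal-volume-sphere diameter uses $(6 v_p/\pi)^{1/3}$ throughout;
for $v_p = 46.5$ nm$^3$ this gives 4.46 nm, and tabulations quoting
4.73 nm for the same volume are inconsistent with that formula.
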