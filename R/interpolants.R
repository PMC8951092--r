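# Power-law interpolants that summarize the exact slender-body inversion
# over a working range of intrinsic viscosities, so that routine molar-mass
# or size estimates do not require root-finding.

power_law_fit <- function(quantity, offset, coefficient, exponent,
                          fit_range, rms_rel_error) {
  stopifnot(coefficient > 0, rms_rel_error >= 0)
  structure(
    list(quantity = quantity, offset = offset, coefficient = coefficient,
         exponent = exponent, fit_range = fit_range,
         rms_rel_error = rms_rel_error),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  form <- if (x$offset != 0) {
    sprintf("%.4g + %.4g * [eta]^%.4g", x$offset, x$coefficient, x$exponent)
  } else {
    sprintf("%.4g * [eta]^%.4g", x$coefficient, x$exponent)
  }
  cat(sprintf("Power-law interpolant for %s: %s  (rms rel. err. %.2g%% on [%g, %g])\n",
              x$quantity, form, 100 * x$rms_rel_error,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Evaluate a power-law interpolant
#'
#' @param object A `power_law_fit` returned by [fit_interpolants()].
#' @param eta Intrinsic viscosities at which to evaluate.
#' @param ... Unused.
#' @return Predicted values of the fitted quantity.
#' @export
predict.power_law_fit <- function(object, eta, ...) {
  object$offset + object$coefficient * eta^object$exponent
}

#' Fit power-law interpolants to the exact slender-body curves
#'
#' Samples the exact inversion of the slender-body viscosity law on a
#' log-uniform grid of intrinsic viscosities and fits compact interpolants:
#' a pure power law `C * [eta]^b` for the aspect ratio (log-log least
#' squares), the same power law scaled by the species constants for the
#' molar mass (`Cm`) and radius of gyration (`dc/sqrt(12)`), and offset
#' power laws `a + C * [eta]^b` for the hydrodynamic diameter and the
#' sedimentation coefficient (nonlinear least squares initialized from a
#' log-log fit of the offset-subtracted curve).
#'
#' All curves are evaluated at the extended-chain diameter of `polymer`,
#' i.e. in the low-ionic-strength limit where the chain is fully extended.
#'
#' @param polymer A [polymer_spec()].
#' @param eta_range Intrinsic-viscosity interval to fit over.
#' @param n_points Number of log-uniform grid points (>= 20).
#' @return Named list of `power_law_fit` objects: `lambda`, `molar_mass`,
#'   `radius_of_gyration`, `hydrodynamic_diameter`,
#'   `sedimentation_coefficient`. Each carries the rms relative error of
#'   the fit against the exact curve over the grid.
#' @examples
#' fits <- fit_interpolants(poly_l_arginine())
#' predict(fits$lambda, 490)
#' @export
fit_interpolants <- function(polymer, eta_range = c(50, 600),
                             n_points = 200) {
  stopifnot(inherits(polymer, "polymer_spec"), n_points >= 20,
            eta_range[1] > 0, eta_range[2] > eta_range[1])
  eta <- exp(seq(log(eta_range[1]), log(eta_range[2]),
                 length.out = n_points))
  lambda <- aspect_ratio_exact(eta)

  rms_rel <- function(pred, truth) sqrt(mean(((pred - truth) / truth)^2))

  # pure power law for the aspect ratio
  ll <- stats::lm(log(lambda) ~ log(eta))
  C_l <- exp(stats::coef(ll)[[1]])
  b_l <- stats::coef(ll)[[2]]
  lam_fit <- power_law_fit("aspect ratio", 0, C_l, b_l, eta_range,
                           rms_rel(C_l * eta^b_l, lambda))

  scaled <- function(quantity, scale, truth) {
    power_law_fit(quantity, 0, scale * C_l, b_l, eta_range,
                  rms_rel(scale * C_l * eta^b_l, truth))
  }
  mm_fit <- scaled("molar mass (kg mol^-1)", mass_per_aspect(polymer),
                   molar_mass_from_aspect_ratio(lambda, polymer))
  rg_fit <- scaled("radius of gyration (nm)", polymer$dc / sqrt(12),
                   radius_of_gyration(lambda, polymer$dc))

  offset_power_fit <- function(quantity, y) {
    a0 <- 0.5 * min(y)
    init <- stats::lm(log(y - a0) ~ log(eta))
    start <- list(a = a0, C = exp(stats::coef(init)[[1]]),
                  b = stats::coef(init)[[2]])
    fit <- minpack.lm::nlsLM(y ~ a + C * eta^b, start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit)
    power_law_fit(quantity, cf[["a"]], cf[["C"]], cf[["b"]], eta_range,
                  rms_rel(cf[["a"]] + cf[["C"]] * eta^cf[["b"]], y))
  }
  dh_fit <- offset_power_fit(
    "hydrodynamic diameter (nm)",
    hydrodynamic_diameter_slender(lambda, polymer$dc))
  sc_fit <- offset_power_fit(
    "sedimentation coefficient",
    sedimentation_coefficient(lambda, polymer$dc))

  list(lambda = lam_fit, molar_mass = mm_fit, radius_of_gyration = rg_fit,
       hydrodynamic_diameter = dh_fit, sedimentation_coefficient = sc_fit)
}
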