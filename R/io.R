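# CSV/JSON input-output and the end-to-end characterization pipeline.

# Read a CSV and fail with an informative message if required columns are
# missing.
read_csv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("CSV ", path, " is missing column(s) ",
         paste(missing, collapse = ", "), "; expected header: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  df
}

# Round every numeric leaf to 6 significant digits so that re-running a
# command on identical inputs yields byte-identical JSON.
.signif_rec <- function(x, digits = 6) {
  if (is.list(x)) {
    lapply(x, .signif_rec, digits = digits)
  } else if (is.numeric(x)) {
    signif(x, digits)
  } else {
    x
  }
}

#' Write a characterization report as JSON
#'
#' Serializes a report (or any nested list of results) to JSON with stable
#' key order and numbers fixed at 6 significant digits, so identical inputs
#' produce byte-identical files.
#'
#' @param report A list, e.g. from [run_full_characterization()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(.signif_rec(unclass_rec(report)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

unclass_rec <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_rec)
  } else {
    x
  }
}

#' Run the full characterization workflow
#'
#' Chains the analysis stages the way a bench characterization proceeds:
#' densitometry gives the solute density; the density and the (known or
#' assumed) molar mass give the molecule volume; viscometry gives the
#' intrinsic viscosity; the slender-body inversion turns it into the
#' aspect ratio and all derived molecular properties; and, when mobility
#' and DLS data are present, the electrokinetic quantities are appended.
#'
#' @param viscosity A [viscosity_series()] or a list of them (one per
#'   ionic strength). Required.
#' @param density A [density_series()], or `NULL` to use the solute
#'   density stored in the viscosity series.
#' @param electrokinetics A data.frame in the schema of
#'   [read_electrokinetics_csv()], or `NULL`.
#' @param polymer A [polymer_spec()].
#' @param molar_mass Nominal molar mass in kg mol^-1 used for the molecule
#'   volume (e.g. a manufacturer value); if `NULL`, the volume is inferred
#'   after the fact from the fitted aspect ratio and the polymer constants.
#' @param ctx A [physical_context()].
#' @return A list of class `characterization_report` with elements
#'   `polymer`, `context`, `constants`, `density` (slope, solute density,
#'   molecule volume, monomer count), `conditions` (one entry per
#'   viscosity series: intrinsic-viscosity fit plus
#'   [characterize()] output) and `electrokinetics` (a data.frame or
#'   `NULL`).
#' @examples
#' visc <- gen_viscometry(eta = 490, noise = 0)
#' dens <- gen_density_series(rho_p = 1500, noise = 0)
#' run_full_characterization(visc, dens, polymer = poly_l_arginine(),
#'                           molar_mass = 42)
#' @export
run_full_characterization <- function(viscosity, density = NULL,
                                      electrokinetics = NULL,
                                      polymer = poly_l_arginine(),
                                      molar_mass = NULL,
                                      ctx = physical_context()) {
  if (inherits(viscosity, "viscosity_series")) {
    viscosity <- list(viscosity)
  }
  stopifnot(length(viscosity) >= 1,
            all(vapply(viscosity, inherits, logical(1), "viscosity_series")))

  density_block <- NULL
  rho_p <- NULL
  if (!is.null(density)) {
    ds <- dilution_slope(density)
    rho_p <- solute_density(ds$slope, density$solvent_density)
    density_block <- list(slope = ds$slope, slope_stderr = ds$stderr,
                          solute_density_kg_m3 = rho_p)
  } else {
    rho_p <- viscosity[[1]]$solute_density
    density_block <- list(slope = NULL, slope_stderr = NULL,
                          solute_density_kg_m3 = rho_p)
  }
  vp <- NULL
  if (!is.null(molar_mass)) {
    vp <- molecule_volume(molar_mass, rho_p)
    density_block$molecule_volume_nm3 <- vp
    density_block$monomer_count <- as.numeric(monomer_count(molar_mass,
                                                            polymer$M1))
  }

  conditions <- lapply(viscosity, function(s) {
    fit <- intrinsic_viscosity_fit(s)
    res <- characterize(fit$eta, polymer, vp = vp, ctx = ctx)
    list(ionic_strength_M = s$ionic_strength,
         intrinsic_viscosity = fit$eta,
         intrinsic_viscosity_stderr = fit$stderr,
         huggins_slope = fit$huggins_slope,
         slender_body = res)
  })

  ek <- NULL
  if (!is.null(electrokinetics)) {
    n_mono <- if (!is.null(molar_mass)) {
      as.numeric(monomer_count(molar_mass, polymer$M1))
    } else {
      NA_real_
    }
    ek <- electrokinetic_table(
      I = electrokinetics$ionic_strength_M,
      mobility = electrokinetics$mobility_umcm_per_Vs,
      D = electrokinetics$diffusion_m2_per_s,
      n_monomers = if (is.na(n_mono)) Inf else n_mono,
      pH = electrokinetics$pH,
      ctx = ctx)
    if (is.na(n_mono)) ek$ionization_degree <- NA_real_
  }

  structure(
    list(polymer = polymer,
         context = ctx,
         constants = polyrod_constants(),
         density = density_block,
         conditions = conditions,
         electrokinetics = ek),
    class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("Characterization report:", x$polymer$name, "\n")
  cat(sprintf("  solute density: %.4g kg m^-3\n",
              x$density$solute_density_kg_m3))
  for (cond in x$conditions) {
    r <- cond$slender_body
    cat(sprintf(
      "  I = %-8s [eta] = %-6.4g lambda = %-5.3g Lc = %-5.3g nm dc = %-5.3g nm Mm = %.3g kg/mol\n",
      ifelse(is.na(cond$ionic_strength_M), "?",
             format(cond$ionic_strength_M)),
      cond$intrinsic_viscosity, r$aspect_ratio, r$cylinder_length,
      r$cylinder_diameter, r$molar_mass))
  }
  if (!is.null(x$electrokinetics)) {
    cat(sprintf("  electrokinetics: %d condition(s)\n",
                nrow(x$electrokinetics)))
  }
  invisible(x)
}
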