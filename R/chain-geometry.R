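# End-to-end-distance analysis of chain simulations: per-chain summaries,
# the proportional length-per-monomer fit, and chain diameters from the
# cylinder model.

#' End-to-end distance table
#'
#' Summary table of chain-simulation end-to-end (EtE) distances: one row
#' per chain length, with the average and maximum EtE over frames and an
#' optional molecule volume.
#'
#' @param n_monomers Monomer counts (integer-valued, >= 2).
#' @param ete_avg Average EtE distances in nm, same length.
#' @param ete_max Maximum EtE distances in nm, same length; must be >=
#'   the averages row-wise.
#' @param volume Optional molecule volumes in nm^3.
#' @return An object of class `ete_table` (a data.frame).
#' @export
ete_table <- function(n_monomers, ete_avg, ete_max, volume = NULL) {
  stopifnot(length(n_monomers) == length(ete_avg),
            length(n_monomers) == length(ete_max),
            all(n_monomers >= 2), all(ete_avg > 0), all(ete_max > 0),
            all(ete_max >= ete_avg))
  df <- data.frame(n_monomers = n_monomers, ete_avg = ete_avg,
                   ete_max = ete_max)
  if (!is.null(volume)) {
    stopifnot(length(volume) == length(n_monomers), all(volume > 0))
    df$volume <- volume
  }
  class(df) <- c("ete_table", "data.frame")
  df
}

#' Summarize per-frame end-to-end distances
#'
#' Arithmetic mean, maximum and a normalized histogram (bin probabilities
#' summing to 1) of a sample of per-frame end-to-end distances.
#'
#' @param values Per-frame EtE distances in nm (>= 1 value, all > 0).
#' @param n_bins Number of histogram bins over `[min, max]`.
#' @return A list with `average`, `maximum` and `histogram` (a data.frame
#'   with `mid`, `lower`, `upper`, `prob`).
#' @examples
#' ete_summary(c(5, 5, 5), n_bins = 1)
#' @export
ete_summary <- function(values, n_bins = 30) {
  if (length(values) < 1) stop("no end-to-end values supplied", call. = FALSE)
  stopifnot(all(values > 0), n_bins >= 1)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    hist_df <- data.frame(mid = rng[1], lower = rng[1], upper = rng[2],
                          prob = 1)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE), nbins = n_bins)
    hist_df <- data.frame(mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                          lower = breaks[-(n_bins + 1)],
                          upper = breaks[-1],
                          prob = counts / length(values))
  }
  list(average = mean(values), maximum = max(values), histogram = hist_df)
}

#' Length per monomer from an end-to-end table
#'
#' Through-origin least-squares fit of the selected EtE summary column
#' against the monomer count: `slope = sum(Nm * L) / sum(Nm^2)`. With
#' `mode = "maximum"` the slope estimates the per-monomer length of the
#' fully extended chain (the contour length per monomer); with
#' `mode = "average"` it estimates the average projected length per
#' monomer at the simulated ionic strength. A free-intercept diagnostic
#' fit is returned alongside.
#'
#' @param table An [ete_table()].
#' @param mode `"average"` or `"maximum"`.
#' @return A list with `slope` (nm per monomer), `stderr` and `diagnostic`
#'   (free-intercept coefficients).
#' @examples
#' tab <- ete_table(c(25, 50), c(5.9, 10.8), c(8.4, 16.8))
#' fit_length_per_monomer(tab, mode = "maximum")$slope
#' @export
fit_length_per_monomer <- function(table, mode = c("average", "maximum")) {
  stopifnot(inherits(table, "ete_table"))
  mode <- match.arg(mode)
  if (length(unique(table$n_monomers)) < 2) {
    stop("need at least two distinct monomer counts", call. = FALSE)
  }
  y <- if (mode == "maximum") table$ete_max else table$ete_avg
  nm <- table$n_monomers
  fit <- stats::lm(y ~ 0 + nm)
  diag_fit <- stats::lm(y ~ nm)
  list(slope = stats::coef(fit)[[1]],
       stderr = summary(fit)$coefficients[1, 2],
       diagnostic = stats::coef(diag_fit))
}

#' Chain diameter from molecule volume and chain length
#'
#' Diameter of the cylinder with volume `vm` and length `L`:
#' `dc = sqrt(4 vm / (pi L))`. With the maximum (contour) length this
#' gives the extended-chain diameter; with the average length, the
#' effective diameter of the partially coiled chain.
#'
#' @param vm Molecule volume in nm^3. Vectorized.
#' @param L Chain length in nm. Vectorized.
#' @return Chain diameter in nm.
#' @examples
#' chain_diameter_from_volume(9.15, 16.77) # ~0.83
#' @export
chain_diameter_from_volume <- function(vm, L) {
  stopifnot(all(vm > 0), all(L > 0))
  sqrt(4 * vm / (pi * L))
}

#' Molecule volume from the monomer count
#'
#' Volumes are additive in the monomer count: `vm = Nm * v1`.
#'
#' @param Nm Monomer count (>= 1). Vectorized.
#' @param v1 Monomer volume in nm^3.
#' @return Molecule volume in nm^3.
#' @examples
#' molecule_volume_scaling(50, 0.183) # 9.15
#' @export
molecule_volume_scaling <- function(Nm, v1) {
  stopifnot(all(Nm >= 1), v1 > 0)
  Nm * v1
}

#' Read an end-to-end table from CSV
#'
#' Accepts either the long per-frame format (columns `n_monomers`, `frame`,
#' `ete_nm`), which is summarized per chain length, or the summary format
#' (columns `n_monomers`, `ete_avg_nm`, `ete_max_nm`).
#'
#' @param path CSV file path.
#' @return An [ete_table()].
#' @export
read_ete_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("n_monomers", "frame", "ete_nm") %in% names(df))) {
    by_nm <- split(df$ete_nm, df$n_monomers)
    nm <- as.numeric(names(by_nm))
    o <- order(nm)
    ete_table(nm[o],
              vapply(by_nm, mean, numeric(1))[o],
              vapply(by_nm, max, numeric(1))[o])
  } else if (all(c("n_monomers", "ete_avg_nm", "ete_max_nm") %in% names(df))) {
    ete_table(df$n_monomers, df$ete_avg_nm, df$ete_max_nm)
  } else {
    stop("CSV ", path, " must have columns (n_monomers, frame, ete_nm) or ",
         "(n_monomers, ete_avg_nm, ete_max_nm); found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
}
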