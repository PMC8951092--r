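# End-to-end distance analysis.

test_that("ete_summary handles degenerate and sampled inputs", {
  s <- ete_summary(c(5, 5, 5), n_bins = 4)
  expect_equal(s$average, 5)
  expect_equal(s$maximum, 5)
  expect_equal(sum(s$histogram$prob), 1)
  expect_equal(nrow(s$histogram), 1)
  expect_error(ete_summary(numeric(0)), "no end-to-end")
  # histogram normalizes for a generated sample
  long <- gen_ete_table(n_monomers = 40, stiffness = 0, n_frames = 2000,
                        long_format = TRUE, seed = 3)
  s2 <- ete_summary(long$ete_nm, n_bins = 25)
  expect_equal(sum(s2$histogram$prob), 1, tolerance = 1e-12)
  # mean of a freely jointed chain: E|R| = b sqrt(8 n / (3 pi)) for n bonds
  n_bonds <- 39
  expected_mean <- 0.333 * sqrt(8 * n_bonds / (3 * pi))
  se <- stats::sd(long$ete_nm) / sqrt(nrow(long))
  expect_lt(abs(s2$average - expected_mean), 3 * se)
})

test_that("through-origin fit recovers extended and average monomer lengths", {
  tab <- table2_fixture()
  fit_max <- fit_length_per_monomer(tab, "maximum")
  fit_avg <- fit_length_per_monomer(tab, "average")
  expect_equal(fit_max$slope, 0.333, tolerance = 1e-3)
  expect_equal(fit_avg$slope, 0.224, tolerance = 2e-3)
  expect_equal(fit_avg$slope, 0.225, tolerance = 0.01)
  # closed-form through-origin slope
  expect_equal(fit_max$slope, sum(ete_nm * ete_max) / sum(ete_nm^2),
               tolerance = 1e-12)
  # maxima dominate averages row-wise, so the slopes order the same way
  expect_gte(fit_max$slope, fit_avg$slope)
})

test_that("through-origin fit is exact on proportional data and rejects degeneracy", {
  tab <- ete_table(c(10, 20), c(1, 2) * 0.9, c(1, 2))
  # zero-residual fit: silence the "perfect fit" note from summary.lm
  expect_equal(suppressWarnings(fit_length_per_monomer(tab, "maximum")$slope),
               0.1)
  expect_error(
    fit_length_per_monomer(ete_table(c(10, 10), c(1, 1), c(2, 2)), "maximum"),
    "distinct")
})

test_that("chain diameter follows from volume and length", {
  expect_equal(chain_diameter_from_volume(9.15, 16.77), 0.834,
               tolerance = 1e-3)
  expect_equal(chain_diameter_from_volume(9.15, 10.78), 1.04,
               tolerance = 2e-3)
  expect_equal(chain_diameter_from_volume(pi / 4, 1), 1)
})

test_that("full table reconstruction: volumes and both diameter rows", {
  tab <- table2_fixture()
  vm <- molecule_volume_scaling(tab$n_monomers, 0.183)
  expect_equal(vm, c(4.58, 5.49, 6.41, 7.32, 8.24, 9.15), tolerance = 0.05 / 4.58)
  dc_ext <- chain_diameter_from_volume(vm, tab$ete_max)
  dc_avg <- chain_diameter_from_volume(vm, tab$ete_avg)
  expect_true(all(abs(dc_ext - c(0.83, 0.84, 0.84, 0.84, 0.83, 0.83)) <= 0.021))
  expect_true(all(abs(dc_avg - c(1.00, 1.04, 1.00, 1.02, 1.01, 1.04)) <= 0.021))
})

test_that("molecule volume scales linearly with monomer count", {
  expect_equal(molecule_volume_scaling(50, 0.183), 9.15)
  expect_equal(molecule_volume_scaling(25, 0.183), 4.575)
  expect_equal(molecule_volume_scaling(1, 0.183), 0.183)
})

test_that("CSV reader accepts both long and summary formats", {
  long <- gen_ete_table(n_monomers = c(25, 50), stiffness = 1,
                        n_frames = 5, long_format = TRUE, seed = 1)
  f_long <- tempfile(fileext = ".csv")
  utils::write.csv(long, f_long, row.names = FALSE)
  tab_long <- read_ete_csv(f_long)
  expect_s3_class(tab_long, "ete_table")
  expect_equal(tab_long$n_monomers, c(25, 50))
  expect_equal(tab_long$ete_max, c(24, 49) * 0.333, tolerance = 1e-12)

  f_sum <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(n_monomers = ete_nm, ete_avg_nm = ete_avg,
                              ete_max_nm = ete_max),
                   f_sum, row.names = FALSE)
  tab_sum <- read_ete_csv(f_sum)
  expect_equal(fit_length_per_monomer(tab_sum, "maximum")$slope, 0.333,
               tolerance = 1e-3)
  # malformed header is a clear error
  f_bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1:3, y = 1:3), f_bad, row.names = FALSE)
  expect_error(read_ete_csv(f_bad), "must have columns")
  unlink(c(f_long, f_sum, f_bad))
})
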