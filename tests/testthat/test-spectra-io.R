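test_that("spectrum construction enforces its invariants", {
  expect_s3_class(spectrum(1:5, rnorm(5)), "spectrum")
  expect_error(spectrum(1, 1), "length")
  expect_error(spectrum(c(1, 2, 2, 3), rnorm(4)), "monotone")
  expect_error(spectrum(c(1, 3, 2), rnorm(3)), "monotone")
  expect_error(spectrum(1:3, c(1, NA, 2)), "non-finite")
  expect_error(spectrum(1:3, c(1, Inf, 2)), "non-finite")
  # descending grids (common in FT-IR exports) are monotone too
  expect_s3_class(spectrum(5:1, rnorm(5)), "spectrum")
})

test_that("peak_intensity uses the nearest grid point, no interpolation", {
  sp <- gaussian_spectrum(337, 25, height = 10)
  expect_equal(peak_intensity(sp, 337), 10)
  # 337.4 on a 1 nm grid resolves to the 337 point
  expect_equal(peak_intensity(sp, 337.4), peak_intensity(sp, 337))
  flat <- spectrum(300:400, rep(7, 101))
  expect_equal(peak_intensity(flat, 350.2), 7)
  expect_error(peak_intensity(sp, 600), "outside")
})

test_that("titration series validates concentrations and shared grid", {
  sp <- gaussian_spectrum(337, 25)
  expect_error(titration_series(310, c(1e-6, 2e-6), list(sp, sp)),
               "first concentration")
  expect_error(titration_series(310, c(0, 2e-6, 1e-6), list(sp, sp, sp)),
               "increasing")
  expect_error(titration_series(-1, c(0, 1e-6), list(sp, sp)), "positive")
  other <- gaussian_spectrum(337, 25, grid = seq(300, 500, by = 2))
  expect_error(titration_series(310, c(0, 1e-6), list(sp, other)),
               "axis grid")
})

test_that("write/read round trip is the identity on titration series", {
  gt <- quenching_ground_truth(noise_sd_rel = 0.01, seed = 42)
  series <- generate_titration(gt, c(0, seq(1.5e-6, 1.05e-5,
                                            length.out = 7)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration_table(series, path)
  back <- read_titration_table(path, series$temperature_K)
  expect_equal(back$ligand_concentrations_M,
               series$ligand_concentrations_M, tolerance = 1e-9)
  for (i in seq_along(series$spectra)) {
    expect_equal(back$spectra[[i]]$axis, series$spectra[[i]]$axis,
                 tolerance = 1e-9)
    expect_equal(back$spectra[[i]]$intensity, series$spectra[[i]]$intensity,
                 tolerance = 1e-9)
  }
  # empty labels are fine: the writer keeps no label column
  expect_identical(back$spectra[[1]]$label, "")
})

test_that("reader sorts columns into ascending concentration order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("nm,5e-7,0",
               "300,2,1",
               "301,4,3",
               "302,6,5"), path)
  series <- read_titration_table(path, 296)
  expect_equal(series$ligand_concentrations_M, c(0, 5e-7))
  # manual permutation: the 0 M column is the second file column
  expect_equal(series$spectra[[1]]$intensity, c(1, 3, 5))
  expect_equal(series$spectra[[2]]$intensity, c(2, 4, 6))
})

test_that("reader rejects malformed files with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("nm,0,5e-7", "300,1,2", "301,1"), path)
  expect_error(read_titration_table(path, 296), "ragged row 3")
  writeLines(c("nm,0,abc", "300,1,2", "301,1,2"), path)
  expect_error(read_titration_table(path, 296), "not a concentration")
  writeLines(c("xyz,0,5e-7", "300,1,2", "301,1,2"), path)
  expect_error(read_titration_table(path, 296), "axis column header")
})

test_that("reader rejects non-monotone axes (shuffled-grid property)", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(11)
  for (rep in 1:20) {
    ax <- sample(300:320)  # shuffled, almost surely non-monotone
    if (!is.unsorted(ax) || !is.unsorted(rev(ax))) next
    writeLines(c("nm,0,5e-7",
                 paste(ax, 1, 2, sep = ",")), path)
    expect_error(read_titration_table(path, 296), "monotone")
  }
})

test_that("quench_ratios reads every member at the ligand-free maximum", {
  gt <- quenching_ground_truth(Ksv_dynamic_per_M = 2e4, Ka_per_M = 0,
                               noise_sd_rel = 0, ligand_eps_ex = 0,
                               ligand_eps_em = 0)
  series <- generate_titration(gt, c(0, 2.5e-5, 5e-5))
  rat <- quench_ratios(series)
  expect_equal(rat$F0F, 1 + 2e4 * c(0, 2.5e-5, 5e-5))
})
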