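random_smooth_pair <- function() {
  # donor: Gaussian mixture emission; acceptor: Gaussian mixture absorbance
  grid <- seq(300, 500, by = runif(1, 0.5, 1.5))
  donor <- rep(0, length(grid))
  for (i in 1:sample(1:3, 1)) {
    donor <- donor + runif(1, 0.5, 2) *
      exp(-(grid - runif(1, 330, 420))^2 / (2 * runif(1, 10, 40)^2))
  }
  agrid <- seq(runif(1, 280, 320), runif(1, 430, 480), by = runif(1, 0.5, 2))
  acc <- rep(0, length(agrid))
  for (i in 1:sample(1:3, 1)) {
    acc <- acc + runif(1, 0.05, 0.4) *
      exp(-(agrid - runif(1, 300, 420))^2 / (2 * runif(1, 10, 30)^2))
  }
  list(donor = spectrum(grid, donor, "wavelength_nm"),
       acceptor = spectrum(agrid, acc, "wavelength_nm"))
}

# independent quadrature oracle: trapezoid rule on the donor grid
oracle_overlap <- function(donor, acceptor, conc, path = 1) {
  lam_cm <- donor$axis * 1e-7
  eps <- stats::approx(acceptor$axis, acceptor$intensity, xout = donor$axis,
                       yleft = 0, yright = 0)$y / (conc * path)
  pracma::trapz(lam_cm, donor$intensity * eps * lam_cm^4) /
    pracma::trapz(lam_cm, donor$intensity)
}

test_that("overlap integral matches a rectangular closed form", {
  skip_if_not_installed("pracma")
  grid <- seq(400, 500, by = 0.5)
  donor <- spectrum(grid, rep(3, length(grid)), "wavelength_nm")
  agrid <- seq(450, 500, by = 0.5)
  conc <- 2e-5
  acc <- spectrum(agrid, rep(1e4 * conc, length(agrid)), "wavelength_nm")
  J <- overlap_integral(donor, acc, conc)
  # analytic: 1e4 * int_450^500 l^4 dl / int_400^500 dl, l in cm
  l1 <- 450e-7; l2 <- 500e-7; l0 <- 400e-7
  J_exact <- 1e4 * (l2^5 - l1^5) / 5 / (l2 - l0)
  expect_equal(J, J_exact, tolerance = 0.01)
  # and matches the trapezoid oracle far more tightly
  expect_equal(J, oracle_overlap(donor, acc, conc), tolerance = 1e-10)
})

test_that("overlap integral is invariant to donor rescaling", {
  set.seed(7)
  p <- random_smooth_pair()
  J1 <- overlap_integral(p$donor, p$acceptor, 5e-7)
  donor10 <- spectrum(p$donor$axis, 10 * p$donor$intensity, "wavelength_nm")
  expect_equal(overlap_integral(donor10, p$acceptor, 5e-7), J1)
})

test_that("disjoint spectral supports give J = 0 with a warning", {
  donor <- gaussian_spectrum(330, 10, grid = seq(300, 360, 1))
  acc <- gaussian_spectrum(450, 10, grid = seq(400, 500, 1))
  expect_warning(J <- overlap_integral(donor, acc, 5e-7), "disjoint")
  expect_equal(J, 0)
})

test_that("overlap integral agrees with the quadrature oracle on random spectra", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (i in 1:25) {
    p <- random_smooth_pair()
    J <- suppressWarnings(overlap_integral(p$donor, p$acceptor, 5e-7))
    Jo <- oracle_overlap(p$donor, p$acceptor, 5e-7)
    if (Jo > 0) expect_lt(abs(J / Jo - 1), 1e-3)
  }
})

test_that("forster_radius follows the sixth-root law", {
  expect_equal(forster_radius(0), 0)
  J <- 1.183e-17
  expect_equal(forster_radius(J * 1e6), 10 * forster_radius(J))
  # direct evaluation oracle of the critical-distance formula
  K2 <- 2 / 3; N <- 1.336; phi <- 0.118
  r0_direct <- (8.8e-25 * K2 * phi * J / N^4)^(1 / 6) * 1e7
  expect_equal(forster_radius(J, K2, N, phi), r0_direct, tolerance = 1e-12)
  expect_error(forster_radius(-1), ">= 0")
})

test_that("transfer efficiency reproduces the published E and limits", {
  E <- transfer_efficiency(1.170, 2.017)
  expect_lt(abs(100 * E - 3.67), 0.05)
  expect_equal(transfer_efficiency(1.5, 1.5), 0.5)
  r <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(transfer_efficiency(1.17, r)) < 0))
  expect_lt(transfer_efficiency(1.17, 50), 1e-8)
})

test_that("binding_distance inverts the efficiency relation", {
  expect_lt(abs(10 * binding_distance(0.0367, 1.170) - 20.17), 0.05)
  expect_equal(binding_distance(0.5, 1.170), 1.170)
  # exact inverse pair over random (E, R0)
  set.seed(3)
  for (i in 1:50) {
    E <- runif(1, 1e-4, 1 - 1e-4)
    R0 <- runif(1, 0.5, 6)
    expect_equal(transfer_efficiency(R0, binding_distance(E, R0)), E,
                 tolerance = 1e-12)
  }
  expect_error(binding_distance(0, 1.17), "inside")
  expect_error(binding_distance(1, 1.17), "inside")
})

test_that("efficiency_from_intensities is 1 - F/F0 with domain checks", {
  expect_equal(efficiency_from_intensities(100, 100), 0)
  expect_equal(efficiency_from_intensities(0.9633 * 250, 250), 0.0367)
  expect_equal(efficiency_from_intensities(50, 100), 0.5)
  expect_error(efficiency_from_intensities(101, 100), "exceed")
})

test_that("fret_analysis assembles a self-consistent result", {
  set.seed(9)
  p <- random_smooth_pair()
  res <- suppressWarnings(
    fret_analysis(p$donor, p$acceptor, 5e-7, F = 0.9633, F0 = 1,
                  R0_nm = 1.170))
  expect_equal(res$E, 0.0367)
  expect_equal(res$r_nm, binding_distance(0.0367, 1.170))
  # stored triplet satisfies E = R0^6/(R0^6 + r^6) exactly
  expect_equal(res$E, transfer_efficiency(res$R0_nm, res$r_nm),
               tolerance = 1e-12)
  expect_true(res$non_radiative)  # r < 8 nm
  # J-derived radius reported alongside the supplied one
  expect_equal(res$R0_from_J_nm,
               forster_radius(res$J_cm3_L_per_mol))
})
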