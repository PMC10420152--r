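test_that("ife_correct evaluates the inner-filter factor", {
  expect_equal(ife_correct(100, 0, 0), 100)
  expect_equal(ife_correct(100, 0.1, 0.1), 100 * exp(0.1))
  # monotone in each absorbance, and never below the observed signal
  a <- seq(0, 1, by = 0.1)
  expect_true(all(diff(ife_correct(100, a, 0.05)) > 0))
  expect_true(all(ife_correct(50, a, a) >= 50))
  expect_error(ife_correct(100, -0.1, 0), "non-negative")
})

test_that("stern_volmer_fit recovers an exact line and its diagnostics", {
  q <- seq(0, 1e-5, length.out = 6)
  fit <- suppressWarnings(stern_volmer_fit(q, 1 + 2e4 * q))
  expect_equal(fit$Ksv_per_M, 2e4)
  expect_equal(fit$r_squared, 1)
  expect_false(fit$intercept_warning)
  flat <- suppressWarnings(stern_volmer_fit(q, rep(1, 6)))
  expect_equal(flat$Ksv_per_M, 0)
  expect_error(stern_volmer_fit(c(0, 1e-6), c(1, 1.1)), "insufficient|>= 3")
})

test_that("Kq = Ksv / tau0 holds bit-exactly, at the published magnitudes", {
  q <- seq(0, 1.05e-5, length.out = 9)
  fit <- suppressWarnings(stern_volmer_fit(q, 1 + 1.832e4 * q,
                                           tau0_s = 1e-8))
  expect_identical(fit$Kq_per_M_s, fit$Ksv_per_M / fit$tau0_s)
  expect_equal(fit$Kq_per_M_s, 1.832e12)
  # property: exact identity across arbitrary fits
  set.seed(4)
  for (i in 1:5) {
    ksv <- runif(1, 1e3, 1e5)
    tau <- 10^runif(1, -9, -7)
    f <- suppressWarnings(
      stern_volmer_fit(q, 1 + ksv * q + rnorm(9, 0, 0.01), tau0_s = tau))
    expect_identical(f$Kq_per_M_s, f$Ksv_per_M / tau)
  }
})

test_that("stern_volmer_fit flags suspect data instead of failing", {
  q <- seq(0, 1e-5, length.out = 6)
  expect_warning(f <- stern_volmer_fit(q, 1.2 + 2e4 * q), "intercept")
  expect_true(f$intercept_warning)
  expect_warning(g <- stern_volmer_fit(q, 1 - 5e3 * q), "negative")
  expect_true(g$negative_ksv)
  # duplicate concentrations are averaged, not double-counted
  dup <- suppressWarnings(
    stern_volmer_fit(c(q, 5e-6), c(1 + 2e4 * q, 1 + 2e4 * 5e-6)))
  expect_equal(dup$Ksv_per_M, 2e4)
})

test_that("mechanism classification follows the Kq/temperature rule table", {
  mk <- function(ksv, temp) {
    q <- seq(0, 1e-5, length.out = 5)
    suppressWarnings(stern_volmer_fit(q, 1 + ksv * q, tau0_s = 1e-8,
                                      temperature_K = temp))
  }
  # published pattern: Kq ~1e12 (static evidence) and Ksv increasing with T
  pub <- list(mk(1.593e4, 296), mk(1.619e4, 303), mk(1.832e4, 310))
  expect_equal(classify_mechanism(pub), "mixed")
  # low Kq, increasing Ksv: purely dynamic
  dyn <- list(mk(10, 296), mk(12, 303), mk(15, 310))
  expect_equal(classify_mechanism(dyn), "dynamic")
  # high Kq, decreasing Ksv: purely static
  sta <- list(mk(1.8e4, 296), mk(1.6e4, 303), mk(1.5e4, 310))
  expect_equal(classify_mechanism(sta), "static")
  # single temperature: Kq magnitude only, flagged
  one <- classify_mechanism(list(mk(1.8e4, 310)))
  expect_equal(as.character(one), "static")
  expect_true(attr(one, "low_confidence"))
})

test_that("double_log_fit recovers the binding isotherm", {
  # identity line: (F0-F)/F = Q exactly means Ka = 1, n = 1
  q <- 10^seq(-6, -4, length.out = 5)
  f <- 100 / (1 + q)
  fit <- suppressWarnings(double_log_fit(c(0, q), 100, c(100, f)))
  expect_equal(fit$Ka_per_M, 1, tolerance = 1e-9)
  expect_equal(fit$n_sites, 1, tolerance = 1e-9)
  # generator round trip at published 296 K binding parameters, noiseless
  s <- static_titration(4923, 0.901)
  r <- quench_ratios(s)
  b <- suppressWarnings(
    double_log_fit(r$concentration_M, r$F[1], r$F))
  expect_equal(b$Ka_per_M, 4923, tolerance = 1e-9)
  expect_equal(b$n_sites, 0.901, tolerance = 1e-9)
})

test_that("double_log_fit is invariant to common intensity rescaling", {
  s <- static_titration(4923, 0.901)
  r <- quench_ratios(s)
  a <- suppressWarnings(double_log_fit(r$concentration_M, r$F[1], r$F))
  b <- suppressWarnings(double_log_fit(r$concentration_M, 2 * r$F[1],
                                       2 * r$F))
  expect_equal(b$Ka_per_M, a$Ka_per_M)
  expect_equal(b$n_sites, a$n_sites)
})

test_that("double_log_fit excludes and counts unusable points", {
  q <- c(0, 1e-6, 2e-6, 4e-6, 8e-6, 1.6e-5)
  f0 <- 100
  f <- c(100, 101, 95, 90, 80, 60)  # one point above F0
  fit <- suppressWarnings(double_log_fit(q, f0, f))
  expect_equal(fit$n_excluded, 1)
  expect_equal(fit$n_used + fit$n_excluded, sum(q > 0))
  expect_error(double_log_fit(q[1:3], f0, c(100, 101, 102)),
               "insufficient")
})

test_that("pure-regime fits recover ground truth to 0.1% without noise", {
  for (ksv in c(5e3, 1.832e4, 1e5)) {
    r <- quench_ratios(dynamic_titration(ksv))
    f <- suppressWarnings(stern_volmer_fit(r$concentration_M, r$F0F))
    expect_lt(abs(f$Ksv_per_M / ksv - 1), 1e-3)
  }
  for (ka in c(158, 4923, 1e5)) {
    r <- quench_ratios(static_titration(ka, 0.85))
    b <- suppressWarnings(double_log_fit(r$concentration_M, r$F[1], r$F))
    expect_lt(abs(b$Ka_per_M / ka - 1), 1e-3)
    expect_lt(abs(b$n_sites / 0.85 - 1), 1e-3)
  }
})

test_that("analyze_titration wires ratios, IFE and both fits together", {
  gt <- quenching_ground_truth(Ksv_dynamic_per_M = 1.832e4, Ka_per_M = 0,
                               noise_sd_rel = 0, ligand_eps_ex = 2000,
                               ligand_eps_em = 200)
  s <- generate_titration(gt, seq(0, 1.05e-5, length.out = 9))
  res <- suppressWarnings(analyze_titration(s, eps_ex = 2000,
                                            eps_em = 200))
  expect_equal(res$quenching$Ksv_per_M, 1.832e4, tolerance = 1e-6)
  expect_equal(res$quenching$temperature_K, 310)
})
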