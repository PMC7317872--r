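test_that("Guinier analysis recovers the sphere and Gaussian radii of gyration", {
  prof <- make_saxs_profile(sphere_model(R = 3, noise_frac = 0))
  g <- guinier_fit(prof)
  expect_lt(abs(g$Rg - 3 * sqrt(3 / 5)) / (3 * sqrt(3 / 5)), 0.005)
  expect_lte(g$qmax_Rg, 1.3)
  # exact recovery on a pure Gaussian profile at the dimer-like Rg
  q <- seq(0.02, 3, by = 0.01)
  gp <- saxs_profile(q, 5 * exp(-q^2 * 3.2^2 / 3))
  gg <- guinier_fit(gp)
  expect_equal(gg$Rg, 3.2, tolerance = 1e-6)
  expect_equal(gg$I0, 5, tolerance = 1e-6)
  # intensity rescaling moves I0, not Rg
  g10 <- guinier_fit(saxs_profile(q, 50 * exp(-q^2 * 3.2^2 / 3)))
  expect_equal(g10$Rg, gg$Rg, tolerance = 1e-9)
  expect_equal(g10$I0, 10 * gg$I0, tolerance = 1e-6)
  # rising low-q intensity (aggregation-like upturn) is an error
  expect_error(guinier_fit(saxs_profile(q, seq_along(q) / 10)), "aggregation")
})

test_that("normalized Kratky peak sits at sqrt(3), 3/e for a globular profile and shifts for rods", {
  q <- seq(0.02, 3, by = 0.005)
  Rg <- 3.2
  prof <- saxs_profile(q, exp(-q^2 * Rg^2 / 3))
  g <- guinier_fit(prof)
  k <- normalized_kratky(prof, g)
  expect_lt(abs(k$peak_x - sqrt(3)), 0.01)
  expect_lt(abs(k$peak_y - 3 / exp(1)), 0.005)
  expect_false(k$rod_like)
  # long thin rod: peak beyond sqrt(3)
  L <- 30
  Irod <- rod_form_factor(q, L)
  rodp <- saxs_profile(q, Irod)
  grod <- guinier_fit(rodp, qRg_max = 1.0)
  krod <- normalized_kratky(rodp, grod)
  expect_gt(krod$peak_x, sqrt(3))
  expect_true(krod$rod_like)
})

test_that("the indirect transform reproduces the sphere pair-distance distribution", {
  prof <- make_saxs_profile(sphere_model(R = 3, noise_frac = 0))
  pr <- ift_pr(prof, Dmax = 7.2)
  pan <- sphere_pr(pr$r, 6)
  err <- max(abs(pr$p / max(pr$p) - pan / max(pan)))
  expect_lt(err, 0.02)
  # endpoint conditions and non-negativity
  expect_equal(pr$p[1], 0)
  expect_equal(pr$p[length(pr$p)], 0)
  expect_true(all(pr$p >= 0))
  # maximum dimension within one grid step of 2R
  expect_lt(abs(pr$Dmax_effective - 6), 7.2 / 60 + 1e-9)
  # two estimators of Rg agree within 2%; I0 within 3%
  g <- guinier_fit(prof)
  expect_lt(abs(pr$Rg_real - g$Rg) / g$Rg, 0.02)
  expect_lt(abs(pr$I0_real - g$I0) / g$I0, 0.03)
})

test_that("IFT residuals are white at the chosen regularization on noisy data", {
  prof <- make_saxs_profile(sphere_model(R = 3, noise_frac = 0.01), seed = 71)
  pr <- ift_pr(prof, Dmax = 7.2)
  z <- runs_test_z(pr$residuals)
  expect_lt(abs(z), 2.6)
  expect_lt(pr$chi2, 2)
})

test_that("Dmax scanning finds sphere and dumbbell dimensions and warns off-range", {
  prof <- make_saxs_profile(sphere_model(R = 5), seed = 72)
  pick <- scan_dmax(prof, candidates = seq(8, 16, by = 1))
  expect_lt(abs(pick$Dmax - 10), 1 + 1e-9)
  # two spheres (R = 2) with centres 8 nm apart: Dmax = 12
  q <- seq(0.02, 3, by = 0.01)
  I <- 2 * (3 * (sin(q * 2) - q * 2 * cos(q * 2)) / (q * 2)^3)^2 *
    (1 + sin(q * 8) / (q * 8))
  dumb <- saxs_profile(q, I, sigma = 0.01 * (sqrt(pmax(I, 0) * 2) + 0.02))
  pickd <- scan_dmax(dumb, candidates = seq(9, 16, by = 1))
  expect_lt(abs(pickd$Dmax - 12), 1 + 1e-9)
  # candidate grid that cannot cover the particle: warning
  expect_warning(scan_dmax(prof, candidates = c(3, 4, 5)), "ambiguous|poorly")
})

test_that("volume-of-correlation mass estimation is scale-invariant and truncation-aware", {
  prof <- make_saxs_profile(sphere_model(R = 3, I0 = 1, noise_frac = 0))
  g <- guinier_fit(prof)
  v1 <- vc_molecular_weight(prof, g)
  prof10 <- saxs_profile(prof$q, 10 * prof$I, prof$sigma)
  g10 <- guinier_fit(prof10)
  v10 <- vc_molecular_weight(prof10, g10)
  expect_equal(v10$Vc, v1$Vc, tolerance = 1e-6)
  expect_equal(v10$MW_Da, v1$MW_Da, tolerance = 1e-6)
  # reducing the integration limit must show up in the sensitivity field
  expect_true(is.finite(v1$MW_sensitivity_Da))
  v_trunc <- vc_molecular_weight(prof, g, qmax = 0.8 * max(prof$q))
  expect_equal(v_trunc$MW_Da - v1$MW_Da, v1$MW_sensitivity_Da,
               tolerance = abs(v1$MW_sensitivity_Da) * 0.2 + 1)
  # calibration self-test: forward-generate a globular profile whose QR is
  # known, then check the recovered mass against the planted calibration
  q <- seq(0.001, 4, by = 0.001)
  Rg <- 2.5
  gauss <- saxs_profile(q, exp(-q^2 * Rg^2 / 3))
  gg <- guinier_fit(gauss)
  vv <- vc_molecular_weight(gauss, gg)
  # analytic: Vc = I0 / int q I dq = (2 Rg^2 / 3)^{-1}... evaluated numerically
  int <- sum(diff(q) * (q * gauss$I)[-1])
  expect_equal(vv$Vc, 1 / int, tolerance = 0.01)
  expect_lt(abs(vv$MW_Da - (vv$QR * 1000 / 0.1231)) / vv$MW_Da, 1e-9)
})

test_that("model z-tests reproduce the normal-theory consistency calls", {
  ex <- data.frame(param = c("Rg", "Dmax", "d_NC"),
                   value = c(3.2, 11.6, 5.6), sd = c(0.2, 0.5, 0.3))
  # a model equal to experiment is consistent with p = 1
  z0 <- model_consistency_z(c(Rg = 3.2, Dmax = 11.6, d_NC = 5.6), ex)
  expect_true(all(z0$table$z == 0))
  expect_true(all(z0$table$p == 1))
  expect_true(z0$consistent)
  # z = 1.28 -> two-sided p ~ 0.20 (frozen from the normal CDF)
  z1 <- model_consistency_z(c(Rg = 3.2 + 1.28 * 0.2), ex[1, , drop = FALSE])
  expect_equal(z1$min_p, 0.2005451, tolerance = 1e-6)
  expect_true(z1$consistent)
  # z = 1.96 -> p ~ 0.05: the rejection boundary
  z2 <- model_consistency_z(c(Rg = 3.2 + 1.96 * 0.2), ex[1, , drop = FALSE])
  expect_equal(z2$min_p, 0.0499958, tolerance = 1e-6)
  expect_false(z2$consistent)
})

test_that("SAXS profiles round-trip through the 3-column dat format with unit conversion", {
  prof <- make_saxs_profile(sphere_model(R = 3), seed = 73)
  path <- tempfile(fileext = ".dat")
  write_saxs_profile(prof, path)
  back <- read_saxs_profile(path)
  expect_equal(back$q, prof$q, tolerance = 1e-9)
  expect_equal(back$I, prof$I, tolerance = 1e-9)
  # Angstrom input is converted to nm^-1 and flagged
  backA <- read_saxs_profile(path, units = "angstrom")
  expect_equal(backA$q, prof$q * 10, tolerance = 1e-9)
  expect_true(backA$metadata$converted_from_angstrom)
})
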