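test_that("reduced buoyant term follows the units and linearity of the Boltzmann exponent", {
  sp <- species_params(M = 26000, vbar = 0.73, rho = 1.0)
  expect_equal(reduced_buoyant_term(sp, 0), 0)
  # dimer term is exactly twice the monomer term
  sp2 <- species_params(M = 52000, vbar = 0.73, rho = 1.0)
  om <- rpm_to_omega(28000)
  expect_equal(reduced_buoyant_term(sp2, om), 2 * reduced_buoyant_term(sp, om))
  # frozen hand-unit-checked value: 26 kDa, 32000 rpm, 293 K
  expect_equal(reduced_buoyant_term(sp, rpm_to_omega(32000), T_K = 293),
               3.235881700878, tolerance = 1e-9)
  expect_error(species_params(vbar = 1.2, rho = 1.0), "unphysical")
})

test_that("the equilibrium profile embeds mass action and its degenerate limits", {
  sp <- species_params()
  r <- seq(6.0, 6.15, length.out = 40)
  # omega = 0: constant at eps*(c + 2 c^2/KD) + baseline
  A0 <- se_profile(r, 2e-5, 1.8e-5, sp, 0, meniscus = 6.0, baseline = 0.05)
  expect_equal(A0, rep(sp$eps_l * (2e-5 + 2 * 4e-10 / 1.8e-5) + 0.05, 40),
               tolerance = 1e-12)
  # enormous KD: single ideal species
  om <- rpm_to_omega(28000)
  A1 <- se_profile(r, 2e-5, 1e9, sp, om, meniscus = 6.0)
  sig <- reduced_buoyant_term(sp, om)
  expect_equal(A1, sp$eps_l * 2e-5 * exp(sig * (r^2 - 36) / 2),
               tolerance = 1e-6)
  # strictly increasing for positive buoyancy
  A2 <- se_profile(r, 2e-5, 1.8e-5, sp, om, meniscus = 6.0)
  expect_true(all(diff(A2) > 0))
  expect_error(se_profile(r, 2e-5, 1.8e-5, sp, 1e5, meniscus = 6.0),
               "overflow")
})

test_that("the global fit reproduces noiseless scans to numerical precision", {
  truth <- se_ground_truth()
  scans <- make_se_scans(truth, noise_sd = 0)
  # tiny noise floor keeps the fit well-posed while staying near-exact
  fit <- global_fit_se(scans, species_params())
  expect_lt(fit$rms, 1e-6)
  expect_lt(abs(fit$KD - truth$KD) / truth$KD, 1e-3)
  expect_lt(max(abs(fit$baseline)), 1e-6)
})

test_that("dissociation constants are recovered for both constructs at study noise", {
  truth12 <- se_ground_truth(KD = 18e-6, M_monomer = 26000, c_load = 36e-6,
                             speeds_rpm = c(24000, 28000, 32000))
  fit12 <- global_fit_se(make_se_scans(truth12, noise_sd = 0.005, seed = 61),
                         species_params(M = 26000))
  expect_lt(abs(fit12$KD - 18e-6) / 18e-6, 0.20)
  expect_true(fit12$KD_ci[1] < 18e-6 && 18e-6 < fit12$KD_ci[2])

  truth1 <- se_ground_truth(KD = 52e-6, M_monomer = 15000, c_load = 45e-6,
                            speeds_rpm = c(18000, 20000, 25000))
  fit1 <- global_fit_se(make_se_scans(truth1, noise_sd = 0.005, seed = 62),
                        species_params(M = 15000))
  expect_lt(abs(fit1$KD - 52e-6) / 52e-6, 0.20)
})

test_that("monomer-only data yields a no-association outcome, not a silent boundary", {
  truth <- se_ground_truth(KD = 1e6)   # effectively no dimer
  scans <- make_se_scans(truth, noise_sd = 0.003, seed = 63)
  fit <- global_fit_se(scans, species_params())
  expect_true(fit$no_association)
})

test_that("radial-scan round trip through CSV preserves data and metadata", {
  scans <- make_se_scans(se_ground_truth(), seed = 64)
  path <- tempfile(fileext = ".csv")
  write_radial_scan(scans[[1]], path, seed = 64)
  back <- read_radial_scan(path)
  expect_equal(back$A, scans[[1]]$A, tolerance = 1e-9)
  expect_equal(back$rpm, scans[[1]]$rpm)
  expect_equal(back$meniscus, scans[[1]]$meniscus)
})
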